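# Run configuration: every tunable the pipeline consumes, serializable to a
# flat key=value file so a run can be reproduced from its manifest.

# Conserved 5' nucleotide anchor flanking the VNAR insert in the amplicon.
VNAR_FLANK5 <- "GCCATGGCTGCTCGAGTGGACCAAACACCGCGTGACTGTGAATGGCCCGGGAGGCCA"

# Synthetic 3' anchor used by the read simulator and as the default 3' flank;
# the assay defines only the 5' anchor, so the 3' side is configurable and
# may be empty (insert then extends to the end of the merged amplicon).
VNAR_FLANK3_SYNTHETIC <- "GGTCAGGGTACCCAAGTCACC"

.config_schema <- c(
  flank5 = "character", flank3 = "character",
  max_flank_mismatches = "integer",
  min_overlap_nt = "integer", max_overlap_mismatch_frac = "numeric",
  min_protein_len_aa = "integer", max_protein_len_aa = "integer",
  clonotype_identity_threshold = "numeric",
  member_search_identity_threshold = "numeric",
  top_n_prevalent = "integer", min_clade_unique_sequences = "integer",
  cdr3_lengths_to_mine = "integer_vector", rng_seed = "integer"
)

#' Pipeline configuration
#'
#' Bundles every parameter of the repertoire-mining pipeline. Defaults:
#' clonotype identity threshold
#' 85 (strictly greater-than), member-search threshold 90, top 2000 most
#' prevalent records per library, clade floor of 30 unique sequences, and
#' CDR3 lengths 14 and 12 mined by default.
#'
#' @param flank5 conserved 5' nucleotide anchor (required, non-empty).
#' @param flank3 3' anchor; empty string means the insert runs to the end of
#'   the merged amplicon.
#' @param max_flank_mismatches maximum Hamming mismatches tolerated when
#'   locating either flank (default 0, exact).
#' @param min_overlap_nt minimum read-pair overlap in nt (default 10).
#' @param max_overlap_mismatch_frac maximum mismatch fraction within the
#'   overlap (default 0.25).
#' @param min_protein_len_aa,max_protein_len_aa accepted translated-protein
#'   length bounds (default 80-220 aa, wide enough for hyper-elongated CDR3
#'   loops of over 80 aa).
#' @param clonotype_identity_threshold percent CDR3 identity above which two
#'   sequences share a clonotype (default 85).
#' @param member_search_identity_threshold percent identity for clonotype
#'   member search around a query (default 90).
#' @param top_n_prevalent records per library entering differential mining
#'   (default 2000).
#' @param min_clade_unique_sequences minimum unique sequences for a candidate
#'   clade (default 30, inclusive).
#' @param cdr3_lengths_to_mine integer CDR3 lengths mined (default c(14, 12)).
#' @param rng_seed integer seed recorded with the run.
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(flank5 = VNAR_FLANK5,
                            flank3 = VNAR_FLANK3_SYNTHETIC,
                            max_flank_mismatches = 0L,
                            min_overlap_nt = 10L,
                            max_overlap_mismatch_frac = 0.25,
                            min_protein_len_aa = 80L,
                            max_protein_len_aa = 220L,
                            clonotype_identity_threshold = 85,
                            member_search_identity_threshold = 90,
                            top_n_prevalent = 2000L,
                            min_clade_unique_sequences = 30L,
                            cdr3_lengths_to_mine = c(14L, 12L),
                            rng_seed = 1L) {
  cfg <- list(
    flank5 = toupper(flank5), flank3 = toupper(flank3),
    max_flank_mismatches = as.integer(max_flank_mismatches),
    min_overlap_nt = as.integer(min_overlap_nt),
    max_overlap_mismatch_frac = as.numeric(max_overlap_mismatch_frac),
    min_protein_len_aa = as.integer(min_protein_len_aa),
    max_protein_len_aa = as.integer(max_protein_len_aa),
    clonotype_identity_threshold = as.numeric(clonotype_identity_threshold),
    member_search_identity_threshold = as.numeric(member_search_identity_threshold),
    top_n_prevalent = as.integer(top_n_prevalent),
    min_clade_unique_sequences = as.integer(min_clade_unique_sequences),
    cdr3_lengths_to_mine = as.integer(cdr3_lengths_to_mine),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!nzchar(cfg$flank5)) stop("flank5 must be non-empty")
  if (grepl("[^ACGT]", cfg$flank5)) stop("flank5 must be over A/C/G/T")
  if (nzchar(cfg$flank3) && grepl("[^ACGT]", cfg$flank3))
    stop("flank3 must be over A/C/G/T")
  if (cfg$max_flank_mismatches < 0L) stop("max_flank_mismatches must be >= 0")
  if (cfg$min_overlap_nt < 1L) stop("min_overlap_nt must be >= 1")
  if (cfg$max_overlap_mismatch_frac < 0 || cfg$max_overlap_mismatch_frac > 1)
    stop("max_overlap_mismatch_frac must be in [0, 1]")
  if (cfg$min_protein_len_aa >= cfg$max_protein_len_aa)
    stop("min_protein_len_aa must be < max_protein_len_aa")
  if (cfg$clonotype_identity_threshold <= 0 ||
      cfg$clonotype_identity_threshold > 100)
    stop("clonotype_identity_threshold must be in (0, 100]")
  if (cfg$top_n_prevalent < 1L) stop("top_n_prevalent must be >= 1")
  if (cfg$min_clade_unique_sequences < 1L)
    stop("min_clade_unique_sequences must be >= 1")
  if (length(cfg$cdr3_lengths_to_mine) < 1L ||
      any(cfg$cdr3_lengths_to_mine < 1L))
    stop("cdr3_lengths_to_mine must be positive integers")
  invisible(cfg)
}

#' Write / read a pipeline configuration
#'
#' Flat `key=value` text format; integer vectors are comma-separated. The
#' round trip `read_config(write_config(cfg))` restores the configuration
#' exactly.
#'
#' @param cfg a `pipeline_config`
#' @param path file path
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  keys <- names(.config_schema)
  lines <- vapply(keys, function(k) {
    v <- cfg[[k]]
    paste0(k, "=", paste(as.character(v), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", character(1))
  missing <- setdiff(names(.config_schema), keys)
  if (length(missing))
    stop("config file is missing keys: ", paste(missing, collapse = ", "))
  args <- setNames(vector("list", length(.config_schema)), names(.config_schema))
  for (k in names(.config_schema)) {
    raw <- vals[match(k, keys)]
    args[[k]] <- switch(.config_schema[[k]],
      character = raw,
      integer = as.integer(raw),
      numeric = as.numeric(raw),
      integer_vector = as.integer(strsplit(raw, ",", fixed = TRUE)[[1L]])
    )
  }
  do.call(pipeline_config, args)
}
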