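# Synthetic paired-repertoire generator. Emulates the statistical structure
# the analysis assumes -- a heavily skewed clone-abundance distribution,
# clonally expanded lineages of point-mutation variants, Type-II-dominant
# cysteine architectures, a 5-25 aa CDR3 length bulk with rare ultralong
# outliers, and near-disjoint target/control libraries -- and records
# complete ground truth for recovery testing. The framework template, FR4
# motif and 3' flank are synthetic stand-ins: only the 5' flank is a
# platform-defined constant; no scaffold sequence is.

# Fixed nurse-shark-like framework segments (synthetic). Only CDR1 and CDR3
# are randomized; canonical cysteines sit at protein positions 17 and 71
# (0-based) and FR4 starts with the motif DGAGT.
.VNAR_FR1  <- "ARVDQTPRTATRETGQSCTI"  # 20 aa, canonical Cys1 at index 17
.VNAR_FR2  <- "YWYRKNPGSSN"           # 11 aa; Type I gains C at index 5
.VNAR_HV2  <- "ETISIGGR"              # 8 aa
.VNAR_FR3A <- "YVESVNKG"              # 8 aa
.VNAR_HV4  <- "SKSFS"                 # 5 aa
.VNAR_FR3B <- "LSISNLRVEDSC"          # 12 aa, canonical Cys2 at index 11
.VNAR_FR4  <- "DGAGTVVTVN"            # 10 aa; Type I gains C at index 7
.VNAR_CDR1_LEN <- 8L

#' Synthetic-repertoire generator configuration
#'
#' Defaults define the emulated study conditions: ~2000 clonally expanded
#' background lineages per library (Zipf-distributed sizes capped below the
#' clade-size floor, so that mined candidates are attributable to planted
#' lineages), four planted target-specific lineages of 40 unique
#' 14-aa-CDR3 variants, five small shared lineages (sequence sharing well
#' under 0.2% per library), a Type-II-dominant subtype mix, a CDR3-length
#' bulk with 1.5x-IQR whiskers at about 5 and 25 aa plus rare ultralong
#' outliers, and a read-count distribution with 90.9% singleton mass and a
#' power-law tail reaching ~1e4 repeats.
#'
#' @param n_background_lineages library-private background lineages per
#'   library.
#' @param n_target_specific_lineages planted target-only lineages.
#' @param n_shared_lineages lineages present in both libraries.
#' @param planted_cdr3_len CDR3 length of planted lineages (aa).
#' @param planted_lineage_size unique variants per planted lineage.
#' @param lineage_zipf_exponent,lineage_size_max Zipf exponent and cap for
#'   background lineage sizes (unique variants).
#' @param shared_lineage_size_max size cap for shared lineages.
#' @param mutation_rate per-residue substitution probability per variant.
#' @param subtype_mix named fractions over subtypes I-IV (sums to 1).
#' @param cdr3_len_mean,cdr3_len_sd,cdr3_len_min,cdr3_len_max parameters of
#'   the rounded-normal CDR3 length bulk.
#' @param ultralong_prob,ultralong_range probability and range of ultralong
#'   CDR3 outliers.
#' @param singleton_fraction probability a unique variant is seen once.
#' @param count_tail_exponent,count_max power-law tail of non-singleton
#'   read counts.
#' @param read_length read length in nt.
#' @param sequencing_error_rate per-base substitution error rate.
#' @param coverage read pairs emitted per molecule count.
#' @param flank5,flank3 nucleotide anchors attached around the insert.
#' @param rng_seed integer seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_background_lineages = 2000L,
                             n_target_specific_lineages = 4L,
                             n_shared_lineages = 5L,
                             planted_cdr3_len = 14L,
                             planted_lineage_size = 40L,
                             lineage_zipf_exponent = 1.0,
                             lineage_size_max = 25L,
                             shared_lineage_size_max = 4L,
                             mutation_rate = 0.01,
                             subtype_mix = c(I = 0.15, II = 0.60,
                                             III = 0.15, IV = 0.10),
                             cdr3_len_mean = 15, cdr3_len_sd = 3.7,
                             cdr3_len_min = 5L, cdr3_len_max = 25L,
                             ultralong_prob = 0.002,
                             ultralong_range = c(60L, 80L),
                             singleton_fraction = 0.909,
                             count_tail_exponent = 1.8,
                             count_max = 10000L,
                             read_length = 300L,
                             sequencing_error_rate = 0.001,
                             coverage = 1L,
                             flank5 = VNAR_FLANK5,
                             flank3 = VNAR_FLANK3_SYNTHETIC,
                             rng_seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$subtype_mix) - 1) > 1e-8)
    stop("subtype_mix must sum to 1")
  if (!identical(sort(names(cfg$subtype_mix)), c("I", "II", "III", "IV")))
    stop("subtype_mix must be named I, II, III, IV")
  for (f in c("mutation_rate", "sequencing_error_rate", "singleton_fraction",
              "ultralong_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$planted_cdr3_len < 1L) stop("planted_cdr3_len must be >= 1")
  structure(cfg, class = "generator_config")
}

.sample_lineage_sizes <- function(n, exponent, size_max) {
  if (n == 0L) return(integer(0))
  sample.int(size_max, n, replace = TRUE,
             prob = seq_len(size_max)^(-exponent))
}

.sample_counts <- function(n, singleton_fraction, tail_exponent, count_max) {
  if (n == 0L) return(integer(0))
  counts <- rep(1L, n)
  tail <- which(runif(n) >= singleton_fraction)
  if (length(tail)) {
    ks <- 2:count_max
    counts[tail] <- sample(ks, length(tail), replace = TRUE,
                           prob = ks^(-tail_exponent))
  }
  counts
}

.sample_cdr3_lengths <- function(n, cfg) {
  if (n == 0L) return(integer(0))
  len <- as.integer(pmin(pmax(round(rnorm(n, cfg$cdr3_len_mean,
                                          cfg$cdr3_len_sd)),
                              cfg$cdr3_len_min), cfg$cdr3_len_max))
  ultra <- which(runif(n) < cfg$ultralong_prob)
  if (length(ultra))
    len[ultra] <- sample(cfg$ultralong_range[1L]:cfg$ultralong_range[2L],
                         length(ultra), replace = TRUE)
  len
}

#' Build a clean VNAR scaffold of a given subtype
#'
#' Framework regions come from the fixed synthetic template (canonical
#' cysteines at positions 17 and 71, FR4 motif DGAGT); CDR1 and CDR3 are
#' randomized and non-canonical cysteines are placed per the subtype rule
#' table so that [classify_subtype()] recovers the label on the clean
#' sequence. Uses the current RNG state.
#'
#' @param subtype "I", "II", "III" or "IV".
#' @param cdr3_len CDR3 length in aa (Type I needs at least 2).
#' @return list with `protein`, `subtype`, `cdr3`, `regions` (ground-truth
#'   0-based half-open intervals), `canonical_cys1`, `canonical_cys2`.
#' @export
build_scaffold <- function(subtype = c("II", "I", "III", "IV"), cdr3_len) {
  subtype <- match.arg(subtype)
  stopifnot(cdr3_len >= 1L, subtype != "I" || cdr3_len >= 2L)
  alph <- .AA_LOOP_ALPHABET
  cdr1 <- sample(alph, .VNAR_CDR1_LEN, replace = TRUE)
  cdr3 <- sample(alph, cdr3_len, replace = TRUE)
  fr2 <- .VNAR_FR2
  fr4 <- .VNAR_FR4
  if (subtype == "I") {
    substr(fr2, 6L, 6L) <- "C"
    substr(fr4, 8L, 8L) <- "C"
    cdr3[sample.int(cdr3_len, 2L)] <- "C"
  } else if (subtype %in% c("II", "III")) {
    pos <- sample.int(.VNAR_CDR1_LEN, if (subtype == "III") 2L else 1L)
    cdr1[pos[1L]] <- "C"
    if (subtype == "III") cdr1[pos[2L]] <- "W"
    cdr3[sample.int(cdr3_len, 1L)] <- "C"
  }
  protein <- paste0(.VNAR_FR1, paste(cdr1, collapse = ""), fr2, .VNAR_HV2,
                    .VNAR_FR3A, .VNAR_HV4, .VNAR_FR3B,
                    paste(cdr3, collapse = ""), fr4)
  bounds <- c(0L, 20L, 28L, 39L, 47L, 55L, 60L, 72L, 72L + cdr3_len,
              82L + cdr3_len)
  regions <- lapply(seq_len(9L), function(i) c(bounds[i], bounds[i + 1L]))
  names(regions) <- .REGION_NAMES
  list(protein = protein, subtype = subtype,
       cdr3 = paste(cdr3, collapse = ""), regions = regions,
       canonical_cys1 = 17L, canonical_cys2 = 71L)
}

#' Expand a lineage into point-mutation variants
#'
#' Produces `n_variants` proteins (the seed first). With a positive
#' mutation rate the variants are pairwise distinct: each draws
#' 1 + Poisson(rate * length) substitutions at allowed positions --
#' cysteines, the FR4 motif and the CDR1 conservation marker are never
#' touched, and substitutions never introduce C or W -- so the subtype
#' label and clonotype membership are stable across the lineage. With rate
#' 0 all variants equal the seed. Uses the current RNG state.
#'
#' @param scaffold result of [build_scaffold()].
#' @param n_variants number of variants (>= 1), seed included.
#' @param mutation_rate per-residue substitution probability.
#' @return character vector of proteins, seed first.
#' @export
expand_lineage <- function(scaffold, n_variants, mutation_rate) {
  stopifnot(n_variants >= 1L)
  seed <- scaffold$protein
  if (mutation_rate == 0 || n_variants == 1L)
    return(rep(seed, n_variants))
  chars <- strsplit(seed, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  fr4_start <- scaffold$regions$FR4[1L]
  protected <- chars == "C" |
    seq_len(n) %in% ((fr4_start + 1L):(fr4_start + 5L)) |
    (chars == "W" & seq_len(n) > scaffold$regions$CDR1[1L] &
       seq_len(n) <= scaffold$regions$CDR1[2L])
  allowed <- which(!protected)
  alph <- .AA_LOOP_ALPHABET
  out <- character(n_variants)
  out[1L] <- seed
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(seed, TRUE, envir = seen)
  for (i in seq_len(n_variants - 1L) + 1L) {
    for (try in seq_len(200L)) {
      k <- 1L + rpois(1L, mutation_rate * n)
      k <- min(k, length(allowed))
      pos <- sample(allowed, k)
      v <- chars
      for (p in pos) {
        v[p] <- sample(setdiff(alph, chars[p]), 1L)
      }
      prot <- paste(v, collapse = "")
      if (!exists(prot, envir = seen, inherits = FALSE)) {
        assign(prot, TRUE, envir = seen)
        out[i] <- prot
        break
      }
    }
    if (!nzchar(out[i]))
      stop("could not generate ", n_variants, " distinct variants")
  }
  out
}

# One lineage: scaffold + variants + per-library counts. Seed gets the
# largest count in each library where the lineage is present.
.make_lineage <- function(lineage_id, class, library, subtype, cdr3_len,
                          size, cfg) {
  scaffold <- build_scaffold(subtype, cdr3_len)
  variants <- expand_lineage(scaffold, size, cfg$mutation_rate)
  counts_for <- function() {
    sort(.sample_counts(size, cfg$singleton_fraction,
                        cfg$count_tail_exponent, cfg$count_max),
         decreasing = TRUE)
  }
  ct <- if (library %in% c("target", "both")) counts_for() else rep(0L, size)
  cc <- if (library %in% c("control", "both")) counts_for() else rep(0L, size)
  ann <- vapply(variants, function(p) {
    a <- annotate_regions(p)
    if (inherits(a, "vnar_unannotatable")) NA_character_ else a$cdr3
  }, character(1), USE.NAMES = FALSE)
  data.frame(lineage_id = lineage_id, class = class, library = library,
             sequence = variants, is_seed = seq_along(variants) == 1L,
             subtype = subtype, cdr3 = ann,
             cdr3_len = ifelse(is.na(ann), NA_integer_, nchar(ann)),
             count_target = ct, count_control = cc,
             stringsAsFactors = FALSE)
}

#' Generate a paired target/control synthetic library
#'
#' Draws background, shared and planted lineages per the configuration and
#' assembles dereplicated, prevalence-ranked repertoire tables for both
#' libraries plus a complete ground-truth manifest. Planted target-specific
#' lineages appear only in the target library; shared lineages appear in
#' both with independently sampled counts.
#'
#' @param cfg a [generator_config()].
#' @return list with `target` and `control` (`repertoire_table`s) and
#'   `manifest` (data.frame: lineage_id, class, library, sequence, is_seed,
#'   subtype, cdr3, cdr3_len, count_target, count_control).
#' @export
generate_library_pair <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$rng_seed)
  specs <- list()
  add_spec <- function(class, library, n, sizes, cdr3_lens) {
    if (n == 0L) return()
    subtypes <- sample(names(cfg$subtype_mix), n, replace = TRUE,
                       prob = cfg$subtype_mix)
    # Type I needs >= 2 CDR3 residues for a cysteine pair
    subtypes[subtypes == "I" & cdr3_lens < 2L] <- "II"
    for (i in seq_len(n))
      specs[[length(specs) + 1L]] <<- list(
        class = class, library = library, subtype = subtypes[i],
        cdr3_len = cdr3_lens[i], size = sizes[i])
  }
  nb <- cfg$n_background_lineages
  add_spec("background", "target", nb,
           .sample_lineage_sizes(nb, cfg$lineage_zipf_exponent,
                                 cfg$lineage_size_max),
           .sample_cdr3_lengths(nb, cfg))
  add_spec("background", "control", nb,
           .sample_lineage_sizes(nb, cfg$lineage_zipf_exponent,
                                 cfg$lineage_size_max),
           .sample_cdr3_lengths(nb, cfg))
  ns <- cfg$n_shared_lineages
  add_spec("shared", "both", ns,
           pmin(.sample_lineage_sizes(ns, cfg$lineage_zipf_exponent,
                                      cfg$lineage_size_max),
                cfg$shared_lineage_size_max),
           .sample_cdr3_lengths(ns, cfg))
  np <- cfg$n_target_specific_lineages
  add_spec("planted", "target", np,
           rep(cfg$planted_lineage_size, np),
           rep(cfg$planted_cdr3_len, np))
  manifest <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    .make_lineage(sprintf("L%05d", i), s$class, s$library, s$subtype,
                  s$cdr3_len, s$size, cfg)
  }))
  rownames(manifest) <- NULL
  table_for <- function(count_col, library_id) {
    rows <- manifest[manifest[[count_col]] > 0L, c("sequence", count_col)]
    names(rows)[2L] <- "count"
    agg <- stats::aggregate(count ~ sequence, data = rows, FUN = sum)
    agg <- agg[order(-agg$count, agg$sequence, method = "radix"), ,
               drop = FALSE]
    agg$rank <- seq_len(nrow(agg))
    repertoire_table(agg, library_id)
  }
  list(target = table_for("count_target", "target"),
       control = table_for("count_control", "control"),
       manifest = manifest)
}

# Codon lists per amino acid, standard genetic code.
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Uniform-codon reverse translation of a protein vector (current RNG state).
.reverse_translate <- function(proteins) {
  ct <- .codon_table()
  aa <- strsplit(proteins, "", fixed = TRUE)
  grp <- rep(seq_along(proteins), lengths(aa))
  v <- unlist(aa, use.names = FALSE)
  cod <- character(length(v))
  for (letter in unique(v)) {
    idx <- which(v == letter)
    codons <- ct[[letter]]
    cod[idx] <- codons[sample.int(length(codons), length(idx),
                                  replace = TRUE)]
  }
  vapply(split(cod, grp), paste, character(1), collapse = "",
         USE.NAMES = FALSE)
}

#' Emit paired-end reads for a repertoire table
#'
#' Each unique molecule is reverse-translated with uniform random codons,
#' wrapped in the configured flanks, and fragmented into
#' `count * coverage` forward/reverse read pairs with substitution errors
#' at the configured rate and constant Q30 base qualities. Deterministic
#' under `seed`.
#'
#' @param tab a `repertoire_table` (truth counts).
#' @param cfg a [generator_config()].
#' @param path_fwd,path_rev output FASTQ paths.
#' @param seed RNG seed (default `cfg$rng_seed`); NULL keeps the current
#'   RNG state.
#' @return invisibly, a data.frame mapping molecule index to sequence,
#'   nt insert and emitted read count.
#' @export
emit_reads <- function(tab, cfg, path_fwd, path_rev, seed = cfg$rng_seed) {
  validate_repertoire_table(tab)
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  proteins <- tab$records$sequence
  counts <- tab$records$count * cfg$coverage
  nt <- .reverse_translate(proteins)
  amp <- paste0(cfg$flank5, nt, cfg$flank3)
  too_long <- which(nchar(amp) > 2L * cfg$read_length - 10L)
  if (length(too_long))
    stop("amplicon too long for an overlapping read pair: molecule(s) ",
         paste(head(too_long, 5L), collapse = ", "),
         " (max insert ", 2L * cfg$read_length - 10L - nchar(cfg$flank5) -
           nchar(cfg$flank3), " nt)")
  rc <- .revcomp(amp)
  idx <- rep(seq_along(amp), counts)
  fwd <- substr(amp[idx], 1L, cfg$read_length)
  rev <- substr(rc[idx], 1L, cfg$read_length)
  if (cfg$sequencing_error_rate > 0) {
    fwd <- .add_substitution_errors(fwd, cfg$sequencing_error_rate)
    rev <- .add_substitution_errors(rev, cfg$sequencing_error_rate)
  }
  copy <- sequence(counts)
  ids <- sprintf("mol%06d_c%04d", idx, copy)
  write_fastq(paste0(ids, "/1"), fwd, strrep("?", nchar(fwd)), path_fwd)
  write_fastq(paste0(ids, "/2"), rev, strrep("?", nchar(rev)), path_rev)
  vnar_log("simulate", "%d molecules -> %d read pairs (%s)",
           length(amp), length(idx), basename(path_fwd))
  invisible(data.frame(molecule = seq_along(amp), sequence = proteins,
                       nt_insert = nt, n_reads = counts,
                       stringsAsFactors = FALSE))
}

.add_substitution_errors <- function(reads, rate) {
  widths <- nchar(reads)
  nerr <- rbinom(length(reads), widths, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(widths[i], nerr[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(.DNA_BASES, cur), 1L)
    }
  }
  reads
}
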