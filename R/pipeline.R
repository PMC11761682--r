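# End-to-end driver chaining the stages over the synthetic library pair:
# simulate -> process -> derep -> annotate -> summarize -> mine -> stats.
# One global seed fans out to per-stage seeds (seed + fixed stage offset)
# so each stage is independently reproducible; identical seed and
# configuration give byte-identical outputs.

.STAGE_OFFSETS <- c(simulate = 1L, emit_target = 2L, emit_control = 3L,
                    stats = 4L)

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  path
}

#' Synthesize an affinity table for prevalence-correlation reporting
#'
#' Draws a monotone-with-noise relation between NGS prevalence and
#' dissociation constant for the top clones (higher prevalence, lower KD),
#' plus Sanger-like repeat counts proportional to prevalence. A synthetic
#' stand-in used by the pipeline's reporting stage; uses the current RNG
#' state.
#'
#' @param tab a `repertoire_table`.
#' @param n number of clones (default 10).
#' @return data.frame with `clone_id`, `kd`, `ngs_repeats`,
#'   `sanger_repeats`.
#' @export
synthesize_affinity <- function(tab, n = 10L) {
  validate_repertoire_table(tab)
  n <- min(n, nrow(tab$records))
  if (n < 3L) stop("need at least 3 records")
  rec <- tab$records[seq_len(n), ]
  kd <- 1e-7 * rec$count^(-0.8) * 10^rnorm(n, 0, 0.3)
  sanger <- rbinom(n, size = pmax(rec$count, 1L), prob = 0.05) + 1L
  data.frame(clone_id = sprintf("NGS%d", rec$rank), kd = kd,
             ngs_repeats = rec$count, sanger_repeats = sanger,
             stringsAsFactors = FALSE)
}

#' Run the full repertoire-mining pipeline on a synthetic library pair
#'
#' Executes simulate -> process -> derep -> annotate -> summarize -> mine
#' -> stats, writing every artifact (FASTQ pairs, truth manifest, annotated
#' repertoire TSVs, QC, overlap/abundance/CDR3 summaries, per-length mining
#' reports with candidate FASTA and Newick trees, correlation TSVs, and a
#' JSON run manifest) under `outdir`. Deterministic: identical `seed`,
#' `config` and `gen_config` reproduce byte-identical outputs.
#'
#' @param outdir output directory (created if missing).
#' @param seed global integer seed, fanned out per stage.
#' @param config a [pipeline_config()].
#' @param gen_config a [generator_config()]; its `rng_seed` is overridden
#'   by the stage seed derived from `seed`.
#' @return invisibly, a list with the main in-memory results (tables,
#'   mining reports, qc, overlap, manifest path).
#' @export
run_pipeline <- function(outdir, seed = 1L, config = pipeline_config(),
                         gen_config = generator_config()) {
  validate_pipeline_config(config)
  stopifnot(inherits(gen_config, "generator_config"))
  seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  stage_seed <- function(stage) seed + .STAGE_OFFSETS[[stage]]

  # --- simulate ---------------------------------------------------------
  gen_config$rng_seed <- stage_seed("simulate")
  vnar_log("simulate", "generating library pair (seed %d)",
           gen_config$rng_seed)
  sim <- generate_library_pair(gen_config)
  .write_tsv(sim$manifest, p("truth_manifest.tsv"))
  fq <- list(target = c(p("target_R1.fastq"), p("target_R2.fastq")),
             control = c(p("control_R1.fastq"), p("control_R2.fastq")))
  emit_reads(sim$target, gen_config, fq$target[1L], fq$target[2L],
             seed = stage_seed("emit_target"))
  emit_reads(sim$control, gen_config, fq$control[1L], fq$control[2L],
             seed = stage_seed("emit_control"))
  write_config(config, p("config.txt"))

  # --- process / derep / annotate --------------------------------------
  tables <- list()
  qcs <- list()
  for (lib in c("target", "control")) {
    proc <- process_library(fq[[lib]][1L], fq[[lib]][2L], config)
    qcs[[lib]] <- proc$qc
    tab <- dereplicate(proc$vnars, library_id = lib)
    tab <- annotate_repertoire(tab)
    tables[[lib]] <- tab
    write_repertoire_table(tab, p(paste0(lib, "_repertoire.tsv")))
    .write_tsv(data.frame(stage = names(unclass(proc$qc)),
                          records = unlist(unclass(proc$qc))),
               p(paste0(lib, "_qc.tsv")))
  }

  # --- summarize --------------------------------------------------------
  ab <- lapply(tables, abundance_summary)
  ov <- library_overlap(tables$target, tables$control)
  .write_tsv(data.frame(library = names(ab),
                        n_unique = vapply(ab, `[[`, 0, "n_unique"),
                        frac_lt_10_reads = vapply(ab, `[[`, 0, "frac_lt_k_reads"),
                        frac_singletons = vapply(ab, `[[`, 0, "frac_singletons")),
             p("abundance.tsv"))
  .write_tsv(as.data.frame(ov), p("overlap.tsv"))
  cls <- cdr3_length_stats(tables$target$records$cdr3_len,
                           ids = record_ids(tables$target),
                           subtypes = tables$target$records$subtype)
  .write_tsv(data.frame(statistic = c("n", "median", "q1", "q3", "iqr",
                                      "whisker_low", "whisker_high"),
                        value = c(cls$n, cls$median, cls$q1, cls$q3,
                                  cls$iqr, cls$whisker_low,
                                  cls$whisker_high)),
             p("cdr3_stats.tsv"))

  # --- mine -------------------------------------------------------------
  reports <- list()
  for (len in config$cdr3_lengths_to_mine) {
    rep_len <- withCallingHandlers(
      mine_differential_clades(tables$target, tables$control, config, len),
      warning = function(w) {
        vnar_log("mine", "%s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    reports[[as.character(len)]] <- rep_len
    .write_tsv(rep_len$clades, p(sprintf("clades_len%d.tsv", len)))
    .write_tsv(rank_candidates(rep_len), p(sprintf("candidates_len%d.tsv", len)))
    if (nrow(rep_len$representatives)) {
      reps <- Biostrings::AAStringSet(rep_len$representatives$sequence)
      names(reps) <- sprintf("clade%d_%s", rep_len$representatives$clade_id,
                             rep_len$representatives$id)
      Biostrings::writeXStringSet(reps, p(sprintf("candidates_len%d.fasta",
                                                  len)))
      members <- rep_len$pooled[rep_len$pooled$clade_id %in%
                                  rep_len$candidates$clade_id, ]
      if (nrow(members) >= 2L) {
        tree <- build_tree(members$pool_id, members$cdr3)
        writeLines(write_newick(tree), p(sprintf("candidates_len%d.nwk", len)))
      }
    }
    vnar_log("mine", "CDR3 length %d: %d clades, %d candidates", len,
             nrow(rep_len$clades), nrow(rep_len$candidates))
  }

  # --- stats ------------------------------------------------------------
  set.seed(stage_seed("stats"))
  aff <- synthesize_affinity(tables$target, n = 10L)
  .write_tsv(aff, p("affinity_synthetic.tsv"))
  corr <- prevalence_affinity_table(aff)
  sanger <- pearson_r2(aff$sanger_repeats, aff$ngs_repeats)
  .write_tsv(rbind(corr$correlations,
                   data.frame(variant = "sanger_vs_ngs_repeats",
                              r = sanger$r, r_squared = sanger$r_squared)),
             p("correlations.tsv"))

  # --- run manifest -----------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir), "run_manifest.json"))
  manifest <- list(
    command = "run_pipeline",
    tool_version = as.character(utils::packageVersion("vnarmine")),
    seed = seed,
    stage_seeds = as.list(seed + .STAGE_OFFSETS),
    config = unclass(config),
    generator_config = unclass(gen_config),
    input_checksums = as.list(setNames(unname(tools::md5sum(unlist(fq))),
                                       basename(unlist(fq)))),
    outputs = as.list(setNames(unname(tools::md5sum(file.path(outdir, outputs))),
                               outputs))
  )
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(tables = tables, qc = qcs, overlap = ov, abundance = ab,
                 cdr3_stats = cls, mining = reports,
                 manifest_path = p("run_manifest.json")))
}
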