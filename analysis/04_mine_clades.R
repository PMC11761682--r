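#!/usr/bin/env Rscript
# Stage 4 -- differential clade mining.
#
# Pools the top-2000 most prevalent equal-length CDR3s from both libraries,
# clusters them at >85% identity (single linkage), and reports the
# target-unique clades with >= 30 unique sequences. Their prevalence-ranked
# representatives are the candidate binders nominated without biopanning.

suppressPackageStartupMessages(library(vnarmine))

indir <- "results/repertoire"
outdir <- "results/mining"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config()

target <- read_repertoire_table(file.path(indir, "target_repertoire.tsv"))
control <- read_repertoire_table(file.path(indir, "control_repertoire.tsv"))

for (len in cfg$cdr3_lengths_to_mine) {
  report <- withCallingHandlers(
    mine_differential_clades(target, control, cfg, len),
    warning = function(w) { message(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  print(report)
  write.table(report$clades, file.path(outdir, sprintf("clades_len%d.tsv", len)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ranked <- rank_candidates(report)
  write.table(ranked, file.path(outdir, sprintf("candidates_len%d.tsv", len)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$representatives)) {
    reps <- Biostrings::AAStringSet(report$representatives$sequence)
    names(reps) <- sprintf("clade%d_%s", report$representatives$clade_id,
                           report$representatives$id)
    Biostrings::writeXStringSet(
      reps, file.path(outdir, sprintf("candidates_len%d.fasta", len)))
    members <- report$pooled[report$pooled$clade_id %in%
                               report$candidates$clade_id, ]
    if (nrow(members) >= 2) {
      writeLines(write_newick(build_tree(members$pool_id, members$cdr3)),
                 file.path(outdir, sprintf("candidates_len%d.nwk", len)))
    }
    cat(sprintf("length %d: representatives %s\n", len,
                paste(report$representatives$id, collapse = ", ")))
  }
}
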