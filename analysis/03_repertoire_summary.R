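#!/usr/bin/env Rscript
# Stage 3 -- library composition summaries.
#
# Rank-abundance skew (singleton and <10-read fractions), subtype
# distribution, CDR3 length distribution with 1.5x-IQR whiskers and
# ultralong outliers, and target/control sequence sharing.

suppressPackageStartupMessages(library(vnarmine))

indir <- "results/repertoire"
outdir <- "results/summary"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tabs <- lapply(c(target = "target", control = "control"), function(lib)
  read_repertoire_table(file.path(indir, paste0(lib, "_repertoire.tsv"))))

ab <- lapply(tabs, abundance_summary)
summary_df <- data.frame(
  library = names(ab),
  n_unique = vapply(ab, `[[`, 0, "n_unique"),
  frac_singletons = vapply(ab, `[[`, 0, "frac_singletons"),
  frac_lt_10_reads = vapply(ab, `[[`, 0, "frac_lt_k_reads"))
write.table(summary_df, file.path(outdir, "abundance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("target singleton fraction: %.1f%%; <10 reads: %.1f%%\n",
            100 * ab$target$frac_singletons, 100 * ab$target$frac_lt_k_reads))

subtype_df <- as.data.frame(table(subtype = tabs$target$records$subtype))
write.table(subtype_df, file.path(outdir, "subtypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("subtype distribution (target):\n")
print(subtype_df)

cls <- cdr3_length_stats(tabs$target$records$cdr3_len,
                         ids = record_ids(tabs$target),
                         subtypes = tabs$target$records$subtype)
cat(sprintf("CDR3 length: median %g, IQR [%g, %g], whiskers [%g, %g], %d outliers\n",
            cls$median, cls$q1, cls$q3, cls$whisker_low, cls$whisker_high,
            nrow(cls$outliers)))
write.table(cls$outliers, file.path(outdir, "cdr3_outliers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ov <- library_overlap(tabs$target, tabs$control)
write.table(as.data.frame(ov), file.path(outdir, "overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("sequence sharing: %.3f%% of target, %.3f%% of control\n",
            100 * ov$frac_shared_of_a, 100 * ov$frac_shared_of_b))
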