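#!/usr/bin/env Rscript
# Stage 5 -- prevalence correlations.
#
# Relates NGS clone prevalence to (synthetic) Sanger hit counts and
# measured affinities for the top clones, reporting Pearson correlations
# under all axis conventions. The affinity table is a labelled synthetic
# stand-in: the pipeline's claim is about the analysis machinery, not about
# any measured binder.

suppressPackageStartupMessages(library(vnarmine))

indir <- "results/repertoire"
outdir <- "results/correlations"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

target <- read_repertoire_table(file.path(indir, "target_repertoire.tsv"))
set.seed(4L)
aff <- synthesize_affinity(target, n = 10L)
write.table(aff, file.path(outdir, "affinity_synthetic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

res <- prevalence_affinity_table(aff)
sanger <- pearson_r2(aff$sanger_repeats, aff$ngs_repeats)
corr <- rbind(res$correlations,
              data.frame(variant = "sanger_vs_ngs_repeats", r = sanger$r,
                         r_squared = sanger$r_squared))
write.table(corr, file.path(outdir, "correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("prevalence/affinity correlations:\n")
print(corr, row.names = FALSE)
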