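#!/usr/bin/env Rscript
# Stage 1 -- simulate the paired sequencing experiment.
#
# Generates the target-immunized and control-immunized synthetic VNAR
# libraries at the default study conditions (~2000 clonally expanded
# lineages and ~5e4 reads per library, four planted target-specific
# lineages of 40 unique 14-aa-CDR3 variants, five small shared lineages)
# and emits error-free paired-end FASTQ plus the ground-truth manifest.

suppressPackageStartupMessages(library(vnarmine))

seed <- 1L
outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

gen <- generator_config(sequencing_error_rate = 0, rng_seed = seed)
pair <- generate_library_pair(gen)
write.table(pair$manifest, file.path(outdir, "truth_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_repertoire_table(pair$target, file.path(outdir, "truth_target.tsv"))
write_repertoire_table(pair$control, file.path(outdir, "truth_control.tsv"))
emit_reads(pair$target, gen, file.path(outdir, "target_R1.fastq"),
           file.path(outdir, "target_R2.fastq"), seed = seed + 1L)
emit_reads(pair$control, gen, file.path(outdir, "control_R1.fastq"),
           file.path(outdir, "control_R2.fastq"), seed = seed + 2L)

cat(sprintf("target:  %d unique VNARs, %d reads\n",
            nrow(pair$target$records), pair$target$total_reads))
cat(sprintf("control: %d unique VNARs, %d reads\n",
            nrow(pair$control$records), pair$control$total_reads))
cat(sprintf("planted target-specific lineages: %d (CDR3 length %d)\n",
            gen$n_target_specific_lineages, gen$planted_cdr3_len))
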