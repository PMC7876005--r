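#!/usr/bin/env Rscript

# Step 1: generate the standard synthetic co-fractionation experiment.
#
# 200 proteins and 30 metabolites over a 48-fraction SEC gradient (38
# protein-containing fractions spanning ~5.2 MDa-20 kDa), 3 biological
# replicates at 15% intensity CV, with 20 planted protein-metabolite
# interactions (grouped on 5 metabolites), 5 planted complexes, and a
# log-linear mass calibration. Inputs are written as the TSV dialect the
# pipeline reads, so later steps run from files exactly as a real
# experiment would.

suppressPackageStartupMessages(library(cofracpmi))

seed <- 1L
out <- "results/sec"
dir.create(file.path(out, "inputs"), recursive = TRUE, showWarnings = FALSE)

cfg <- benchmark_config(seed)
sim <- simulate_fractionation(cfg)
paths <- write_fraction_tables(sim$dataset, file.path(out, "inputs"),
                               truth = sim$truth)
refs <- generate_calibration_refs(6, cfg$mass_range, c(1, cfg$protein_span))
write.table(refs, file.path(out, "inputs", "calibration.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$peaks, file.path(out, "truth_peaks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$complexes, file.path(out, "truth_complexes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d proteins + %d metabolites x %d fractions, %d replicates\n",
            cfg$n_proteins, cfg$n_metabolites, cfg$n_fractions, cfg$n_replicates))
cat(sprintf("Planted: %d PMIs on %d metabolites, %d complexes, noise CV %.0f%%\n",
            nrow(sim$truth$pmis), length(unique(sim$truth$pmis$metabolite_id)),
            length(unique(sim$truth$complexes$complex_id)), 100 * cfg$noise_cv))
cat("Inputs written under", file.path(out, "inputs"), "\n")
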