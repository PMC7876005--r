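#!/usr/bin/env Rscript

# Step 3: co-elution scoring, ROC threshold selection, FDR estimate and
# the interaction network, with a ground-truth comparison.
#
# Every metabolite peak inside the protein-containing window is correlated
# with every protein peak; feature pairs are summarized by their best
# peak-pair correlation; the planted (known) interactions against a
# 100-iteration random-pair null give the ROC curve, the FDR estimate at
# the 0.7 operating threshold and the fold-enrichment over chance.

suppressPackageStartupMessages(library(cofracpmi))

inputs <- "results/sec/inputs"
if (!dir.exists(inputs)) stop("run analysis/01_simulate_sec.R first")
seed <- 1L

run <- run_cofrac(list(
  proteins = sort(Sys.glob(file.path(inputs, "proteins_rep*.tsv"))),
  metabolites = sort(Sys.glob(file.path(inputs, "metabolites_rep*.tsv"))),
  calibration = file.path(inputs, "calibration.tsv"),
  known = file.path(inputs, "known_pmis.tsv"),
  out_dir = "results/sec/results",
  seed = seed
))

truth <- read_pair_list(file.path(inputs, "known_pmis.tsv"))
planted <- paste(truth$chemical_id, truth$protein_id)
called <- paste(run$network$edges$metabolite_id, run$network$edges$protein_id)

cat(sprintf("ROC AUC %.3f; at PCC >= %.1f: TPR %.2f, FPR %.4f\n",
            run$roc$auc, run$roc$t_star, run$roc$tpr_star, run$roc$fpr_star))
cat(sprintf("Recovered %d of %d planted PMIs; %d network edges total\n",
            length(intersect(called, planted)), length(planted), length(called)))
cat(sprintf("Estimated FDR %.1f%%; realized FDR %.1f%%; fold over chance: %s\n",
            100 * run$roc$fdr,
            100 * (if (length(called)) mean(!(called %in% planted)) else 0),
            if (is.infinite(run$roc$fold_enrichment)) "infinite (no chance hits)"
            else sprintf("%.1f", run$roc$fold_enrichment)))
cat("Tables under results/sec/results\n")
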