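# cofracpmi

Inference of protein–metabolite interactions (PMIs) from co-fractionation
mass spectrometry, for proteomics/metabolomics groups running
size-exclusion (SEC) co-elution experiments and for methodologists who
want every statistical step of such a pipeline testable against planted
ground truth.

A native lysate separated by SEC keeps complexes intact: molecules that
are bound travel together, so a protein-bound metabolite shows up in
high-molecular-weight fractions with an elution profile matching its
partner's. `cofracpmi` turns fraction × feature intensity tables into a
thresholded PMI network with FDR control, and adds the surrounding
analyses such experiments use: molecular-weight calibration and
oligomeric-state calls, thermal proteome profiling (TPP) curve tests,
affinity-purification (AP) enrichment, evidence tiering, and targeted
binding/enzymology fits.

## The model in brief

* **Elution peaks.** Each feature's replicate-averaged, max-normalized
  profile is deconvolved into single Gaussian peaks
  (A·exp(−(x−μ)²/2σ²)); peaks are kept when their apex recurs in ≥2 of 3
  replicates. A reference-protein calibration line
  log₁₀(mass) = a·fraction + b converts peak centers to apparent masses;
  an oligomeric state ratio (apparent / monomeric mass) above 1.5 calls
  a peak multimeric.
* **Co-elution scoring.** Pearson correlation (PCC) between every
  metabolite peak and protein peak over the protein-containing window,
  summarized per feature pair by the maximum over peak pairs.
* **Threshold, FDR, enrichment.** A ROC curve of known interactions
  against a 100-iteration random-pair null selects the operating point
  (default PCC ≥ 0.7); there,
  FDR = m̄_null / (m̄_null + m_true) and fold-enrichment over chance
  = m_true / m̄_null.
* **Orthogonal evidence.** TPP melting curves
  f(T) = (1−p)/(1+exp(b−a/T)) + p are compared between vehicle and
  treatment by a nested-model F-test (shared vs per-condition curves,
  parameter-counting degrees of freedom, Benjamini–Hochberg across
  proteins); AP enrichment is a Welch t-test + BH + log2FC ≥ 1 in either
  coupling orientation; proteins supported by ≥2 of {SEC, AP, TPP} form
  the interactome, 3 of 3 the high-confidence tier.
* **Binding fits.** Dose–response curves are fitted with the quadratic
  1:1 isotherm
  response = f₀ + (f₁−f₀)·[(K_d+P_t+L) − √((K_d+P_t+L)² − 4·P_t·L)]/(2·P_t),
  which reduces to L/(K_d+L) at trace target concentration.

A bundled generator simulates every input with planted truth: 48-fraction
SEC runs (38 protein-containing, ~5.2 MDa–20 kDa), 3 replicates,
multiplicative lognormal noise, planted complexes and PMIs, TPP midpoint
shifts, AP enrichments and dose–response ladders.

## Worked example

The one-command demo generates the standard benchmark (200 proteins, 30
metabolites, 20 planted PMIs, 3 replicates, 15% noise), writes the input
TSVs, runs the full file-based pipeline and compares the called network
with the planted truth:

```r
library(cofracpmi)
demo <- run_demo(seed = 1, out_dir = "demo")
str(demo$report)
#> List of 11
#>  $ seed               : num 1
#>  $ n_planted          : int 20
#>  $ n_edges            : int 20
#>  $ n_recovered        : int 20
#>  $ n_false            : int 0
#>  $ n_complex_artifacts: int 0
#>  $ sensitivity        : num 1
#>  $ realized_fdr       : num 0
#>  $ estimated_fdr      : num 0
#>  $ auc                : num 1
#>  $ fold_enrichment    : num Inf
```

All 20 planted interactions are recovered at PCC ≥ 0.7 with no false
edges; the null-based FDR estimate (0) agrees with the realized FDR
against ground truth, and the fold-enrichment over chance is infinite
because no random pair reaches the threshold. Stage outputs (peak table
with apparent masses, pair scores, ROC curve, network, oligomeric-state
calls) land under `demo/results/`.

The same machinery as a step-by-step analysis lives in `analysis/`
(numbered scripts, run from the repository root in order):

```text
01_simulate_sec.R        inputs under results/sec/inputs
02_deconvolve_calibrate.R  321 peaks from 227 features; mean replicate
                           reproducibility r = 0.979; 149/289 protein
                           peaks multimeric
03_coelution_network.R   ROC AUC 1.000; 20/20 planted PMIs; estimated
                           FDR 0.0% vs realized 0.0%
04_orthogonal_evidence.R interactome (≥2 of 3 arms): 6; high confidence: 4
05_binding_enzymology.R  K_d 419 µM; ATP affinity 118 µM → 3.0 µM
                           (39-fold); 32.3% inhibition
```

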