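---
title: "Inferring protein-metabolite interactions from co-fractionation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protein-metabolite interactions from co-fractionation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofracpmi)
```

## The measurement and the inference problem

Co-fractionation mass spectrometry probes molecular interactions without
baits: a native cell lysate is separated by size-exclusion chromatography
(SEC), the fractions are analysed in parallel by proteomics and
metabolomics, and molecules that are physically associated travel
together, producing matching elution profiles. A metabolite bound to a
protein appears in high-molecular-weight fractions where a free small
molecule could not elute; a protein engaged in a complex elutes at an
apparent mass far above its monomeric mass. The inference problem is to
turn two fraction-by-feature intensity tables into a thresholded
protein-metabolite interaction (PMI) network with an estimate of its
false discovery rate, and to corroborate targets with orthogonal
evidence (thermal proteome profiling and affinity purification) and
targeted binding assays.

`cofracpmi` implements that chain end to end, together with a
ground-truthed synthetic generator for every stage, so each statistical
component can be validated against planted truth.

## Elution model and deconvolution

Profiles are modelled as sums of Gaussian peaks in fraction coordinates.
The default peak width is $\sigma = 1.5$ fractions, matching the visual
width of well-behaved SEC peaks on a 48-fraction gradient; it is a
configurable parameter of the generator, and nothing in the fitting
assumes it. Each feature's replicate profiles are first normalized to
their own maximum (intensities are only comparable within a feature),
averaged, and re-normalized.

Deconvolution — splitting a multi-modal profile into single peaks, each
treated downstream as an independent molecular species — uses standard
chromatographic peak picking:

* moving-average smoothing, window 3 fractions;
* candidate apexes = local maxima with topographic prominence at least
  5% of the profile maximum;
* a minimum apex separation of 2 fractions (of two closer apexes the
  taller wins — a deterministic tie-break);
* region boundaries at the minima between adjacent apexes, support
  trimmed where the profile falls below 1% of the regional maximum;
* a least-squares Gaussian fit per region (`minpack.lm::nlsLM`);
* filters: support of at least 3 fractions and fitted
  $\hat\sigma \ge 0.5$ fractions. A candidate whose fit does not
  converge is dropped with a logged message, never a pipeline failure.

A fitted peak is kept only when its apex recurs (within one fraction) in
at least 2 of 3 replicates. This merge rule — deconvolve the mean
profile, gate by replicate apex support — was a genuinely open design
choice; it is cheap, deterministic, and on the synthetic benchmark it
removes noise peaks without costing planted ones. All thresholds are
exposed in `peak_params()`.

## Mass calibration and oligomeric state

Reference proteins of known mass define a log-linear calibration,
$\log_{10}(\mathrm{mass}) = a \cdot \mathrm{fraction} + b$, fitted by
least squares; the slope must be negative (mass decreases along the
elution) and predictions outside the reference span are flagged as
extrapolated. The default synthetic gradient spans 5.2 MDa at the first
protein-containing fraction to 20 kDa at the 38th. A peak's apparent
mass divided by the protein's monomeric mass gives the oligomeric state
ratio; a ratio above 1.5 calls the peak part of a multimeric assembly.
The 1.5 cut-off leaves room for calibration error around a monomer
(ratio 1) while still catching dimers (ratio 2): at the default
calibration one fraction corresponds to a mass factor of about 1.16, so
the decision margin of $\log_{10}(2/1.5) \approx 1.9$ fractions is
comfortably larger than the apex error observed at 15% intensity noise.
Calibration is done on fraction indices by default; an elution-volume
abscissa works identically if provided.

## Co-elution scoring, threshold choice and FDR

Every metabolite peak whose apex lies inside the protein-containing
window is correlated (Pearson) with every protein peak in the window,
using the fitted single-peak profiles restricted to that window. Pairs
with fewer than three nonzero fractions or zero variance are undefined
and excluded — not scored zero. A feature pair is summarized by the
maximum correlation over its peak pairs: a single co-eluting peak pair
is the evidence of interest, and averaging across unrelated peak pairs
would dilute it.

The operating threshold is chosen on a ROC curve: the true-positive rate
comes from a list of known interactions restricted to detected features,
the false-positive rate from a permutation null — per iteration, as many
random metabolite-protein pairs as the known set holds, drawn without
replacement and excluding known pairs, each given its feature-level
score (pairs never co-scored take the floor of $-1$). One hundred
iterations is the default. At the threshold $t^\ast$ (default 0.7) the
false discovery rate is estimated as

$$\widehat{FDR}(t^\ast) = \frac{\bar m_{null}}{\bar m_{null} + m_{true}},$$

where $m_{true}$ counts known pairs at or above $t^\ast$ and
$\bar m_{null}$ is the mean per-iteration count of null pairs at or
above it. This is the natural like-for-like reading of a recovery
experiment — both counts refer to equally sized pair sets — and the same
counts give the fold-enrichment over chance, $m_{true}/\bar m_{null}$.
With no null positives the enrichment is reported as infinite and
flagged; a 0/0 FDR is reported as undefined rather than 0.

Correlation magnitudes above threshold are deliberately treated as
qualitative. The network retains scores for provenance, but nothing in
the package ranks edges by them: co-elution of deconvolved peaks, not
the size of the correlation, is the evidence.

## The synthetic generator and what passing tests mean

`simulate_fractionation()` emulates the study conditions the pipeline is
benchmarked under: 48 fractions of which the first 38 contain proteins,
three biological replicates, multiplicative lognormal intensity noise at
a configurable coefficient of variation (benchmark default 15%, a free
parameter of the simulation since per-feature MS noise is not otherwise
pinned down), one or two Gaussian peaks per protein, planted complexes
whose members share a peak at the fraction implied by the complex mass,
and planted PMIs whose metabolite receives a bound peak exactly
co-located with a dedicated partner peak plus a free-pool peak beyond
the protein span (free metabolites elute late; the scoring window
excludes them). Intensities below a configurable floor can be censored
to zero to mimic MS missingness; the benchmark leaves censoring off so
that every failure mode observed in testing is attributable to noise,
not to missingness.

Two structural choices keep the planted truth *identifiable*, and they
are the main caveat when extrapolating from green tests to real data:

* **Grouped interactions.** Planted PMIs are grouped — one planted
  metabolite co-elutes with up to four partner proteins at a single
  center. Single metabolite peaks matching several protein partners are
  exactly what co-fractionation data show for cofactor-like molecules,
  and grouping keeps the number of distinct planted neighbourhoods small
  enough to separate on a 38-fraction gradient.
* **Clearance.** Two Gaussian peaks of width 1.5 correlate above 0.7
  whenever their centers are within about 1.6 fractions. A random
  200-protein background therefore *necessarily* produces chance
  co-elutions that no correlation-based method could reject — such
  pairs are not a meaningful test of the method. The generator keeps
  unrelated protein peaks at least `min_clearance` (default 2.5)
  fractions away from planted metabolite centers, and planted/complex
  centers mutually separated by 3.

Consequently, the benchmark measures noise robustness, replicate
handling, deconvolution accuracy and the correctness of the scoring and
FDR machinery — not the method's behaviour under elution crowding. On
real data, chance co-elution is an irreducible part of the reported FDR,
which is precisely why the threshold is chosen on a ROC curve against a
measured null rather than fixed a priori. The generator also does not
simulate raw spectra, retention-time drift, isotope patterns, peak-width
heterogeneity or correlated (batch) noise.

## Thermal proteome profiling

Melting curves follow the standard sigmoid
$f(T) = (1-p)/(1+e^{\,b - a/T}) + p$ with plateau $p$ bounded in
$[0, 0.3]$ by default (typical high-temperature plateaus) and midpoint
$a/b$. Fits use a small deterministic multi-start ladder around a
data-driven start, so results are reproducible without consuming random
numbers. A treatment effect is tested by the nested-model F statistic on
residual sums of squares — one shared curve (3 parameters) against
per-condition curves (6) — with *theoretical* parameter-counting degrees
of freedom, $d_1 = 3$, $d_2 = n_{obs} - 6$. The per-condition fits are
started from the pooled solution, which guarantees
$RSS_1 \le RSS_0$ structurally. The empirically rescaled degrees of
freedom used by some curve-testing implementations are intentionally out
of scope; the theoretical F is well calibrated on the package's own null
simulations (rejection rate close to 0.05 at $\alpha = 0.05$ over 300
null proteins with noise s.d. 0.02), which the test suite verifies.
Benjamini-Hochberg adjustment runs across all proteins with convergent
fits in both conditions.

## Affinity purification and evidence tiers

"Significantly enriched" is operationalized — the underlying assay
reports no test — as a Welch two-sample t-test of bait-bead versus
control-bead log2 intensities, BH-adjusted $q \le 0.05$ and log2
fold-change $\ge 1$, in at least one of the two coupling orientations
(N- or C-terminal ligand coupling). The union rule is the default
because a binding epitope blocked by one coupling chemistry should not
veto the other; an intersection mode is available. The three evidence
arms — SEC co-elution, AP enrichment, TPP hits — are intersected into
per-protein support counts: support of at least 2 defines the
interactome, 3 of 3 the high-confidence tier.

## Binding and enzymology fits

Dose-response curves are fitted with the quadratic 1:1 binding isotherm
(the microscale-thermophoresis convention, with the labeled-target
concentration fixed), which reduces to the hyperbola $L/(K_d+L)$ when
the target is at trace concentration; a hyperbolic mode is available.
A "no measurable interaction" outcome is operationalized as any of:
non-convergence, $\hat K_d$ above the top of the dilution ladder, or a
fitted amplitude below a signal floor. Reaction rates are least-squares
slopes of product versus time inside a user-chosen linear window (no
automatic linearity detection); percent inhibition and isotope-labeling
fraction intensities (enrichment multiplied by total intensity, log2
ratios to the baseline time point) are exact arithmetic.

## Problem sizes and reproducibility

The test-suite and acceptance sizes are the package's own validation
conditions: the standard SEC benchmark (200 proteins, 30 metabolites, 20
planted PMIs, 3 replicates, 15% CV), 500 two-peak profiles for
deconvolution accuracy, 300 null and 150 shifted proteins for the curve
test, and 100 simulated dose-response ladders for $K_d$ recovery. Every
stochastic step takes an explicit seed, generators restore the caller's
RNG state, and two runs of `run_demo()` with the same seed produce
byte-identical result tables.

## Known limitations

* Scores are computed on deconvolved single-peak profiles; a raw
  whole-profile mode exists only implicitly (correlate the normalized
  mean profiles yourself) rather than behind a pipeline flag.
* The clearance-based benchmark does not measure behaviour under peak
  crowding (see above); reported FDRs on real data will be higher than
  benchmark FDRs.
* The curve test's theoretical degrees of freedom assume approximately
  Gaussian, homoscedastic residuals; heavy-tailed proteome-wide noise
  would require the permutation alternative, which is not implemented.
* Apparent masses assume globular elution behaviour through a log-linear
  calibration; strongly non-globular species violate it.
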