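Package: cofracpmi
Title: Co-Fractionation Mass Spectrometry Analysis of Protein-Metabolite
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring protein-metabolite interactions from
    size-exclusion co-fractionation mass spectrometry. Elution profiles
    are normalized, averaged across replicates and deconvolved into
    single Gaussian peaks; apparent masses are assigned from a
    reference-protein calibration curve and oligomeric states classified.
    Metabolite and protein peaks are scored for co-elution by Pearson
    correlation, with a permutation null, ROC-based threshold selection,
    false discovery rate estimation and network construction. Orthogonal
    evidence from thermal proteome profiling (nested-model F-tests on
    melting curves) and affinity-purification enrichment is intersected
    into tiered target sets, and targeted validation fits (quadratic
    binding isotherms, reaction rates, isotope-labeling arithmetic) are
    included, together with a ground-truthed synthetic data generator
    for every stage.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
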