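# Molecular-weight calibration and oligomeric-state classification.

#' Fit a molecular-weight calibration curve
#'
#' Least-squares line on (fraction, log10 mass) over a set of
#' reference-protein points. Mass must decrease along the elution, so the
#' fitted slope is required to be negative.
#'
#' @param refs Data frame with columns `fraction` (index or elution
#'   volume) and `mass_da`.
#' @return List of class `calibration_curve`: `slope`, `intercept`
#'   (log10-mass units), `r_squared`, `fraction_range`, `refs`.
#' @export
fit_calibration <- function(refs) {
  stopifnot(is.data.frame(refs), all(c("fraction", "mass_da") %in% names(refs)))
  refs <- refs[stats::complete.cases(refs[c("fraction", "mass_da")]), ]
  if (nrow(refs) < 2 || length(unique(refs$fraction)) < 2) {
    stop("calibration requires at least 2 reference points at distinct fractions")
  }
  if (any(refs$mass_da <= 0)) stop("reference masses must be positive")
  fit <- stats::lm(log10(mass_da) ~ fraction, data = refs)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("calibration slope is non-negative; mass must decrease with fraction index")
  }
  tss <- sum((log10(refs$mass_da) - mean(log10(refs$mass_da)))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    fraction_range = range(refs$fraction),
    refs = refs
  ), class = "calibration_curve")
}

#' Apparent mass of elution peaks from a calibration curve
#'
#' Back-transforms fitted peak centers through the log-linear calibration:
#' `mass = 10^(slope * fraction + intercept)`. Peaks eluting outside the
#' range covered by the reference proteins are still converted but flagged
#' as extrapolated.
#'
#' @param fraction Numeric vector of peak centers (fractional indices).
#' @param cal A `calibration_curve`.
#' @return Data frame with columns `mass_da` and `extrapolated`.
#' @export
apparent_mass <- function(fraction, cal) {
  stopifnot(inherits(cal, "calibration_curve"), is.numeric(fraction))
  data.frame(
    mass_da = 10^(cal$slope * fraction + cal$intercept),
    extrapolated = fraction < cal$fraction_range[1] | fraction > cal$fraction_range[2]
  )
}

#' Attach apparent masses to a peak set
#'
#' @param peak_set A `peak_set` from [deconvolve_dataset()].
#' @param cal A `calibration_curve`.
#' @return The `peak_set` with `apparent_mass_da` and `mass_extrapolated`
#'   columns added to its peak table.
#' @export
add_apparent_mass <- function(peak_set, cal) {
  stopifnot(inherits(peak_set, "peak_set"))
  am <- apparent_mass(peak_set$peaks$mu, cal)
  peak_set$peaks$apparent_mass_da <- am$mass_da
  peak_set$peaks$mass_extrapolated <- am$extrapolated
  peak_set
}

#' Classify the oligomeric state of protein peaks
#'
#' The oligomeric state ratio is the apparent (elution-derived) mass of a
#' peak divided by the protein's theoretical monomeric mass; a ratio above
#' the threshold (default 1.5) classifies the peak as part of a multimeric
#' assembly. Entries without a monomeric mass are skipped and reported via
#' the `n_skipped` attribute.
#'
#' @param protein_id Character vector of protein identifiers.
#' @param apparent_mass_da Apparent masses (Da) of the peaks.
#' @param monomeric_mass_da Theoretical monomeric masses (Da); `NA` skips.
#' @param threshold Ratio above which a peak is called multimeric.
#' @return Data frame (`protein_id`, `apparent_mass_da`,
#'   `monomeric_mass_da`, `ratio`, `multimeric`) with attribute
#'   `n_skipped`.
#' @export
classify_oligomeric <- function(protein_id, apparent_mass_da, monomeric_mass_da,
                                threshold = 1.5) {
  stopifnot(length(protein_id) == length(apparent_mass_da),
            length(protein_id) == length(monomeric_mass_da),
            all(apparent_mass_da > 0, na.rm = TRUE))
  if (any(monomeric_mass_da <= 0, na.rm = TRUE)) {
    stop("monomeric masses must be positive")
  }
  ok <- !is.na(monomeric_mass_da) & !is.na(apparent_mass_da)
  out <- data.frame(
    protein_id = protein_id[ok],
    apparent_mass_da = apparent_mass_da[ok],
    monomeric_mass_da = monomeric_mass_da[ok]
  )
  out$ratio <- out$apparent_mass_da / out$monomeric_mass_da
  out$multimeric <- out$ratio > threshold
  attr(out, "n_skipped") <- sum(!ok)
  out
}
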