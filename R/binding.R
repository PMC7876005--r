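# Targeted validation assays: dose-response binding fits, reaction rates,
# percent inhibition and isotope-labeling arithmetic.

#' Quadratic 1:1 binding isotherm
#'
#' Fraction-bound response for a labeled target at fixed concentration
#' `pt` titrated with ligand `l`:
#' `response = f0 + (f1 - f0) * ((kd + pt + l) - sqrt((kd + pt + l)^2 - 4 pt l)) / (2 pt)`.
#' This is the microscale-thermophoresis convention; it reduces to the
#' hyperbola `l / (kd + l)` when `pt << kd` (ligand depletion negligible).
#'
#' @param l Ligand concentrations (molar).
#' @param kd Dissociation constant (molar).
#' @param pt Labeled-target concentration (molar).
#' @param f0,f1 Response asymptotes (unbound, saturated).
#' @return Numeric response vector.
#' @export
binding_response <- function(l, kd, pt, f0 = 0, f1 = 1) {
  s <- kd + pt + l
  frac <- (s - sqrt(pmax(s^2 - 4 * pt * l, 0))) / (2 * pt)
  f0 + (f1 - f0) * frac
}

#' Simulate a dose-response (MST-style) binding curve
#'
#' A serial-dilution ladder with additive Gaussian noise scaled to the
#' response amplitude.
#'
#' @param kd,pt True dissociation constant and target concentration
#'   (molar).
#' @param n_points Ladder length (default 16).
#' @param top Highest ligand concentration; default `128 * kd`, so a
#'   16-point 2-fold ladder brackets the Kd by orders of magnitude.
#' @param dilution Dilution factor between steps (default 2).
#' @param f0,f1 Response asymptotes.
#' @param noise_frac Noise standard deviation as a fraction of
#'   `|f1 - f0|`.
#' @param n_replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return List with `data` (`conc`, `response`, `replicate`) and `truth`.
#' @export
simulate_binding_curve <- function(kd, pt, n_points = 16L, top = 128 * kd,
                                   dilution = 2, f0 = 0, f1 = 1,
                                   noise_frac = 0.02, n_replicates = 1L,
                                   seed = 1L) {
  stopifnot(kd > 0, pt > 0, n_points >= 4, top > 0, dilution > 1)
  l <- top / dilution^(seq_len(n_points) - 1)
  with_seed(seed, {
    data <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      mu <- binding_response(l, kd, pt, f0, f1)
      data.frame(conc = l, replicate = r,
                 response = mu + stats::rnorm(n_points, 0, noise_frac * abs(f1 - f0)))
    }))
    list(data = data, truth = list(kd = kd, pt = pt, f0 = f0, f1 = f1))
  })
}

#' Fit a dissociation constant to a dose-response curve
#'
#' Least-squares fit of the quadratic 1:1 binding isotherm (or its
#' hyperbolic limit) to a dose-response ladder. The fit is flagged
#' unreliable when it does not converge, when the estimated Kd exceeds the
#' highest ligand concentration of the ladder, or when the fitted
#' amplitude falls below `min_amplitude` - the operational reading of a
#' "no interaction measurable" outcome.
#'
#' @param conc Ligand concentrations (molar).
#' @param response Measured responses (replicates stacked).
#' @param pt Labeled-target concentration (molar); required for the
#'   quadratic model.
#' @param model `"quadratic"` (default) or `"hyperbolic"`.
#' @param min_amplitude Smallest `|f1 - f0|` considered a real signal.
#' @return List of class `kd_fit`: `kd`, `kd_se`, `f0`, `f1`, `rss`,
#'   `converged`, `unreliable`, `reason`.
#' @export
fit_kd <- function(conc, response, pt = NULL,
                   model = c("quadratic", "hyperbolic"),
                   min_amplitude = 0.05) {
  model <- match.arg(model)
  stopifnot(length(conc) == length(response), all(conc > 0), length(conc) >= 4)
  if (model == "quadratic" && (is.null(pt) || pt <= 0)) {
    stop("the quadratic isotherm requires the labeled-target concentration pt")
  }
  df <- data.frame(l = conc, y = response)
  lo_resp <- mean(df$y[df$l <= stats::quantile(df$l, 0.25)])
  hi_resp <- mean(df$y[df$l >= stats::quantile(df$l, 0.75)])
  kd0 <- exp(mean(log(range(conc))))
  starts <- list(
    list(kd = kd0, f0 = lo_resp, f1 = hi_resp),
    list(kd = kd0 / 10, f0 = lo_resp, f1 = hi_resp),
    list(kd = kd0 * 10, f0 = lo_resp, f1 = hi_resp)
  )
  formula <- if (model == "quadratic") {
    y ~ f0 + (f1 - f0) * ((kd + pt + l) - sqrt((kd + pt + l)^2 - 4 * pt * l)) / (2 * pt)
  } else {
    y ~ f0 + (f1 - f0) * l / (kd + l)
  }
  env <- list2env(list(pt = pt), parent = environment())
  span <- range(df$y)
  pad <- diff(span) + 1
  best <- NULL
  for (s in starts) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      formula, data = df, start = s,
      lower = c(kd = min(conc) / 1e6, f0 = span[1] - pad, f1 = span[1] - pad),
      upper = c(kd = max(conc) * 1e6, f0 = span[2] + pad, f1 = span[2] + pad),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit)))["kd"], error = function(e) NA_real_)
      best <- list(kd = unname(cf["kd"]), kd_se = unname(se),
                   f0 = unname(cf["f0"]), f1 = unname(cf["f1"]),
                   rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) {
    best <- list(kd = NA_real_, kd_se = NA_real_, f0 = NA_real_, f1 = NA_real_,
                 rss = NA_real_, converged = FALSE)
  }
  reason <- NULL
  if (!best$converged) {
    reason <- "fit did not converge"
  } else if (best$kd > max(conc)) {
    reason <- "estimated Kd beyond the top of the dilution ladder"
  } else if (abs(best$f1 - best$f0) < min_amplitude) {
    reason <- "response amplitude below the signal floor"
  }
  best$unreliable <- !is.null(reason)
  best$reason <- reason %||% NA_character_
  structure(best, class = "kd_fit")
}

#' Affinity fold-change between two dissociation constants
#'
#' @param kd_reference,kd_treatment Dissociation constants (same units,
#'   both positive).
#' @return `kd_reference / kd_treatment`; values above 1 mean the
#'   treatment increased affinity.
#' @export
affinity_fold_change <- function(kd_reference, kd_treatment) {
  stopifnot(kd_reference > 0, kd_treatment > 0)
  kd_reference / kd_treatment
}

#' Initial reaction rate from a product progress curve
#'
#' Slope of the least-squares line of product versus time within the
#' user-specified linear window.
#'
#' @param time Time points (minutes, ascending).
#' @param product Product amounts.
#' @param window Length-2 time span to fit within (default: all points).
#' @return List: `rate` (product units per minute), `r_squared`, `n`.
#' @export
reaction_rate <- function(time, product, window = range(time)) {
  stopifnot(length(time) == length(product), !is.unsorted(time))
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 3) stop("at least 3 points are required within the rate window")
  fit <- stats::lm(product[keep] ~ time[keep])
  tss <- sum((product[keep] - mean(product[keep]))^2)
  list(rate = unname(stats::coef(fit)[2]),
       r_squared = if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss,
       n = sum(keep))
}

#' Percent inhibition of a reaction rate
#'
#' @param rate_treated,rate_control Reaction rates; the control rate must
#'   be positive.
#' @return Percent inhibition, `100 * (1 - rate_treated / rate_control)`.
#' @export
percent_inhibition <- function(rate_treated, rate_control) {
  if (!is.numeric(rate_control) || any(rate_control <= 0)) {
    stop("control rate must be positive")
  }
  100 * (1 - rate_treated / rate_control)
}

#' Isotope-labeling fraction intensities over a time course
#'
#' The labeled fraction intensity of a metabolite is its enrichment level
#' multiplied by its relative (total) intensity. Enrichment may be given
#' as a fraction in `[0, 1]` or as percent in `[0, 100]`; percentages are
#' detected (any value above 1) and converted.
#'
#' @param total Total metabolite intensities.
#' @param enrichment Labeled-isotope enrichment per time point.
#' @param times Time points (minutes).
#' @return Data frame `time`, `total_intensity`, `enrichment`
#'   (as a fraction), `fraction_intensity`, with the unit convention
#'   recorded in the `enrichment_unit` attribute.
#' @export
labeling_series <- function(total, enrichment, times) {
  if (length(total) != length(enrichment) || length(total) != length(times)) {
    stop("total, enrichment and times must have equal length")
  }
  if (any(enrichment < 0) || any(enrichment > 100)) {
    stop("enrichment must lie in [0, 1] or [0, 100] percent")
  }
  unit <- if (any(enrichment > 1)) "percent" else "fraction"
  frac <- if (unit == "percent") enrichment / 100 else enrichment
  structure(
    data.frame(time = times, total_intensity = total, enrichment = frac,
               fraction_intensity = frac * total),
    enrichment_unit = unit
  )
}

#' Log2 ratios to a baseline time point
#'
#' @param values Positive measurements over a time course.
#' @param t0_index Index of the baseline time point (default 1); its value
#'   must be positive.
#' @return `log2(value / baseline)` per time point; non-positive later
#'   values are reported as `NA` (missing).
#' @export
log2_ratio_to_baseline <- function(values, t0_index = 1L) {
  stopifnot(is.numeric(values), t0_index >= 1, t0_index <= length(values))
  baseline <- values[t0_index]
  if (is.na(baseline) || baseline <= 0) stop("baseline value must be positive")
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values) & values > 0
  out[ok] <- log2(values[ok] / baseline)
  out
}
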