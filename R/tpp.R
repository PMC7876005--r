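# Thermal proteome profiling: melting-curve fits and the nested-model
# F-test on response curves.
#
# A protein's soluble fraction after heating, normalized to the lowest
# temperature, follows the standard melting sigmoid
#   f(T) = (1 - p) / (1 + exp(b - a/T)) + p
# with plateau p. Ligand binding shifts thermal stability, so the test
# compares one shared curve for vehicle and treatment (null) against
# per-condition curves (alternative) through an F statistic on residual
# sums of squares, with theoretical parameter-counting degrees of
# freedom. This tests differences in whole curves rather than differences
# in a derived melting temperature.

#' Melting sigmoid
#'
#' @param temperature Temperature in degrees Celsius (> 0).
#' @param a Scale parameter (degC units); the midpoint lies at `a / b`.
#' @param b Steepness parameter (unitless).
#' @param p High-temperature plateau in `[0, 1)`.
#' @return Relative soluble fraction.
#' @export
melt_sigmoid <- function(temperature, a, b, p) {
  (1 - p) / (1 + exp(b - a / temperature)) + p
}

# Deterministic multi-start table: the data-driven start plus fixed
# relative jitters, so fits are reproducible without touching the RNG.
melt_starts <- function(temperature, value, p_max) {
  t_mid <- temperature[which.min(abs(value - (max(value) + min(value)) / 2))]
  b0 <- 10
  base <- c(a = b0 * t_mid, b = b0, p = min(max(min(value), 0.01), p_max - 0.01))
  jit <- rbind(c(1, 1, 1), c(0.9, 0.8, 1.5), c(1.1, 1.2, 0.5),
               c(1, 0.6, 1), c(1, 1.5, 1))
  lapply(seq_len(nrow(jit)), function(i) {
    s <- base * jit[i, ]
    s["p"] <- min(max(s["p"], 0), p_max - 1e-3)
    as.list(s)
  })
}

#' Fit a melting curve
#'
#' Least-squares fit of the melting sigmoid to (temperature, fold-change)
#' observations, pooling any replicates, with bounded plateau and a small
#' deterministic multi-start ladder; the best converged fit wins.
#'
#' @param temperature,value Numeric vectors (at least 6 points are
#'   expected to span the sigmoid transition).
#' @param p_max Upper bound on the plateau (default 0.3, a typical TPP
#'   plateau range).
#' @param extra_starts Optional list of extra start values (named lists
#'   with `a`, `b`, `p`), tried in addition to the built-in ladder.
#' @return List of class `sigmoid_fit`: `a`, `b`, `p`, `rss`, `converged`,
#'   `n`.
#' @export
fit_melting_curve <- function(temperature, value, p_max = 0.3, extra_starts = NULL) {
  stopifnot(length(temperature) == length(value), length(value) >= 6,
            all(temperature > 0))
  df <- data.frame(temperature = temperature, value = value)
  best <- NULL
  starts <- c(melt_starts(temperature, value, p_max), extra_starts %||% list())
  for (s in starts) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      value ~ (1 - p) / (1 + exp(b - a / temperature)) + p,
      data = df, start = s,
      lower = c(a = 1, b = 0.1, p = 0),
      upper = c(a = 1e4, b = 100, p = p_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(a = unname(cf["a"]), b = unname(cf["b"]), p = unname(cf["p"]),
                   rss = rss, converged = TRUE, n = nrow(df))
    }
  }
  if (is.null(best)) {
    best <- list(a = NA_real_, b = NA_real_, p = NA_real_, rss = NA_real_,
                 converged = FALSE, n = nrow(df))
  }
  structure(best, class = "sigmoid_fit")
}

#' Nested-model F-test for a treatment effect on a melting curve
#'
#' The null model fits one sigmoid to the pooled vehicle and treatment
#' observations (RSS0); the alternative fits one sigmoid per condition
#' (RSS1 = sum of the two condition RSS, which cannot exceed RSS0 because
#' the per-condition fits are started from the pooled solution). The
#' statistic is
#' `F = ((RSS0 - RSS1) / d1) / (RSS1 / d2)` with `d1` the difference in
#' parameter count (3) and `d2 = n_obs - 6`, referred to the F
#' distribution. Degrees of freedom are theoretical (parameter counting).
#'
#' @param vehicle,treatment Data frames with columns `temperature`,
#'   `value` (replicate observations stacked).
#' @param p_max Plateau bound passed to [fit_melting_curve()].
#' @return List of class `nparc_result`: `rss0`, `rss1`, `f`, `df1`,
#'   `df2`, `p_value`, `converged`.
#' @export
nparc_test <- function(vehicle, treatment, p_max = 0.3) {
  stopifnot(all(c("temperature", "value") %in% names(vehicle)),
            all(c("temperature", "value") %in% names(treatment)))
  n_obs <- nrow(vehicle) + nrow(treatment)
  df1 <- 3L
  df2 <- n_obs - 6L
  if (df2 <= 0) stop("too few observations for the per-condition model")
  pooled <- fit_melting_curve(c(vehicle$temperature, treatment$temperature),
                              c(vehicle$value, treatment$value), p_max = p_max)
  if (!pooled$converged) {
    return(structure(list(rss0 = NA_real_, rss1 = NA_real_, f = NA_real_,
                          df1 = df1, df2 = df2, p_value = NA_real_,
                          converged = FALSE), class = "nparc_result"))
  }
  start0 <- list(list(a = pooled$a, b = pooled$b, p = pooled$p))
  fv <- fit_melting_curve(vehicle$temperature, vehicle$value, p_max = p_max,
                          extra_starts = start0)
  ft <- fit_melting_curve(treatment$temperature, treatment$value, p_max = p_max,
                          extra_starts = start0)
  if (!fv$converged || !ft$converged) {
    return(structure(list(rss0 = pooled$rss, rss1 = NA_real_, f = NA_real_,
                          df1 = df1, df2 = df2, p_value = NA_real_,
                          converged = FALSE), class = "nparc_result"))
  }
  rss1 <- fv$rss + ft$rss
  f <- max(0, ((pooled$rss - rss1) / df1) / (rss1 / df2))
  structure(list(rss0 = pooled$rss, rss1 = rss1, f = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 converged = TRUE), class = "nparc_result")
}

#' Screen a TPP dataset for treatment-affected melting curves
#'
#' Runs [nparc_test()] per protein and adjusts p-values across the tested
#' set (all proteins with convergent fits in both conditions) by
#' Benjamini-Hochberg.
#'
#' @param tpp_data Long-format data frame: `protein_id`, `condition`
#'   (`"vehicle"` / `"treatment"`), `replicate`, `temperature`, `value`.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param p_max Plateau bound.
#' @return Data frame, one row per protein: RSS components, `f`,
#'   `p_value`, `q_value`, `significant`, `converged`.
#' @export
nparc_screen <- function(tpp_data, alpha = 0.05, p_max = 0.3) {
  stopifnot(all(c("protein_id", "condition", "temperature", "value") %in% names(tpp_data)),
            all(tpp_data$condition %in% c("vehicle", "treatment")))
  res <- do.call(rbind, lapply(split(tpp_data, tpp_data$protein_id), function(d) {
    v <- d[d$condition == "vehicle", c("temperature", "value")]
    tr <- d[d$condition == "treatment", c("temperature", "value")]
    r <- nparc_test(v, tr, p_max = p_max)
    data.frame(protein_id = d$protein_id[1], rss0 = r$rss0, rss1 = r$rss1,
               f = r$f, df1 = r$df1, df2 = r$df2, p_value = r$p_value,
               converged = r$converged)
  }))
  rownames(res) <- NULL
  res$q_value <- NA_real_
  tested <- res$converged & !is.na(res$p_value)
  res$q_value[tested] <- bh_adjust(res$p_value[tested])
  res$significant <- !is.na(res$q_value) & res$q_value <= alpha
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted (q) values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
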