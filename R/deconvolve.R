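# Elution-peak picking and Gaussian deconvolution.
#
# Most proteins and metabolites elute with more than one maximum; profiles
# are therefore split into single peaks, each treated downstream as an
# independent molecular species/state. The procedure is standard
# chromatographic peak picking: light smoothing, prominence-filtered local
# maxima, region boundaries at inter-apex minima, and a per-region Gaussian
# least-squares fit.

#' Peak-picking and fitting parameters
#'
#' @param smooth_window Moving-average window (fractions) applied before
#'   apex detection; the Gaussian fit itself uses the unsmoothed profile.
#' @param min_prominence Minimum apex prominence, as a proportion of the
#'   profile maximum.
#' @param min_apex_separation Minimum distance between retained apexes
#'   (fractions); of two closer apexes the smaller is discarded.
#' @param min_support Minimum peak support width in fractions; narrower
#'   candidates are dropped.
#' @param min_sigma Minimum fitted Gaussian width (fractions); narrower
#'   fits are treated as noise spikes and dropped.
#' @param tail_fraction Support extends around the apex while the profile
#'   stays above this proportion of the regional maximum.
#' @return List of class `peak_params`.
#' @export
peak_params <- function(smooth_window = 3L,
                        min_prominence = 0.05,
                        min_apex_separation = 2,
                        min_support = 3L,
                        min_sigma = 0.5,
                        tail_fraction = 0.01) {
  stopifnot(smooth_window >= 1, min_prominence >= 0, min_apex_separation >= 1,
            min_support >= 2, min_sigma > 0, tail_fraction >= 0, tail_fraction < 1)
  structure(list(smooth_window = as.integer(smooth_window),
                 min_prominence = min_prominence,
                 min_apex_separation = min_apex_separation,
                 min_support = as.integer(min_support),
                 min_sigma = min_sigma,
                 tail_fraction = tail_fraction),
            class = "peak_params")
}

# Local maxima of a numeric vector (strict on the left, non-strict on the
# right so plateau onsets count once); boundary points qualify.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 2) return(integer())
  left <- c(TRUE, y[-1] > y[-n])
  right <- c(y[-n] >= y[-1], TRUE)
  which(left & right & y > 0)
}

# Topographic prominence of each candidate apex.
apex_prominence <- function(y, apexes) {
  vapply(apexes, function(a) {
    h <- y[a]
    left_min <- h
    i <- a - 1L
    while (i >= 1L) {
      if (y[i] > h) break
      left_min <- min(left_min, y[i])
      i <- i - 1L
    }
    right_min <- h
    i <- a + 1L
    while (i <= length(y)) {
      if (y[i] > h) break
      right_min <- min(right_min, y[i])
      i <- i + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

# Candidate apexes after smoothing, prominence filtering and separation
# enforcement. Exposed internally so replicate-reproducibility checks can
# reuse it.
pick_apexes <- function(y, params) {
  ys <- moving_average(y, params$smooth_window)
  apexes <- local_maxima(ys)
  if (!length(apexes)) return(integer())
  prom <- apex_prominence(ys, apexes)
  keep <- prom >= params$min_prominence * max(ys)
  apexes <- apexes[keep]
  if (length(apexes) <= 1) return(apexes)
  # greedy: keep taller apexes, drop any within the minimum separation
  ord <- order(ys[apexes], decreasing = TRUE)
  kept <- integer()
  for (a in apexes[ord]) {
    if (!length(kept) || all(abs(a - kept) >= params$min_apex_separation)) {
      kept <- c(kept, a)
    }
  }
  sort(kept)
}

fit_gaussian_region <- function(x, y, apex, sigma0 = 1.5) {
  df <- data.frame(x = x, y = y)
  start <- list(A = max(y), mu = apex, s = sigma0)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
    data = df, start = start,
    lower = c(A = 1e-8, mu = min(x) - 1, s = 0.1),
    upper = c(A = 2 * max(y) + 1, mu = max(x) + 1, s = diff(range(x)) + 2),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  est <- stats::coef(fit)
  list(A = unname(est["A"]), mu = unname(est["mu"]), sigma = unname(est["s"]),
       rss = sum(stats::resid(fit)^2))
}

#' Deconvolve an elution profile into single Gaussian peaks
#'
#' Splits a (max-normalized) profile into single peaks: candidate apexes
#' are local maxima of the lightly smoothed profile passing a prominence
#' filter and a minimum-separation rule; region boundaries fall at the
#' minima between adjacent apexes; each region is fitted by least squares
#' with a Gaussian. Candidates whose fit fails to converge, whose support
#' is narrower than `min_support` fractions, or whose fitted width falls
#' below `min_sigma` are dropped (logged via [message()]), not errors.
#'
#' @param profile Normalized intensity vector (see [normalize_profile()]).
#' @param params A [peak_params()] list.
#' @return List of class `deconvolution` with `peaks` (data frame: `peak`,
#'   `apex_fraction`, `mu`, `sigma`, `amplitude`, `support_lo`,
#'   `support_hi`, `rss`), `profiles` (matrix, one fitted single-peak
#'   profile per row: the fitted Gaussian inside the support, 0 outside)
#'   and `residual` (root-mean-square difference between the profile and
#'   the sum of fitted peaks).
#' @export
deconvolve <- function(profile, params = peak_params()) {
  y <- as.numeric(profile)
  n <- length(y)
  empty <- list(
    peaks = data.frame(peak = integer(), apex_fraction = integer(),
                       mu = numeric(), sigma = numeric(), amplitude = numeric(),
                       support_lo = integer(), support_hi = integer(), rss = numeric()),
    profiles = matrix(numeric(), nrow = 0, ncol = n),
    residual = 0
  )
  class(empty) <- "deconvolution"
  if (n < 3 || max(y) == 0) return(empty)

  apexes <- pick_apexes(y, params)
  if (!length(apexes)) return(empty)

  # region boundaries at the minima between adjacent apexes
  bounds <- c(1L, vapply(seq_len(length(apexes) - 1L), function(k) {
    seg <- apexes[k]:apexes[k + 1]
    seg[which.min(moving_average(y, params$smooth_window)[seg])]
  }, integer(1)), n)

  rows <- list(); profs <- list(); dropped <- character()
  for (k in seq_along(apexes)) {
    region <- bounds[k]:bounds[k + 1]
    apex <- apexes[k]
    # contiguous support around the apex above the tail threshold
    thr <- params$tail_fraction * max(y[region])
    lo <- apex
    while (lo > min(region) && y[lo - 1L] > thr) lo <- lo - 1L
    hi <- apex
    while (hi < max(region) && y[hi + 1L] > thr) hi <- hi + 1L
    support <- lo:hi
    if (length(support) < params$min_support) {
      dropped <- c(dropped, sprintf("apex %d: support < %d fractions", apex, params$min_support))
      next
    }
    fit <- fit_gaussian_region(support, y[support], apex)
    if (is.null(fit)) {
      dropped <- c(dropped, sprintf("apex %d: Gaussian fit did not converge", apex))
      next
    }
    if (fit$sigma < params$min_sigma) {
      dropped <- c(dropped, sprintf("apex %d: fitted width %.2f below minimum", apex, fit$sigma))
      next
    }
    single <- numeric(n)
    single[support] <- fit$A * exp(-(support - fit$mu)^2 / (2 * fit$sigma^2))
    rows[[length(rows) + 1L]] <- data.frame(
      apex_fraction = as.integer(min(max(round(fit$mu), lo), hi)),
      mu = fit$mu, sigma = fit$sigma, amplitude = fit$A,
      support_lo = lo, support_hi = hi, rss = fit$rss
    )
    profs[[length(profs) + 1L]] <- single
  }
  if (length(dropped)) {
    message("deconvolve: dropped ", length(dropped), " candidate peak(s): ",
            paste(dropped, collapse = "; "))
  }
  if (!length(rows)) return(empty)

  peaks <- do.call(rbind, rows)
  ord <- order(peaks$mu)
  peaks <- peaks[ord, , drop = FALSE]
  peaks <- cbind(peak = seq_len(nrow(peaks)), peaks)
  rownames(peaks) <- NULL
  profiles <- do.call(rbind, profs)[ord, , drop = FALSE]
  structure(list(
    peaks = peaks,
    profiles = profiles,
    residual = sqrt(mean((y - colSums(profiles))^2))
  ), class = "deconvolution")
}

#' Deconvolve every feature of a fractionation dataset
#'
#' For each feature the replicate profiles are normalized and averaged
#' ([average_replicates()]) and the mean profile deconvolved. A fitted
#' peak is retained only when its apex is reproduced (a candidate apex
#' within one fraction) in at least `min_replicated` replicates.
#'
#' @param dataset A `fractionation_dataset`.
#' @param params [peak_params()].
#' @param min_replicated Minimum number of replicates in which an apex
#'   must recur (capped at the number of replicates available).
#' @return List of class `peak_set`: `peaks` (data frame with `feature_id`,
#'   `kind`, peak geometry and, after [add_apparent_mass()], apparent
#'   masses), `profiles` (matrix of fitted single-peak profiles, one row
#'   per peak), `reproducibility` (per-feature mean pairwise replicate
#'   correlation) and the fraction bookkeeping of the input.
#' @export
deconvolve_dataset <- function(dataset, params = peak_params(), min_replicated = 2L) {
  stopifnot(inherits(dataset, "fractionation_dataset"))
  n_rep <- length(dataset$replicates)
  need <- min(min_replicated, n_rep)
  ids <- dataset$features$feature_id

  all_peaks <- list(); all_profiles <- list()
  repro <- data.frame(feature_id = ids, reproducibility = NA_real_)
  for (i in seq_along(ids)) {
    id <- ids[i]
    mat <- do.call(rbind, lapply(dataset$replicates, function(m) m[id, ]))
    if (max(mat) == 0) next
    avg <- average_replicates(mat)
    repro$reproducibility[i] <- avg$reproducibility
    dec <- suppressMessages(deconvolve(avg$profile, params))
    if (!nrow(dec$peaks)) next
    if (n_rep > 1 && need > 1) {
      rep_apexes <- lapply(seq_len(n_rep), function(r) {
        pick_apexes(as.numeric(normalize_profile(mat[r, ])), params)
      })
      support_count <- vapply(dec$peaks$apex_fraction, function(a) {
        sum(vapply(rep_apexes, function(ap) any(abs(ap - a) <= 1), logical(1)))
      }, numeric(1))
      keep <- support_count >= need
      dec$peaks <- dec$peaks[keep, , drop = FALSE]
      dec$profiles <- dec$profiles[keep, , drop = FALSE]
    }
    if (!nrow(dec$peaks)) next
    dec$peaks$peak <- seq_len(nrow(dec$peaks))
    all_peaks[[length(all_peaks) + 1L]] <- cbind(
      feature_id = id, kind = dataset$features$kind[i], dec$peaks,
      stringsAsFactors = FALSE
    )
    all_profiles[[length(all_profiles) + 1L]] <- dec$profiles
  }
  peaks <- if (length(all_peaks)) do.call(rbind, all_peaks) else
    data.frame(feature_id = character(), kind = character(), peak = integer(),
               apex_fraction = integer(), mu = numeric(), sigma = numeric(),
               amplitude = numeric(), support_lo = integer(),
               support_hi = integer(), rss = numeric())
  rownames(peaks) <- NULL
  profiles <- if (length(all_profiles)) do.call(rbind, all_profiles) else
    matrix(numeric(), nrow = 0, ncol = dataset$n_fractions)
  structure(list(
    peaks = peaks,
    profiles = profiles,
    reproducibility = repro,
    n_fractions = dataset$n_fractions,
    protein_span = dataset$protein_span
  ), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks from %d features (%d protein / %d metabolite peaks)\n",
              nrow(x$peaks), length(unique(x$peaks$feature_id)),
              sum(x$peaks$kind == "protein"), sum(x$peaks$kind == "metabolite")))
  invisible(x)
}
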