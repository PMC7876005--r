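# Elution-profile normalization and replicate handling.

#' Normalize an elution profile to its maximum
#'
#' Intensities are expressed relative to the maximum intensity measured
#' across the fractionation range, so the profile apex equals 1. An
#' all-zero profile is returned unchanged and flagged.
#'
#' @param x Non-negative numeric intensity vector, one value per fraction.
#' @return Numeric vector scaled to `[0, 1]`, with attribute `all_zero`
#'   set to `TRUE` for the degenerate all-zero input.
#' @export
normalize_profile <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("intensity vector must be finite and non-negative")
  }
  m <- max(x)
  if (m == 0) {
    return(structure(x, all_zero = TRUE))
  }
  structure(x / m, all_zero = FALSE)
}

#' Average replicate elution profiles
#'
#' Each replicate is normalized to its own maximum, the element-wise mean
#' is taken, and the mean profile re-normalized. Reproducibility is
#' summarized as the mean Pearson correlation over all replicate pairs
#' (the SEC runs behind the pipeline are expected to be highly
#' reproducible; poorly correlated replicates are a red flag, not an
#' error).
#'
#' @param profiles A matrix with one replicate per row, or a list of
#'   equal-length numeric vectors.
#' @return List with `profile` (normalized mean profile), `reproducibility`
#'   (mean pairwise Pearson correlation; `NA` for a single replicate) and
#'   `n_replicates`.
#' @export
average_replicates <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1) stop("replicate profiles differ in length")
    profiles <- do.call(rbind, profiles)
  }
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  norm <- t(apply(profiles, 1, function(r) as.numeric(normalize_profile(r))))
  if (ncol(profiles) == 1) norm <- t(norm)  # 1-fraction edge case
  mean_profile <- normalize_profile(colMeans(norm))

  n <- nrow(profiles)
  reproducibility <- NA_real_
  if (n >= 2) {
    cors <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::sd(norm[i, ]) > 0 && stats::sd(norm[j, ]) > 0) {
          cors <- c(cors, stats::cor(norm[i, ], norm[j, ]))
        }
      }
    }
    if (length(cors)) reproducibility <- mean(cors)
  }
  list(profile = mean_profile, reproducibility = reproducibility, n_replicates = n)
}
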