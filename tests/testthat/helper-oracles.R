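# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities from first principles so they
# stay independent of the implementation paths they check.

# Product-moment correlation straight from the defining formula.
oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Benjamini-Hochberg step-up by its textbook definition: sort, scale by
# m / rank, enforce monotonicity from the largest p down.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(scaled, 1))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Gaussian elution profile on an integer fraction grid.
gaussian_profile <- function(n, mu, sigma = 1.5, amplitude = 1) {
  x <- seq_len(n)
  rowSums(vapply(seq_along(mu), function(k) {
    amplitude[min(k, length(amplitude))] * exp(-(x - mu[k])^2 / (2 * sigma^2))
  }, numeric(n)))
}

# Multiplicative lognormal noise with unit mean at a given CV.
noisy <- function(y, cv) {
  if (cv <= 0) return(y)
  s <- sqrt(log(1 + cv^2))
  y * exp(rnorm(length(y), -s^2 / 2, s))
}

# Hand-built peak_set for scoring tests: one single-peak profile per row
# of `spec_df` (feature_id, kind, mu), Gaussian over `n` fractions.
make_peak_set <- function(spec_df, n = 48, protein_span = 38, sigma = 1.5) {
  profiles <- t(vapply(seq_len(nrow(spec_df)), function(i) {
    gaussian_profile(n, spec_df$mu[i], sigma)
  }, numeric(n)))
  peaks <- data.frame(
    feature_id = spec_df$feature_id, kind = spec_df$kind,
    peak = stats::ave(seq_len(nrow(spec_df)), spec_df$feature_id, FUN = seq_along),
    apex_fraction = as.integer(round(spec_df$mu)), mu = spec_df$mu,
    sigma = sigma, amplitude = 1,
    support_lo = pmax(1L, as.integer(round(spec_df$mu - 4))),
    support_hi = pmin(as.integer(n), as.integer(round(spec_df$mu + 4))),
    rss = 0
  )
  structure(list(peaks = peaks, profiles = profiles, n_fractions = n,
                 protein_span = protein_span,
                 reproducibility = data.frame(feature_id = unique(spec_df$feature_id),
                                              reproducibility = NA_real_)),
            class = "peak_set")
}

# null_distribution with a prescribed score matrix, for testing the
# FDR/enrichment arithmetic against hand-computed operating points.
make_null <- function(scores) {
  structure(list(scores = scores, n_iterations = nrow(scores),
                 n_pairs = ncol(scores), seed = NA_integer_),
            class = "null_distribution")
}

# Small, fast benchmark variant for pipeline-level unit tests.
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_proteins = 40, n_metabolites = 10, n_planted = 6,
         complexes = 2, noise_cv = 0.15, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}
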