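# Profile normalization, replicate averaging, deconvolution, mass
# calibration and oligomeric-state calls.

test_that("profiles are normalized to their maximum", {
  expect_equal(as.numeric(normalize_profile(c(2, 4, 8, 4))), c(0.25, 0.5, 1, 0.5))
  z <- normalize_profile(rep(0, 5))
  expect_true(attr(z, "all_zero"))
  expect_equal(as.numeric(z), rep(0, 5))
  for (i in 1:10) {
    set.seed(i)
    v <- normalize_profile(runif(20))
    expect_equal(max(v), 1)
  }
  expect_error(normalize_profile(c(1, -1, 2)), "non-negative")
})

test_that("replicate averaging reports mean pairwise correlation", {
  p <- gaussian_profile(20, 10)
  same <- average_replicates(rbind(p, p, p))
  expect_equal(as.numeric(same$profile), p / max(p))
  expect_equal(same$reproducibility, 1)

  one <- average_replicates(matrix(p, nrow = 1))
  expect_equal(as.numeric(one$profile), p / max(p))
  expect_true(is.na(one$reproducibility))

  set.seed(42)
  reps <- t(replicate(3, noisy(p, 0.1)))
  got <- average_replicates(reps)
  norm <- t(apply(reps, 1, function(r) r / max(r)))
  pairs <- combn(3, 2)
  oracle <- mean(apply(pairs, 2, function(ij) oracle_pcc(norm[ij[1], ], norm[ij[2], ])))
  expect_equal(got$reproducibility, oracle, tolerance = 1e-12)

  expect_error(average_replicates(list(1:4, 1:5)), "length")
})

test_that("single noiseless Gaussians are recovered nearly exactly", {
  y <- gaussian_profile(38, 15, 1.5)
  dec <- deconvolve(normalize_profile(y))
  expect_equal(nrow(dec$peaks), 1)
  expect_lt(abs(dec$peaks$mu - 15), 0.1)
  expect_lt(abs(dec$peaks$sigma - 1.5), 0.1)
  expect_lt(dec$residual, 1e-3)
})

test_that("a two-component mixture splits into two accurate peaks", {
  y <- gaussian_profile(38, c(10, 20), 1.5, c(1, 1))
  dec <- deconvolve(normalize_profile(y))
  expect_equal(nrow(dec$peaks), 2)
  expect_lt(abs(dec$peaks$mu[1] - 10), 1)
  expect_lt(abs(dec$peaks$mu[2] - 20), 1)
  # sum of fitted single peaks reconstructs the input
  expect_lt(dec$residual, 0.02)
})

test_that("flat and degenerate profiles give no peaks", {
  expect_equal(nrow(deconvolve(rep(0, 38))$peaks), 0)
  expect_equal(nrow(deconvolve(c(0, 1, 0))$peaks), 0)  # support too narrow
})

test_that("planted k-peak profiles are recovered at the planted count", {
  set.seed(101)
  n_ok <- 0; n_tot <- 60
  for (i in seq_len(n_tot)) {
    k <- sample(1:3, 1)
    mus <- sort(5 + cumsum(runif(k, 6, 9)))
    y <- noisy(gaussian_profile(38, mus, 1.5, runif(k, 0.5, 1)), 0.1)
    dec <- suppressMessages(deconvolve(normalize_profile(y)))
    if (nrow(dec$peaks) == k && all(abs(dec$peaks$mu - mus) <= 1)) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("calibration fits are exact on exact data and predictive on held-out refs", {
  refs <- generate_calibration_refs(5)
  cal <- fit_calibration(refs)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_lt(abs(cal$slope - (log10(2e4) - log10(5.2e6)) / 37), 1e-12)

  two <- fit_calibration(refs[c(1, 5), ])
  expect_equal(apparent_mass(refs$fraction[1], two)$mass_da, refs$mass_da[1])

  six <- generate_calibration_refs(6)
  cal5 <- fit_calibration(six[-3, ])
  pred <- apparent_mass(six$fraction[3], cal5)$mass_da
  expect_lt(abs(pred - six$mass_da[3]) / six$mass_da[3], 0.01)

  expect_error(fit_calibration(data.frame(fraction = 1, mass_da = 100)), "at least 2")
  expect_error(fit_calibration(data.frame(fraction = c(2, 2), mass_da = c(10, 20))),
               "at least 2")
  expect_error(fit_calibration(data.frame(fraction = 1:3, mass_da = c(10, 20, 40))),
               "slope")
})

test_that("apparent masses interpolate geometrically and flag extrapolation", {
  refs <- generate_calibration_refs(2, c(1e6, 1e4), span = c(5, 25))
  cal <- fit_calibration(refs)
  mid <- apparent_mass(15, cal)
  expect_equal(mid$mass_da, sqrt(1e6 * 1e4), tolerance = 1e-9)
  expect_false(mid$extrapolated)
  out <- apparent_mass(c(2, 30), cal)
  expect_true(all(out$extrapolated))
})

test_that("oligomeric-state calls follow the 1.5 ratio rule", {
  calls <- classify_oligomeric(
    c("Pnp1", "Pnp1", "X"),
    apparent_mass_da = c(138e3, 88e3, 50e3),
    monomeric_mass_da = c(33e3, 33e3, 50e3)
  )
  expect_equal(calls$ratio, c(138 / 33, 88 / 33, 1), tolerance = 1e-12)
  expect_equal(calls$multimeric, c(TRUE, TRUE, FALSE))

  # scale invariance: multiplying both masses by c leaves the call unchanged
  for (c_scale in c(0.01, 3, 1e4)) {
    scaled <- classify_oligomeric(c("Pnp1", "Pnp1", "X"),
                                  c(138e3, 88e3, 50e3) * c_scale,
                                  c(33e3, 33e3, 50e3) * c_scale)
    expect_equal(scaled$ratio, calls$ratio, tolerance = 1e-12)
    expect_equal(scaled$multimeric, calls$multimeric)
  }

  skipped <- classify_oligomeric(c("a", "b"), c(1e5, 2e5), c(5e4, NA))
  expect_equal(nrow(skipped), 1)
  expect_equal(attr(skipped, "n_skipped"), 1)
  expect_error(classify_oligomeric("a", 1e5, -3), "positive")
})

test_that("dataset-level deconvolution keeps replicate-supported peaks only", {
  cfg <- small_config(seed = 8, noise_cv = 0.1)
  sim <- simulate_fractionation(cfg)
  ps <- deconvolve_dataset(sim$dataset)
  expect_s3_class(ps, "peak_set")
  expect_gt(nrow(ps$peaks), 0)
  # every planted partner protein retains a peak near its planted center
  for (i in seq_len(nrow(sim$truth$pmis))) {
    mus <- ps$peaks$mu[ps$peaks$feature_id == sim$truth$pmis$protein_id[i]]
    expect_true(any(abs(mus - sim$truth$pmis$center[i]) <= 1))
  }
  # fitted peak centers map back to the planted centers (calibration
  # consistency within one fraction)
  truth_peaks <- sim$truth$peaks[sim$truth$peaks$kind == "protein", ]
  for (j in sample(nrow(truth_peaks), 10)) {
    mus <- ps$peaks$mu[ps$peaks$feature_id == truth_peaks$feature_id[j]]
    expect_true(any(abs(mus - truth_peaks$center[j]) <= 1))
  }
})
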