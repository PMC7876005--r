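# The synthetic generators: determinism, planted structure, noise model.

test_that("calibration references lie exactly on a log-linear line", {
  refs <- generate_calibration_refs(5, c(5.2e6, 2e4), span = c(1, 38))
  fit <- lm(log10(mass_da) ~ fraction, data = refs)
  expect_lt(max(abs(resid(fit))), 1e-12)
  expect_equal(refs$mass_da[1], 5.2e6)
  expect_equal(refs$mass_da[5], 2e4)
  expect_true(all(diff(refs$mass_da) < 0))
  # two references are the endpoints themselves
  two <- generate_calibration_refs(2, c(5.2e6, 2e4), span = c(1, 38))
  expect_equal(two$fraction, c(1, 38))
  expect_equal(two$mass_da, c(5.2e6, 2e4))
  expect_error(generate_calibration_refs(1), "at least 2")
  # determinism under a seed, with noise
  a <- generate_calibration_refs(5, noise_sd = 0.05, seed = 7)
  b <- generate_calibration_refs(5, noise_sd = 0.05, seed = 7)
  expect_identical(a, b)
})

test_that("fractionation simulation is deterministic and dimensioned by its config", {
  cfg <- small_config(seed = 3)
  sim1 <- simulate_fractionation(cfg)
  sim2 <- simulate_fractionation(cfg)
  expect_identical(sim1$dataset$replicates, sim2$dataset$replicates)
  expect_identical(sim1$truth$pmis, sim2$truth$pmis)

  d <- sim1$dataset
  expect_equal(nrow(d$features), cfg$n_proteins + cfg$n_metabolites)
  expect_length(d$replicates, cfg$n_replicates)
  expect_equal(dim(d$replicates$rep1),
               c(cfg$n_proteins + cfg$n_metabolites, cfg$n_fractions))
  expect_equal(nrow(sim1$truth$pmis), 6)
  # disjoint id namespaces
  expect_length(intersect(d$features$feature_id[d$features$kind == "protein"],
                          d$features$feature_id[d$features$kind == "metabolite"]), 0)
  expect_true(all(sim1$truth$pmis$protein_id %in% d$features$feature_id))
  expect_true(all(sim1$truth$pmis$metabolite_id %in% d$features$feature_id))
})

test_that("noiseless planted pairs co-elute perfectly and complex members share a peak", {
  # single-peaked proteins and no free metabolite pool, so raw
  # whole-profile correlations are exact
  cfg <- small_config(seed = 5, noise_cv = 0, p_two_peak = 0,
                      free_pool_fraction = 0)
  sim <- simulate_fractionation(cfg)
  m <- sim$dataset$replicates$rep1
  win <- seq_len(cfg$protein_span)
  for (i in seq_len(nrow(sim$truth$pmis))) {
    met <- m[sim$truth$pmis$metabolite_id[i], win]
    prot <- m[sim$truth$pmis$protein_id[i], win]
    expect_gt(cor(met, prot), 1 - 1e-9)
  }
  # complex members: identical normalized profiles, apex at the fraction
  # implied by the complex mass through the calibration line
  cpx <- sim$truth$complexes
  one <- cpx[cpx$complex_id == cpx$complex_id[1], ]
  profs <- m[one$protein_id, , drop = FALSE]
  norm <- profs / apply(profs, 1, max)
  expect_lt(max(abs(sweep(norm, 2, norm[1, ]))), 1e-9)
  refs <- generate_calibration_refs(6, cfg$mass_range, c(1, cfg$protein_span))
  cal <- fit_calibration(refs)
  predicted_fraction <- (log10(one$mass_da[1]) - cal$intercept) / cal$slope
  expect_lt(abs(which.max(profs[1, ]) - predicted_fraction), 1)
})

test_that("replicate noise realizes the configured coefficient of variation", {
  cfg <- sim_config(n_proteins = 200, n_metabolites = 30, n_planted = 20,
                    complexes = 5, noise_cv = 0.15, seed = 1)
  sim <- simulate_fractionation(cfg)
  reps <- simplify2array(sim$dataset$replicates)  # features x fractions x reps
  mu <- apply(reps, c(1, 2), mean)
  sdv <- apply(reps, c(1, 2), sd)
  signal <- mu > 1e3  # well above the peak tails
  cv <- mean(sdv[signal] / mu[signal])
  expect_lt(abs(cv - 0.15) / 0.15, 0.2)
})

test_that("an out-of-range complex mass is refused", {
  cpx <- data.frame(complex_id = "CPX01", protein_id = c("P0001", "P0002"),
                    mass_da = 1e9)
  cfg <- sim_config(n_proteins = 10, n_metabolites = 2, complexes = cpx, seed = 1)
  expect_error(simulate_fractionation(cfg), "outside the calibrated")
})

test_that("TPP simulation plants midpoint shifts and is seed-stable", {
  a <- simulate_tpp(5, 2, 3, 0.02, seed = 9)
  b <- simulate_tpp(5, 2, 3, 0.02, seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$truth$is_binder), 2)

  # no shift, no noise: conditions coincide exactly
  null <- simulate_tpp(4, 2, 0, 0, seed = 2)
  v <- null$data[null$data$condition == "vehicle", ]
  t <- null$data[null$data$condition == "treatment", ]
  expect_equal(v$value, t$value)

  # a +3 degC shift leaves the treated protein above half-melted at the
  # vehicle midpoint (evaluated analytically from the truth parameters)
  shifted <- simulate_tpp(3, 1, 3, 0, seed = 4)
  tm <- shifted$truth$tm_vehicle[1]
  d <- shifted$data
  binder_t <- d[d$protein_id == shifted$truth$protein_id[1] &
                  d$condition == "treatment" & d$replicate == 1, ]
  f_at_tm <- approx(binder_t$temperature, binder_t$value, xout = tm)$y
  expect_gt(f_at_tm, 0.5)
})

test_that("AP simulation plants exact offsets and exact bookkeeping", {
  s <- simulate_ap(20, 5, 2, 0, n_replicates = 3, seed = 11)
  expect_equal(sum(s$truth$enriched), 5)
  m <- s$data$log2_intensities
  g <- s$data$groups
  for (i in which(s$truth$enriched)) {
    coup <- s$truth$coupling[i]
    if (coup %in% c("n", "both")) {
      expect_equal(mean(m[i, g == "bait_n"]) - mean(m[i, g == "control"]), 2)
    }
    if (coup %in% c("c", "both")) {
      expect_equal(mean(m[i, g == "bait_c"]) - mean(m[i, g == "control"]), 2)
    }
  }
  # null effect: no planted separation anywhere
  null <- simulate_ap(20, 5, 0, 0, seed = 12)
  mn <- null$data$log2_intensities
  expect_equal(rowMeans(mn[, null$data$groups == "bait_n"]),
               rowMeans(mn[, null$data$groups == "control"]))
})
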