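# Melting-curve fitting, the nested-F curve test, BH adjustment, AP
# enrichment and the evidence intersection.

test_that("melting-curve fits recover generating parameters on clean data", {
  temps <- c(37, 41, 44, 47, 50, 53, 56, 59, 63, 67)
  truth <- list(a = 10 * 51, b = 10, p = 0.12)
  y <- melt_sigmoid(temps, truth$a, truth$b, truth$p)
  fit <- fit_melting_curve(temps, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - truth$a) / truth$a, 0.01)
  expect_lt(abs(fit$b - truth$b) / truth$b, 0.01)
  expect_lt(abs(fit$p - truth$p) / truth$p, 0.01)
  # asymptotes of the model family
  expect_lt(abs(melt_sigmoid(5, truth$a, truth$b, truth$p) - 1), 1e-6)
  expect_equal(melt_sigmoid(1e6, truth$a, truth$b, truth$p),
               truth$p + (1 - truth$p) / (1 + exp(truth$b)), tolerance = 1e-3)
})

test_that("identical conditions give F = 0 and noisy fits keep RSS1 <= RSS0", {
  temps <- c(37, 41, 44, 47, 50, 53, 56, 59, 63, 67)
  y <- melt_sigmoid(temps, 500, 10, 0.1)
  d <- data.frame(temperature = temps, value = y)
  same <- nparc_test(d, d)
  expect_equal(same$rss1, same$rss0, tolerance = 1e-10)
  expect_lt(same$f, 1e-6)
  expect_gt(same$p_value, 0.999)

  set.seed(5)
  for (i in 1:10) {
    v <- data.frame(temperature = rep(temps, 2),
                    value = melt_sigmoid(rep(temps, 2), 520, 10, 0.1) + rnorm(20, 0, 0.05))
    t2 <- data.frame(temperature = rep(temps, 2),
                     value = melt_sigmoid(rep(temps, 2), 520, 10, 0.1) + rnorm(20, 0, 0.05))
    r <- nparc_test(v, t2)
    expect_lte(r$rss1, r$rss0 + 1e-10)
    expect_gte(r$f, 0)
  }
})

test_that("a planted 3-degree shift is detected in a small screen", {
  sim <- simulate_tpp(20, 2, 3, 0.02, seed = 31)
  res <- nparc_screen(sim$data)
  binders <- sim$truth$protein_id[sim$truth$is_binder]
  expect_true(all(res$q_value[res$protein_id %in% binders] <= 0.05))
})

test_that("BH adjustment equals the step-up definition and is order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("AP enrichment calls exactly the planted set on clean data", {
  s <- simulate_ap(30, 6, 2, 0, n_replicates = 3, seed = 41)
  res <- ap_enrichment(s$data, alpha = 0.05, min_log2fc = 1)
  expect_setequal(res$protein_id[res$enriched],
                  s$truth$protein_id[s$truth$enriched])

  # identical bait and control matrices: nothing is called
  flat <- s
  m <- flat$data$log2_intensities
  m[, flat$data$groups != "control"] <-
    m[, rep(which(flat$data$groups == "control"), 2)]
  flat$data$log2_intensities <- m
  expect_equal(sum(ap_enrichment(flat$data)$enriched), 0)

  # null simulation: with no planted effect the BH-controlled call rate
  # stays near zero
  null <- simulate_ap(200, 0, 0, 0.3, n_replicates = 3, seed = 42)
  expect_lte(sum(ap_enrichment(null$data)$enriched), 10)
})

test_that("intersection requires the coupling rule it is asked for", {
  s <- simulate_ap(30, 6, 2, 0, n_replicates = 3, seed = 43)
  both <- s$truth$protein_id[s$truth$enriched & s$truth$coupling == "both"]
  inter <- ap_enrichment(s$data, combine = "intersection")
  expect_setequal(inter$protein_id[inter$enriched], both)
})

test_that("evidence intersection is correct set algebra and symmetric", {
  expect_equal(sum(intersect_evidence(c("a", "b"), c("c"), c("d"))$interactome), 0)
  all3 <- intersect_evidence("x", "x", "x")
  expect_true(all3$high_confidence)
  expect_true(all3$interactome)

  set.seed(8)
  for (i in 1:10) {
    pool <- paste0("p", 1:30)
    a <- sample(pool, sample(5:15, 1))
    b <- sample(pool, sample(5:15, 1))
    c <- sample(pool, sample(5:15, 1))
    got <- intersect_evidence(a, b, c)
    for (j in seq_len(nrow(got))) {
      id <- got$protein_id[j]
      oracle <- sum(id %in% a, id %in% b, id %in% c)
      expect_equal(got$support[j], oracle)
      expect_equal(got$interactome[j], oracle >= 2)
      expect_equal(got$high_confidence[j], oracle == 3)
    }
    perm <- intersect_evidence(c, a, b)
    expect_equal(perm$support[order(perm$protein_id)],
                 got$support[order(got$protein_id)])
  }
})
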