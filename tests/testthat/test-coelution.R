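# Pair scoring, null sampling, ROC/FDR arithmetic and network calls.

test_that("pcc matches the product-moment definition and guards its preconditions", {
  expect_equal(pcc(1:5, 1:5), 1)
  expect_equal(pcc(1:5, -(1:5)), -1)
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pcc(c(1, 1, 1), c(1, 2, 3))))
  expect_equal(attr(pcc(c(1, 1, 1), c(1, 2, 3)), "reason"), "zero variance")
  expect_true(is.na(pcc(c(1, 0, 0, 2), c(1, 2, 0, 3))))
  expect_error(pcc(1:4, 1:5), "equal length")
})

test_that("score_pairs scores every eligible combination on the protein window", {
  spec <- data.frame(
    feature_id = c("M1", "M1", "M2", "P1", "P2", "P3"),
    kind = c(rep("metabolite", 3), rep("protein", 3)),
    mu = c(10, 42, 20, 10, 20, 30)
  )
  ps <- make_peak_set(spec)
  cand <- score_pairs(ps)
  # M1's free-pool peak (fraction 42) is outside the window: 2 metabolite
  # peaks x 3 protein peaks remain
  expect_equal(nrow(cand), 6)
  expect_equal(cand$r[cand$metabolite_id == "M1" & cand$protein_id == "P1" &
                        cand$met_peak == 1], 1, tolerance = 1e-12)
  # non-overlapping peaks anti-correlate or are uncorrelated
  expect_lte(max(cand$r[cand$metabolite_id == "M1" & cand$protein_id == "P3"]), 0)
  expect_lte(max(cand$r[cand$metabolite_id == "M2" & cand$protein_id == "P1"]), 0)
})

test_that("pair_score takes the maximum over peak pairs (exhaustive oracle)", {
  expect_equal(pair_score(data.frame(metabolite_id = "m", protein_id = "p",
                                     met_peak = 1, prot_peak = 1, r = 0.9))$score, 0.9)
  expect_equal(pair_score(data.frame(metabolite_id = "m", protein_id = "p",
                                     met_peak = c(1, 2), prot_peak = 1,
                                     r = c(0.2, 0.8)))$score, 0.8)
  set.seed(7)
  for (i in 1:5) {
    cand <- data.frame(
      metabolite_id = sample(paste0("m", 1:4), 50, replace = TRUE),
      protein_id = sample(paste0("p", 1:6), 50, replace = TRUE),
      met_peak = sample(2, 50, replace = TRUE),
      prot_peak = sample(2, 50, replace = TRUE),
      r = runif(50, -1, 1)
    )
    got <- pair_score(cand)
    for (j in seq_len(nrow(got))) {
      sel <- cand$metabolite_id == got$metabolite_id[j] &
        cand$protein_id == got$protein_id[j]
      expect_equal(got$score[j], max(cand$r[sel]))
      expect_equal(got$n_peak_pairs[j], sum(sel))
    }
  }
})

test_that("the true set is the detected subset of the known list, deduplicated", {
  features <- data.frame(feature_id = c("m1", "m2", "p1", "p2"),
                         kind = c("metabolite", "metabolite", "protein", "protein"))
  known <- data.frame(chemical_id = c("m1", "m1", "m2", "m9", "m1"),
                      protein_id = c("p1", "p2", "p9", "p1", "p1"))
  ts <- build_true_set(known, features)
  expect_equal(ts$n_pairs, 2)  # m1-p1 (deduped), m1-p2
  expect_error(build_true_set(data.frame(chemical_id = "zz", protein_id = "qq"),
                              features), "no known interaction")
})

test_that("null sampling is seeded, shaped, and excludes true pairs", {
  features <- data.frame(
    feature_id = c(paste0("m", 1:5), paste0("p", 1:10)),
    kind = rep(c("metabolite", "protein"), c(5, 10))
  )
  # the only scored pair is the true one, at a distinctive score
  scores <- data.frame(metabolite_id = "m1", protein_id = "p1", score = 0.99,
                       n_peak_pairs = 1)
  ts <- build_true_set(data.frame(chemical_id = "m1", protein_id = "p1"), features)
  null <- sample_null(scores, features, ts, n_pairs = 10, n_iterations = 50, seed = 3)
  expect_equal(dim(null$scores), c(50, 10))
  # true pair excluded, and unscored pairs take the -1 floor
  expect_true(all(null$scores == -1))
  null2 <- sample_null(scores, features, ts, n_pairs = 10, n_iterations = 50, seed = 3)
  expect_identical(null$scores, null2$scores)
  expect_error(sample_null(scores, features, ts, n_pairs = 1000, seed = 1),
               "eligible")
})

test_that("ROC endpoints, separation and null-equivalence behave as expected", {
  sep_null <- make_null(matrix(0.05, nrow = 100, ncol = 20))
  roc <- roc_analysis(rep(0.95, 20), sep_null, t_star = 0.7)
  expect_equal(roc$auc, 1)
  expect_equal(roc$tpr_star, 1)
  expect_equal(roc$fpr_star, 0)
  # boundary: at t = -1 everything is called
  at_floor <- roc$curve[roc$curve$threshold == -1, ]
  expect_equal(at_floor$tpr, 1)
  expect_equal(at_floor$fpr, 1)
  # monotonicity in t
  expect_true(all(diff(roc$curve$tpr) <= 0 | diff(roc$curve$threshold) <= 0))
  expect_true(all(diff(roc$curve$fpr[order(roc$curve$threshold)]) <= 0))

  # true scores drawn from the null distribution: AUC near 1/2
  set.seed(9)
  pool <- runif(5000, -1, 1)
  same <- roc_analysis(sample(pool, 200),
                       make_null(matrix(sample(pool, 5000), nrow = 100)))
  expect_lt(abs(same$auc - 0.5), 0.05)

  expect_error(roc_analysis(numeric(), sep_null), "empty true set")
})

test_that("FDR and enrichment reproduce the reference operating point", {
  # 14 recovered true interactions against ~3 expected by chance
  null3 <- make_null(matrix(rep(c(0.9, -1), c(3, 84)), nrow = 100, ncol = 87,
                            byrow = TRUE))
  true_scores <- rep(c(0.9, -1), c(14, 73))
  f <- fdr_at_threshold(true_scores, null3, 0.7)
  expect_equal(f$m_true, 14)
  expect_equal(f$m_null_bar, 3)
  expect_equal(f$fdr, 3 / 17)
  expect_equal(round(100 * f$fdr, 1), 17.6)

  # boundary cases
  clean <- make_null(matrix(-1, nrow = 10, ncol = 87))
  expect_equal(fdr_at_threshold(true_scores, clean, 0.7)$fdr, 0)
  expect_equal(fdr_at_threshold(rep(-1, 87), null3, 0.7)$fdr, 1)
  expect_true(is.na(fdr_at_threshold(rep(-1, 87), clean, 0.7)$fdr))

  # five-fold enrichment at 14 true positives over 2.8 expected by chance:
  # 8 iterations with 3 null positives, 2 with 2 -> mean 2.8
  m <- matrix(-1, nrow = 10, ncol = 87)
  m[1:8, 1:3] <- 0.9
  m[9:10, 1:2] <- 0.9
  e <- enrichment_over_chance(true_scores, make_null(m), 0.7)
  expect_equal(e$m_null_bar, 2.8)
  expect_equal(e$fold, 5)
  inf <- enrichment_over_chance(true_scores, clean, 0.7)
  expect_true(inf$infinite)
  expect_identical(inf$fold, Inf)
  expect_equal(enrichment_over_chance(true_scores,
                                      make_null(m[1:8, , drop = FALSE]), 0.7)$fold,
               14 / 3)
})

test_that("network calls are thresholded and monotone in the threshold", {
  set.seed(13)
  scores <- data.frame(
    metabolite_id = sample(paste0("m", 1:6), 40, replace = TRUE),
    protein_id = sample(paste0("p", 1:10), 40, replace = TRUE),
    score = runif(40, -1, 1), n_peak_pairs = 1
  )
  scores <- scores[!duplicated(scores[1:2]), ]
  expect_equal(nrow(call_interactions(scores, 1.01)$edges), 0)
  thresholds <- sort(runif(5, -1, 1))
  edge_sets <- lapply(thresholds, function(t) {
    e <- call_interactions(scores, t)$edges
    paste(e$metabolite_id, e$protein_id)
  })
  for (k in seq_len(length(thresholds) - 1)) {
    expect_true(all(edge_sets[[k + 1]] %in% edge_sets[[k]]))
  }
})

test_that("predicted-list validation equals brute-force set intersection", {
  net <- call_interactions(data.frame(
    metabolite_id = c("m1", "m1", "m2", "m3"),
    protein_id = c("p1", "p2", "p1", "p4"),
    score = c(0.9, 0.8, 0.75, 0.95), n_peak_pairs = 1
  ), 0.7)
  empty <- validate_predicted(net, data.frame(chemical_id = character(),
                                              protein_id = character(),
                                              score = numeric()))
  expect_equal(empty$n_interactions, 0)
  expect_equal(empty$n_metabolites, 0)

  set.seed(21)
  for (i in 1:5) {
    pred <- data.frame(
      chemical_id = sample(paste0("m", 1:4), 20, replace = TRUE),
      protein_id = sample(paste0("p", 1:5), 20, replace = TRUE),
      score = runif(20)
    )
    got <- validate_predicted(net, pred, min_score = 0.4)
    keep <- unique(pred[pred$score >= 0.4, 1:2])
    oracle <- merge(net$edges, keep,
                    by.x = c("metabolite_id", "protein_id"),
                    by.y = c("chemical_id", "protein_id"))
    expect_equal(got$n_interactions, nrow(oracle))
    expect_equal(got$n_metabolites, length(unique(oracle$metabolite_id)))
  }
})

test_that("noiseless planted interactions are recovered exactly through the stack", {
  cfg <- small_config(seed = 17, noise_cv = 0)
  sim <- simulate_fractionation(cfg)
  ps <- deconvolve_dataset(sim$dataset)
  scores <- pair_score(score_pairs(ps))
  net <- call_interactions(scores, 0.7)
  called <- paste(net$edges$metabolite_id, net$edges$protein_id)
  planted <- paste(sim$truth$pmis$metabolite_id, sim$truth$pmis$protein_id)
  expect_setequal(called, planted)
  # planted pairs score ~1 (identical pre-noise shapes; small departures
  # come only from per-region support truncation in the fits)
  expect_true(all(scores$score[paste(scores$metabolite_id, scores$protein_id)
                               %in% planted] > 0.99))
})
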