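# Co-elution scoring, ROC threshold selection, FDR estimation and network
# construction.
#
# Co-elution of a metabolite peak with a protein peak across the
# size-exclusion gradient is the evidence for a putative interaction. Peak
# pairs are scored by Pearson correlation of their fitted single-peak
# profiles over the protein-containing fraction window; a feature-level
# pair score is the maximum over its peak pairs. The correlation threshold
# is chosen from a ROC curve of known interactions against a
# random-pair permutation null, which also yields an FDR estimate and a
# fold-enrichment over chance. The correlation magnitude itself is treated
# as qualitative: it selects edges but is never used to rank them.

#' Pearson correlation between two elution vectors
#'
#' Standard product-moment correlation, guarded by the scoring
#' preconditions: equal length of at least 3, at least 3 nonzero entries
#' per vector, and nonzero variance. A pair failing the preconditions is
#' undefined and returns `NA` (to be excluded from scoring, never scored
#' as 0) with the reason in the `"reason"` attribute.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pcc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) return(structure(NA_real_, reason = "fewer than 3 fractions"))
  if (sum(x != 0) < 3 || sum(y != 0) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 nonzero fractions"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  stats::cor(x, y)
}

#' Score all metabolite-peak x protein-peak combinations
#'
#' Computes the Pearson correlation for every combination of a metabolite
#' peak and a protein peak whose apexes fall inside the scoring window
#' (default: the protein-containing span), on the fitted single-peak
#' profiles restricted to that window. Combinations failing the [pcc()]
#' preconditions are excluded.
#'
#' @param peak_set A `peak_set` containing both feature kinds.
#' @param window Integer vector of fraction indices to score over;
#'   defaults to the protein-containing span.
#' @return Data frame of interaction candidates: `metabolite_id`,
#'   `met_peak`, `protein_id`, `prot_peak`, `r`.
#' @export
score_pairs <- function(peak_set, window = NULL) {
  stopifnot(inherits(peak_set, "peak_set"))
  window <- window %||% seq_len(peak_set$protein_span)
  pk <- peak_set$peaks
  in_win <- pk$apex_fraction %in% window
  im <- which(pk$kind == "metabolite" & in_win)
  ip <- which(pk$kind == "protein" & in_win)
  empty <- data.frame(metabolite_id = character(), met_peak = integer(),
                      protein_id = character(), prot_peak = integer(), r = numeric())
  if (!length(im) || !length(ip)) return(empty)

  mm <- peak_set$profiles[im, window, drop = FALSE]
  pm <- peak_set$profiles[ip, window, drop = FALSE]
  valid_m <- rowSums(mm != 0) >= 3 & apply(mm, 1, stats::sd) > 0
  valid_p <- rowSums(pm != 0) >= 3 & apply(pm, 1, stats::sd) > 0
  im <- im[valid_m]; ip <- ip[valid_p]
  if (!length(im) || !length(ip)) return(empty)

  r <- stats::cor(t(peak_set$profiles[im, window, drop = FALSE]),
                  t(peak_set$profiles[ip, window, drop = FALSE]))
  out <- data.frame(
    metabolite_id = rep(pk$feature_id[im], times = length(ip)),
    met_peak = rep(pk$peak[im], times = length(ip)),
    protein_id = rep(pk$feature_id[ip], each = length(im)),
    prot_peak = rep(pk$peak[ip], each = length(im)),
    r = as.vector(r)
  )
  out[!is.na(out$r), , drop = FALSE]
}

#' Summarize peak-pair scores at the feature-pair level
#'
#' A metabolite-protein pair is summarized by the maximum correlation over
#' all of its peak-pair combinations: any single co-eluting peak pair is
#' enough evidence, and averaging would dilute it. Pairs with no candidate
#' are absent from the result (not scored 0).
#'
#' @param candidates Data frame from [score_pairs()].
#' @return Data frame `metabolite_id`, `protein_id`, `score`,
#'   `n_peak_pairs`.
#' @export
pair_score <- function(candidates) {
  stopifnot(all(c("metabolite_id", "protein_id", "r") %in% names(candidates)))
  if (!nrow(candidates)) {
    return(data.frame(metabolite_id = character(), protein_id = character(),
                      score = numeric(), n_peak_pairs = integer()))
  }
  key <- interaction(candidates$metabolite_id, candidates$protein_id, drop = TRUE)
  agg <- do.call(rbind, lapply(split(candidates, key), function(d) {
    data.frame(metabolite_id = d$metabolite_id[1], protein_id = d$protein_id[1],
               score = max(d$r), n_peak_pairs = nrow(d))
  }))
  rownames(agg) <- NULL
  agg[order(agg$metabolite_id, agg$protein_id), , drop = FALSE]
}

#' Restrict a known-interaction list to detected features
#'
#' @param known Data frame with columns `chemical_id`, `protein_id` (a
#'   STITCH-export-like pair list). Duplicate pairs collapse to one.
#' @param features Feature table of the dataset (`feature_id`, `kind`), or
#'   a `fractionation_dataset`.
#' @return List of class `known_set`: `pairs` (data frame `metabolite_id`,
#'   `protein_id`) and `n_pairs`.
#' @export
build_true_set <- function(known, features) {
  if (inherits(features, "fractionation_dataset")) features <- features$features
  stopifnot(all(c("chemical_id", "protein_id") %in% names(known)),
            all(c("feature_id", "kind") %in% names(features)))
  mets <- features$feature_id[features$kind == "metabolite"]
  prots <- features$feature_id[features$kind == "protein"]
  pairs <- unique(data.frame(metabolite_id = known$chemical_id,
                             protein_id = known$protein_id))
  pairs <- pairs[pairs$metabolite_id %in% mets & pairs$protein_id %in% prots, ]
  if (!nrow(pairs)) {
    stop("no known interaction has both partners detected in the dataset; ",
         "check identifier conventions of the pair list")
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_pairs = nrow(pairs)), class = "known_set")
}

# Scores of the true-set pairs; pairs never co-scored get the floor.
true_pair_scores <- function(true_set, pair_scores, floor = -1) {
  stopifnot(inherits(true_set, "known_set"))
  lut <- stats::setNames(pair_scores$score,
                         paste(pair_scores$metabolite_id, pair_scores$protein_id, sep = "\r"))
  s <- lut[paste(true_set$pairs$metabolite_id, true_set$pairs$protein_id, sep = "\r")]
  s[is.na(s)] <- floor
  unname(s)
}

#' Sample a random-pair null distribution of co-elution scores
#'
#' Per iteration, `n_pairs` metabolite-protein pairs are drawn uniformly
#' without replacement from all detected pairs excluding the known true
#' interactions, and each sampled pair is given its feature-level
#' co-elution score; pairs that were never co-scored (no eligible peak
#' combination) are assigned the scoring floor of -1.
#'
#' @param pair_scores Data frame from [pair_score()].
#' @param features Feature table or `fractionation_dataset`.
#' @param true_set A `known_set` whose pairs are excluded from sampling.
#' @param n_pairs Pairs per iteration; defaults to the size of the true
#'   set, mirroring like-for-like comparison of score sets.
#' @param n_iterations Number of random draws (default 100).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List of class `null_distribution`: `scores` (matrix,
#'   `n_iterations` x `n_pairs`), `n_iterations`, `n_pairs`, `seed`.
#' @export
sample_null <- function(pair_scores, features, true_set, n_pairs = NULL,
                        n_iterations = 100L, seed) {
  if (inherits(features, "fractionation_dataset")) features <- features$features
  stopifnot(inherits(true_set, "known_set"), n_iterations >= 1)
  n_pairs <- n_pairs %||% true_set$n_pairs
  stopifnot(n_pairs >= 1)
  mets <- features$feature_id[features$kind == "metabolite"]
  prots <- features$feature_id[features$kind == "protein"]
  total <- length(mets) * length(prots)
  true_idx <- (match(true_set$pairs$metabolite_id, mets) - 1L) * length(prots) +
    match(true_set$pairs$protein_id, prots)
  eligible <- setdiff(seq_len(total), true_idx[!is.na(true_idx)])
  if (length(eligible) < n_pairs) {
    stop(sprintf("only %d eligible random pairs available but %d requested per iteration",
                 length(eligible), n_pairs))
  }
  lut <- stats::setNames(pair_scores$score,
                         paste(pair_scores$metabolite_id, pair_scores$protein_id, sep = "\r"))
  scores <- with_seed(seed, {
    t(vapply(seq_len(n_iterations), function(i) {
      idx <- sample(eligible, n_pairs)
      m <- mets[(idx - 1L) %/% length(prots) + 1L]
      p <- prots[(idx - 1L) %% length(prots) + 1L]
      s <- lut[paste(m, p, sep = "\r")]
      s[is.na(s)] <- -1
      unname(s)
    }, numeric(n_pairs)))
  })
  if (n_pairs == 1L) scores <- matrix(scores, ncol = 1L)
  structure(list(scores = scores, n_iterations = n_iterations,
                 n_pairs = n_pairs, seed = seed),
            class = "null_distribution")
}

#' ROC analysis of co-elution scores against the permutation null
#'
#' TPR(t) is the fraction of known-true pairs scoring at least `t`; FPR(t)
#' is the mean, over null iterations, of the fraction of random pairs
#' scoring at least `t`. The area under the (FPR, TPR) curve is computed
#' by the trapezoid rule, and the chosen operating threshold is annotated
#' with its FDR estimate and fold-enrichment over chance.
#'
#' @param true_scores Numeric scores of the true-set pairs (see
#'   [true_pair_scores()]; unscored pairs at the -1 floor).
#' @param null A `null_distribution`.
#' @param t_grid Threshold grid (default `seq(-1, 1, by = 0.01)`).
#' @param t_star Operating threshold (default 0.7).
#' @return List of class `roc_result`: `curve` (data frame `threshold`,
#'   `tpr`, `fpr`), `auc`, `t_star`, `tpr_star`, `fpr_star`, `fdr`
#'   (estimate at `t_star`), `fold_enrichment`, and the positive counts
#'   behind them.
#' @export
roc_analysis <- function(true_scores, null, t_grid = seq(-1, 1, by = 0.01),
                         t_star = 0.7) {
  stopifnot(inherits(null, "null_distribution"))
  if (!length(true_scores)) stop("empty true set")
  tpr <- vapply(t_grid, function(t) mean(true_scores >= t), numeric(1))
  fpr <- vapply(t_grid, function(t) mean(null$scores >= t), numeric(1))
  ord <- order(t_grid, decreasing = TRUE)  # FPR non-decreasing
  fx <- c(0, fpr[ord], 1)
  ty <- c(0, tpr[ord], 1)
  auc <- sum(diff(fx) * (ty[-1] + ty[-length(ty)]) / 2)
  fdr <- fdr_at_threshold(true_scores, null, t_star)
  fold <- enrichment_over_chance(true_scores, null, t_star)
  structure(list(
    curve = data.frame(threshold = t_grid, tpr = tpr, fpr = fpr),
    auc = auc, t_star = t_star,
    tpr_star = mean(true_scores >= t_star),
    fpr_star = mean(null$scores >= t_star),
    fdr = fdr$fdr, m_true = fdr$m_true, m_null_bar = fdr$m_null_bar,
    fold_enrichment = fold$fold, fold_infinite = fold$infinite
  ), class = "roc_result")
}

#' False discovery rate estimate at a score threshold
#'
#' `FDR(t) = m_null / (m_null + m_true)` where `m_true` counts true-set
#' pairs at or above `t` and `m_null` is the mean per-iteration count of
#' null pairs at or above `t`. With no positives at all (0/0) the estimate
#' is undefined and returned as `NA`.
#'
#' @inheritParams roc_analysis
#' @param t Score threshold.
#' @return List: `fdr`, `m_true`, `m_null_bar`.
#' @export
fdr_at_threshold <- function(true_scores, null, t) {
  stopifnot(inherits(null, "null_distribution"))
  m_true <- sum(true_scores >= t)
  m_null_bar <- mean(rowSums(null$scores >= t))
  denom <- m_true + m_null_bar
  list(fdr = if (denom == 0) NA_real_ else m_null_bar / denom,
       m_true = m_true, m_null_bar = m_null_bar)
}

#' Fold-enrichment of recovered true interactions over chance
#'
#' Ratio of the number of true-set pairs called at threshold `t` to the
#' mean number of random pairs called in an equally sized draw. A zero
#' chance count is reported as infinite and flagged.
#'
#' @inheritParams fdr_at_threshold
#' @return List: `fold`, `infinite`, `m_true`, `m_null_bar`.
#' @export
enrichment_over_chance <- function(true_scores, null, t) {
  stopifnot(inherits(null, "null_distribution"))
  m_true <- sum(true_scores >= t)
  m_null_bar <- mean(rowSums(null$scores >= t))
  if (m_null_bar == 0) {
    list(fold = Inf, infinite = TRUE, m_true = m_true, m_null_bar = 0)
  } else {
    list(fold = m_true / m_null_bar, infinite = FALSE,
         m_true = m_true, m_null_bar = m_null_bar)
  }
}

#' Call the protein-metabolite interaction network
#'
#' Edges are all feature pairs whose co-elution score reaches the chosen
#' threshold. Scores are retained on the edges for provenance but are
#' qualitative: they should not be used to rank interactions.
#'
#' @param pair_scores Data frame from [pair_score()].
#' @param t_star Score threshold (default 0.7).
#' @return List of class `pmi_network`: `edges` (data frame
#'   `metabolite_id`, `protein_id`, `score`, `n_peak_pairs`) and `t_star`.
#' @export
call_interactions <- function(pair_scores, t_star = 0.7) {
  stopifnot(all(c("metabolite_id", "protein_id", "score") %in% names(pair_scores)))
  edges <- pair_scores[pair_scores$score >= t_star, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, t_star = t_star), class = "pmi_network")
}

#' Intersect a called network with a predicted-interaction list
#'
#' Filters the predicted list at a minimum prediction score and intersects
#' it with the called network edges, reporting the validated edges and the
#' counts of interactions and unique metabolites they involve.
#'
#' @param network A `pmi_network`.
#' @param predicted Data frame with `chemical_id`, `protein_id` and an
#'   optional `score` column (prediction confidence).
#' @param min_score Minimum prediction score (default 0.4); ignored when
#'   the list carries no scores.
#' @return List: `edges`, `n_interactions`, `n_metabolites`.
#' @export
validate_predicted <- function(network, predicted, min_score = 0.4) {
  stopifnot(inherits(network, "pmi_network"),
            all(c("chemical_id", "protein_id") %in% names(predicted)))
  if ("score" %in% names(predicted)) {
    predicted <- predicted[predicted$score >= min_score, , drop = FALSE]
  }
  predicted <- unique(predicted[c("chemical_id", "protein_id")])
  key_pred <- paste(predicted$chemical_id, predicted$protein_id, sep = "\r")
  key_net <- paste(network$edges$metabolite_id, network$edges$protein_id, sep = "\r")
  hits <- network$edges[key_net %in% key_pred, , drop = FALSE]
  rownames(hits) <- NULL
  list(edges = hits, n_interactions = nrow(hits),
       n_metabolites = length(unique(hits$metabolite_id)))
}
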