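# Synthetic thermal proteome profiling and affinity-purification data
# with planted ground truth.

#' Simulate a thermal proteome profiling experiment
#'
#' Vehicle melting curves are drawn from the melting sigmoid family with
#' per-protein midpoints, steepness and plateaus; for planted binders the
#' treatment midpoint is shifted by `delta_tm`. Additive Gaussian noise is
#' applied to the fold-changes.
#'
#' @param n_proteins Number of proteins.
#' @param n_binders Number of planted binders (0 to `n_proteins`).
#' @param delta_tm Planted melting-point shift in degC.
#' @param noise_sd Additive Gaussian noise on fold-changes.
#' @param temperatures Temperature ladder in degC (at least 6, spanning
#'   the transition; default a 10-point 37-67 degC ladder).
#' @param n_replicates Replicates per condition (default 2).
#' @param tm_range Range the per-protein vehicle midpoints are drawn from.
#' @param seed Integer seed.
#' @return List with `data` (long data frame: `protein_id`, `condition`,
#'   `replicate`, `temperature`, `value`) and `truth` (`protein_id`,
#'   `is_binder`, `delta_tm`, `tm_vehicle`).
#' @export
simulate_tpp <- function(n_proteins, n_binders, delta_tm, noise_sd,
                         temperatures = c(37, 41, 44, 47, 50, 53, 56, 59, 63, 67),
                         n_replicates = 2L, tm_range = c(45, 55), seed = 1L) {
  stopifnot(length(temperatures) >= 6, n_binders >= 0, n_binders <= n_proteins,
            noise_sd >= 0, n_replicates >= 1)
  if (n_binders > 0 &&
      (max(tm_range) + delta_tm > max(temperatures) ||
       min(tm_range) + delta_tm < min(temperatures))) {
    warning("delta_tm moves melting midpoints outside the temperature span")
  }
  with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_proteins))
    tm <- stats::runif(n_proteins, tm_range[1], tm_range[2])
    b <- stats::runif(n_proteins, 8, 12)
    p <- stats::runif(n_proteins, 0.05, 0.2)
    binder <- seq_len(n_proteins) <= n_binders
    grid <- expand.grid(condition = c("vehicle", "treatment"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(n_proteins), function(i) {
      do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
        shift <- if (grid$condition[g] == "treatment" && binder[i]) delta_tm else 0
        mu <- melt_sigmoid(temperatures, a = b[i] * (tm[i] + shift), b = b[i], p = p[i])
        data.frame(protein_id = ids[i], condition = grid$condition[g],
                   replicate = grid$replicate[g], temperature = temperatures,
                   value = mu + stats::rnorm(length(temperatures), 0, noise_sd))
      }))
    })
    list(
      data = do.call(rbind, rows),
      truth = data.frame(protein_id = ids, is_binder = binder,
                         delta_tm = ifelse(binder, delta_tm, 0), tm_vehicle = tm)
    )
  })
}

#' Simulate a ligand-coupled-bead affinity purification
#'
#' Log2 intensities are Gaussian around a per-protein baseline; planted
#' enriched proteins are offset by `effect_log2fc` in the bait-bead
#' columns of one or both coupling orientations (chosen at random per
#' protein).
#'
#' @param n_proteins Number of proteins.
#' @param n_enriched Number of planted enriched proteins.
#' @param effect_log2fc Planted log2 fold-change over control beads.
#' @param noise_sd Per-column Gaussian noise on log2 intensities.
#' @param n_replicates Replicates per bead type (at least 2).
#' @param seed Integer seed.
#' @return List with `data` (an `ap_data` list for [ap_enrichment()]) and
#'   `truth` (`protein_id`, `enriched`, `coupling`).
#' @export
simulate_ap <- function(n_proteins, n_enriched, effect_log2fc, noise_sd,
                        n_replicates = 3L, seed = 1L) {
  stopifnot(n_enriched <= n_proteins, n_replicates >= 2, noise_sd >= 0)
  with_seed(seed, {
    ids <- sprintf("A%04d", seq_len(n_proteins))
    groups <- rep(c("bait_n", "bait_c", "control"), each = n_replicates)
    base <- stats::rnorm(n_proteins, mean = 25, sd = 2)
    m <- matrix(base, nrow = n_proteins, ncol = length(groups)) +
      matrix(stats::rnorm(n_proteins * length(groups), 0, noise_sd),
             nrow = n_proteins)
    enriched <- seq_len(n_proteins) <= n_enriched
    coupling <- rep(NA_character_, n_proteins)
    if (n_enriched > 0 && effect_log2fc != 0) {
      coupling[enriched] <- sample(c("n", "c", "both"), n_enriched, replace = TRUE)
    } else if (n_enriched > 0) {
      coupling[enriched] <- "both"
    }
    for (i in which(enriched)) {
      if (coupling[i] %in% c("n", "both")) {
        m[i, groups == "bait_n"] <- m[i, groups == "bait_n"] + effect_log2fc
      }
      if (coupling[i] %in% c("c", "both")) {
        m[i, groups == "bait_c"] <- m[i, groups == "bait_c"] + effect_log2fc
      }
    }
    rownames(m) <- ids
    colnames(m) <- paste(groups, rep(seq_len(n_replicates), times = 3), sep = "_")
    list(
      data = list(log2_intensities = m, groups = groups),
      truth = data.frame(protein_id = ids, enriched = enriched, coupling = coupling)
    )
  })
}
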