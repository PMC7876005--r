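# Affinity-purification enrichment and orthogonal-evidence intersection.

#' Enrichment analysis of an affinity-purification experiment
#'
#' The ligand is coupled to beads in two orientations (N-terminal and
#' C-terminal coupling); each coupling's eluates are compared against
#' control beads by a Welch (unequal-variance) two-sample t-test on log2
#' intensities, with Benjamini-Hochberg adjustment across proteins within
#' each coupling. A protein is called enriched when, in at least one
#' coupling (`combine = "union"`, the default) or in both
#' (`"intersection"`), its q-value is at most `alpha` and its log2
#' fold-change at least `min_log2fc`.
#'
#' @param ap_data List with `log2_intensities` (matrix, proteins x
#'   columns) and `groups` (character vector per column:
#'   `"bait_n"`, `"bait_c"`, `"control"`).
#' @param alpha q-value cutoff (default 0.05).
#' @param min_log2fc Minimum log2 fold-change over control (default 1).
#' @param combine `"union"` or `"intersection"` of the two couplings.
#' @return Data frame per protein: per-coupling `log2fc_*`, `p_*`, `q_*`,
#'   per-coupling enrichment flags and the combined `enriched` call.
#' @export
ap_enrichment <- function(ap_data, alpha = 0.05, min_log2fc = 1,
                          combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  m <- ap_data$log2_intensities
  groups <- ap_data$groups
  stopifnot(is.matrix(m), length(groups) == ncol(m),
            sum(groups == "control") >= 2)
  ctrl <- m[, groups == "control", drop = FALSE]
  res <- data.frame(protein_id = rownames(m))
  for (coup in c("bait_n", "bait_c")) {
    cols <- groups == coup
    tag <- sub("bait_", "", coup)
    if (sum(cols) < 2) {
      res[[paste0("log2fc_", tag)]] <- NA_real_
      res[[paste0("p_", tag)]] <- NA_real_
      res[[paste0("q_", tag)]] <- NA_real_
      res[[paste0("enriched_", tag)]] <- NA
      next
    }
    bait <- m[, cols, drop = FALSE]
    lfc <- rowMeans(bait) - rowMeans(ctrl)
    pv <- vapply(seq_len(nrow(m)), function(i) {
      if (stats::sd(bait[i, ]) == 0 && stats::sd(ctrl[i, ]) == 0) {
        if (abs(lfc[i]) < .Machine$double.eps^0.5) return(1)
        return(0)
      }
      stats::t.test(bait[i, ], ctrl[i, ], var.equal = FALSE)$p.value
    }, numeric(1))
    qv <- bh_adjust(pv)
    res[[paste0("log2fc_", tag)]] <- lfc
    res[[paste0("p_", tag)]] <- pv
    res[[paste0("q_", tag)]] <- qv
    res[[paste0("enriched_", tag)]] <- qv <= alpha & lfc >= min_log2fc
  }
  en <- cbind(res$enriched_n, res$enriched_c)
  res$enriched <- if (combine == "union") {
    apply(en, 1, function(z) isTRUE(any(z)))
  } else {
    apply(en, 1, function(z) isTRUE(all(z)))
  }
  res
}

#' Intersect the three lines of target evidence
#'
#' Combines the protein sets supported by SEC co-elution, affinity
#' purification and thermal proteome profiling into per-protein support
#' counts. Proteins supported by at least `min_support` strategies form
#' the interactome; proteins supported by all three are high-confidence
#' targets. The operation is symmetric in its three inputs.
#'
#' @param sec_targets,ap_targets,tpp_targets Character vectors of protein
#'   ids over one namespace.
#' @param min_support Minimum number of supporting strategies (default 2).
#' @return Data frame: `protein_id`, logical `sec`, `ap`, `tpp`,
#'   `support`, `interactome`, `high_confidence`.
#' @export
intersect_evidence <- function(sec_targets, ap_targets, tpp_targets,
                               min_support = 2L) {
  ids <- sort(unique(c(sec_targets, ap_targets, tpp_targets)))
  out <- data.frame(
    protein_id = ids,
    sec = ids %in% sec_targets,
    ap = ids %in% ap_targets,
    tpp = ids %in% tpp_targets
  )
  out$support <- rowSums(out[c("sec", "ap", "tpp")])
  out$interactome <- out$support >= min_support
  out$high_confidence <- out$support == 3L
  out
}
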