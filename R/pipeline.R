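# End-to-end orchestration: deconvolution -> calibration -> co-elution
# scoring -> ROC/FDR -> network, from a single seeded configuration, plus
# the one-command synthetic demo with a ground-truth comparison report.

#' Run the co-fractionation interaction pipeline
#'
#' Reads fraction tables, calibration references and a known-interaction
#' list, deconvolves elution profiles, assigns apparent masses, scores
#' metabolite-protein co-elution, selects the operating point on a ROC
#' curve against a seeded random-pair null, calls the interaction network
#' and persists every stage's output. Any stage failure aborts with the
#' stage name in the error.
#'
#' @param config Named list, or path to a YAML/JSON file with the same
#'   fields: `proteins` and `metabolites` (per-replicate TSV paths),
#'   `calibration` (TSV path), `known` (TSV path), `out_dir`, `seed`;
#'   optional `predicted` (TSV path), `protein_span` (default 38),
#'   `t_star` (default 0.7), `n_iterations` (default 100), `null_pairs`
#'   (default: size of the true set), `min_score_predicted` (default
#'   0.4), `min_replicated` (default 2) and `peak_params` (list passed to
#'   [peak_params()]).
#' @return Invisibly, a list with the stage objects (`dataset`, `cal`,
#'   `peak_set`, `pair_scores`, `roc`, `network`, `validated`, `summary`)
#'   and the written `paths`.
#' @export
run_cofrac <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  for (field in c("proteins", "metabolites", "calibration", "known", "out_dir", "seed")) {
    if (is.null(config[[field]])) {
      stop(sprintf("config field '%s' is missing", field))
    }
  }
  t_star <- config$t_star %||% 0.7
  n_iterations <- config$n_iterations %||% 100L
  protein_span <- config$protein_span %||% 38L
  pp <- do.call(peak_params, config$peak_params %||% list())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  dataset <- tryCatch(
    read_fraction_data(config$proteins, config$metabolites, protein_span),
    error = function(e) stop_stage("read_inputs", e))
  cal <- tryCatch(
    fit_calibration(read_calibration_table(config$calibration)),
    error = function(e) stop_stage("calibration", e))
  peak_set <- tryCatch(
    add_apparent_mass(
      deconvolve_dataset(dataset, pp, config$min_replicated %||% 2L), cal),
    error = function(e) stop_stage("deconvolution", e))
  scores <- tryCatch({
    candidates <- score_pairs(peak_set)
    pair_score(candidates)
  }, error = function(e) stop_stage("scoring", e))
  roc <- tryCatch({
    true_set <- build_true_set(read_pair_list(config$known), dataset)
    null <- sample_null(scores, dataset, true_set,
                        n_pairs = config$null_pairs %||% NULL,
                        n_iterations = n_iterations, seed = config$seed)
    roc_analysis(true_pair_scores(true_set, scores), null, t_star = t_star)
  }, error = function(e) stop_stage("roc", e))
  network <- tryCatch(
    call_interactions(scores, t_star),
    error = function(e) stop_stage("network", e))
  validated <- NULL
  if (!is.null(config$predicted)) {
    validated <- tryCatch(
      validate_predicted(network, read_pair_list(config$predicted),
                         config$min_score_predicted %||% 0.4),
      error = function(e) stop_stage("validate_predicted", e))
  }

  oligo <- tryCatch({
    pk <- peak_set$peaks[peak_set$peaks$kind == "protein", , drop = FALSE]
    mono <- dataset$features$monomeric_mass_da[
      match(pk$feature_id, dataset$features$feature_id)]
    classify_oligomeric(pk$feature_id, pk$apparent_mass_da, mono)
  }, error = function(e) stop_stage("oligomeric_state", e))

  summary <- list(
    seed = config$seed,
    n_proteins = sum(dataset$features$kind == "protein"),
    n_metabolites = sum(dataset$features$kind == "metabolite"),
    n_peaks = nrow(peak_set$peaks),
    n_protein_peaks = sum(peak_set$peaks$kind == "protein"),
    n_metabolite_peaks = sum(peak_set$peaks$kind == "metabolite"),
    mean_reproducibility = mean(peak_set$reproducibility$reproducibility, na.rm = TRUE),
    n_multimeric_peaks = sum(oligo$multimeric),
    t_star = t_star, auc = roc$auc,
    tpr_star = roc$tpr_star, fpr_star = roc$fpr_star,
    fdr = roc$fdr, fold_enrichment = roc$fold_enrichment,
    m_true = roc$m_true, m_null_bar = roc$m_null_bar,
    n_edges = nrow(network$edges),
    n_validated = if (is.null(validated)) NA else validated$n_interactions
  )

  paths <- list(
    peaks = write_tsv(peak_set$peaks, file.path(config$out_dir, "peaks.tsv")),
    pair_scores = write_tsv(scores, file.path(config$out_dir, "pair_scores.tsv")),
    roc_curve = write_tsv(roc$curve, file.path(config$out_dir, "roc_curve.tsv")),
    network = write_tsv(network$edges, file.path(config$out_dir, "network.tsv")),
    oligomeric = write_tsv(oligo, file.path(config$out_dir, "oligomeric_state.tsv")),
    summary = file.path(config$out_dir, "summary.json")
  )
  if (!is.null(validated)) {
    paths$validated <- write_tsv(validated$edges, file.path(config$out_dir, "validated.tsv"))
  }
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  invisible(list(dataset = dataset, cal = cal, peak_set = peak_set,
                 pair_scores = scores, roc = roc, network = network,
                 validated = validated, oligomeric = oligo,
                 summary = summary, paths = paths))
}

#' Run the standard synthetic benchmark end to end
#'
#' Generates the standard ground-truthed benchmark (see
#' [benchmark_config()]), writes its input tables, runs the full pipeline
#' on the files, and compares the called network against the planted
#' truth: sensitivity (planted pairs recovered at the operating
#' threshold), realized FDR (called edges that were not planted, with
#' edges explained by a planted complex sharing the partner's elution
#' flagged separately) and the null-based estimated FDR.
#'
#' @param seed Integer seed driving simulation and null sampling.
#' @param out_dir Output directory; defaults to a fresh temporary
#'   directory.
#' @param config A `sim_config`; defaults to the standard benchmark at
#'   `seed`.
#' @return Invisibly, a list with `report` (named numbers summarizing the
#'   ground-truth comparison), `run` (the [run_cofrac()] result),
#'   `truth`, and `paths`.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, config = NULL) {
  config <- config %||% benchmark_config(seed)
  out_dir <- out_dir %||% file.path(tempfile("cofrac_demo_"))
  in_dir <- file.path(out_dir, "inputs")
  res_dir <- file.path(out_dir, "results")
  sim <- simulate_fractionation(config)
  paths <- write_fraction_tables(sim$dataset, in_dir, truth = sim$truth)
  refs <- generate_calibration_refs(6, config$mass_range, c(1, config$protein_span))
  cal_path <- file.path(in_dir, "calibration.tsv")
  utils::write.table(refs, cal_path, sep = "\t", quote = FALSE, row.names = FALSE)

  run <- run_cofrac(list(
    proteins = paths$proteins, metabolites = paths$metabolites,
    calibration = cal_path, known = paths$known,
    out_dir = res_dir, seed = seed, protein_span = config$protein_span
  ))

  planted <- paste(sim$truth$pmis$metabolite_id, sim$truth$pmis$protein_id, sep = "\r")
  called <- paste(run$network$edges$metabolite_id, run$network$edges$protein_id, sep = "\r")
  hits <- called %in% planted
  # edges explained by a planted complex: the protein shares a complex with
  # the metabolite's planted partner, so it co-elutes by construction
  cpx_of <- split(sim$truth$complexes$complex_id, sim$truth$complexes$protein_id)
  partner_of <- split(sim$truth$pmis$protein_id, sim$truth$pmis$metabolite_id)
  artifact <- vapply(seq_len(nrow(run$network$edges)), function(i) {
    if (hits[i]) return(FALSE)
    met <- run$network$edges$metabolite_id[i]
    prot <- run$network$edges$protein_id[i]
    partners <- partner_of[[met]] %||% character()
    any(vapply(partners, function(p) {
      length(intersect(cpx_of[[p]] %||% character(),
                       cpx_of[[prot]] %||% character())) > 0
    }, logical(1)))
  }, logical(1))

  n_edges <- nrow(run$network$edges)
  sensitivity <- sum(hits) / nrow(sim$truth$pmis)
  realized_fdr <- if (n_edges == 0) NA_real_ else sum(!hits) / n_edges
  report <- list(
    seed = seed,
    n_planted = nrow(sim$truth$pmis),
    n_edges = n_edges,
    n_recovered = sum(hits),
    n_false = sum(!hits),
    n_complex_artifacts = sum(artifact),
    sensitivity = sensitivity,
    realized_fdr = realized_fdr,
    estimated_fdr = run$roc$fdr,
    auc = run$roc$auc,
    fold_enrichment = run$roc$fold_enrichment
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(report = report, run = run, truth = sim$truth,
                 paths = c(run$paths, list(report = report_path))))
}
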