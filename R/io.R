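# Reading and writing the pipeline's TSV dialects.
#
# Fraction tables: one feature per row, first column `feature_id`, an
# optional `monomeric_mass_da` column for proteins, remaining columns one
# fraction each in elution order; replicates live in separate files.
# Pair lists (known/predicted interactions): `chemical_id`, `protein_id`,
# optional `score`. Calibration: `fraction`, `mass_da`.

#' Read a single-replicate fraction table
#'
#' @param path TSV file path.
#' @param kind `"protein"` or `"metabolite"`.
#' @return List of class `fraction_table`: `intensities` (matrix features
#'   x fractions), `features` (data frame `feature_id`, `kind`,
#'   `monomeric_mass_da`), `fraction_labels`.
#' @export
read_fraction_table <- function(path, kind = c("protein", "metabolite")) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(raw)) {
    stop(sprintf("%s: first column must be 'feature_id'", path))
  }
  dup <- duplicated(raw$feature_id)
  if (any(dup)) {
    stop(sprintf("%s: duplicate feature ids: %s", path,
                 paste(unique(raw$feature_id[dup]), collapse = ", ")))
  }
  mono <- if ("monomeric_mass_da" %in% names(raw)) raw$monomeric_mass_da else
    rep(NA_real_, nrow(raw))
  frac_cols <- setdiff(names(raw), c("feature_id", "monomeric_mass_da"))
  if (length(frac_cols) < 2) stop(sprintf("%s: no fraction columns found", path))
  m <- as.matrix(raw[frac_cols])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric intensity values", path))
  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: negative or missing intensity for feature '%s' in fraction '%s'",
                 path, raw$feature_id[bad[1, 1]], frac_cols[bad[1, 2]]))
  }
  rownames(m) <- raw$feature_id
  structure(list(
    intensities = m,
    features = data.frame(feature_id = raw$feature_id, kind = kind,
                          monomeric_mass_da = mono),
    fraction_labels = frac_cols
  ), class = "fraction_table")
}

#' Assemble a fractionation dataset from per-replicate tables
#'
#' @param protein_paths,metabolite_paths Character vectors of TSV paths,
#'   one file per replicate, fraction order identical across files.
#' @param protein_span Number of leading protein-containing fractions.
#' @return A `fractionation_dataset`.
#' @export
read_fraction_data <- function(protein_paths, metabolite_paths, protein_span = 38L) {
  stopifnot(length(protein_paths) >= 1, length(metabolite_paths) >= 1,
            length(protein_paths) == length(metabolite_paths))
  prot <- lapply(protein_paths, read_fraction_table, kind = "protein")
  met <- lapply(metabolite_paths, read_fraction_table, kind = "metabolite")
  labels <- prot[[1]]$fraction_labels
  for (tab in c(prot, met)) {
    if (!identical(tab$fraction_labels, labels)) {
      stop("fraction columns differ across replicate files")
    }
  }
  for (tabs in list(prot, met)) {
    ids <- tabs[[1]]$features$feature_id
    for (tab in tabs) {
      if (!identical(tab$features$feature_id, ids)) {
        stop("feature ids differ across replicate files")
      }
    }
  }
  features <- rbind(prot[[1]]$features, met[[1]]$features)
  replicates <- lapply(seq_along(prot), function(r) {
    rbind(prot[[r]]$intensities, met[[r]]$intensities)
  })
  names(replicates) <- sprintf("rep%d", seq_along(replicates))
  if (protein_span > length(labels)) {
    stop("protein_span exceeds the number of fractions")
  }
  structure(list(
    replicates = replicates,
    features = features,
    fraction_labels = labels,
    n_fractions = length(labels),
    protein_span = as.integer(protein_span)
  ), class = "fractionation_dataset")
}

#' Write a fractionation dataset as per-replicate TSV tables
#'
#' Produces the same dialect [read_fraction_table()] consumes, one
#' proteins and one metabolites file per replicate, plus the ground-truth
#' pair list when a `sim_truth` is supplied.
#'
#' @param dataset A `fractionation_dataset`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `sim_truth`; its planted PMIs are written as
#'   `known_pmis.tsv`.
#' @return Named list of written paths (`proteins`, `metabolites`,
#'   optionally `known`).
#' @export
write_fraction_tables <- function(dataset, dir, truth = NULL) {
  stopifnot(inherits(dataset, "fractionation_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- split(dataset$features, dataset$features$kind)
  paths <- list(proteins = character(), metabolites = character())
  for (r in seq_along(dataset$replicates)) {
    for (kind in names(kinds)) {
      ids <- kinds[[kind]]$feature_id
      df <- data.frame(feature_id = ids, check.names = FALSE)
      if (kind == "protein") df$monomeric_mass_da <- kinds[[kind]]$monomeric_mass_da
      df <- cbind(df, as.data.frame(dataset$replicates[[r]][ids, , drop = FALSE],
                                    check.names = FALSE))
      path <- file.path(dir, sprintf("%ss_rep%d.tsv", kind, r))
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      slot <- paste0(kind, "s")
      paths[[slot]] <- c(paths[[slot]], path)
    }
  }
  if (!is.null(truth)) {
    known <- data.frame(chemical_id = truth$pmis$metabolite_id,
                        protein_id = truth$pmis$protein_id)
    paths$known <- file.path(dir, "known_pmis.tsv")
    utils::write.table(known, paths$known, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}

#' Read a chemical-protein pair list
#'
#' @param path TSV with columns `chemical_id`, `protein_id`, optional
#'   `score` (STITCH-export-like).
#' @return Data frame.
#' @export
read_pair_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chemical_id", "protein_id") %in% names(df))) {
    stop(sprintf("%s: pair list needs 'chemical_id' and 'protein_id' columns", path))
  }
  df
}

#' Read a calibration reference table
#'
#' @param path TSV with columns `fraction`, `mass_da`.
#' @return Data frame.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("fraction", "mass_da") %in% names(df))) {
    stop(sprintf("%s: calibration table needs 'fraction' and 'mass_da' columns", path))
  }
  df
}

# Deterministic TSV writers for pipeline outputs.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
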