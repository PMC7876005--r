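# Ground-truthed synthetic size-exclusion co-fractionation data.
#
# The generator emulates a PROMIS-style experiment: native complexes run
# over an SEC column, 48 one-fraction cuts of which the first 38 contain
# proteins (about 5.2 MDa down to 20 kDa), three biological replicates,
# and parallel proteomics/metabolomics intensity tables. Elution peaks are
# Gaussian in fraction coordinates; replicate intensities carry
# multiplicative lognormal noise.
#
# Identifiability: two Gaussian peaks of width 1.5 fractions correlate
# above 0.7 whenever their centers are within ~1.6 fractions, so a
# benchmark in which unrelated protein peaks may fall arbitrarily close to
# a planted metabolite peak has no well-defined ground truth - no
# co-elution method could reject those chance co-elutions. Planted
# interaction neighbourhoods are therefore kept clear of unrelated peaks
# (see `min_clearance`), and planted PMIs are grouped: one planted
# metabolite co-elutes with several partner proteins at a single cleared
# center, mirroring the expectation that a single metabolite peak often
# corresponds to multiple protein partners.

#' Simulation configuration for a synthetic co-fractionation run
#'
#' Collects and validates every knob of [simulate_fractionation()]. The
#' defaults are the study conditions the pipeline is benchmarked under:
#' 48 fractions of which the first 38 contain proteins, three biological
#' replicates, Gaussian elution peaks of width `sigma = 1.5` fractions and
#' a calibration span of 5.2 MDa to 20 kDa.
#'
#' Planted protein-metabolite interactions (PMIs) place a metabolite
#' "bound" peak exactly on a dedicated elution peak of its partner
#' protein(s). Planted pairs are grouped by metabolite: each planted
#' metabolite receives up to `pmi_partners` partner proteins, all
#' co-eluting at the metabolite's target center. So that the planted truth
#' stays identifiable, target centers are mutually separated and given a
#' clearance window (`min_clearance` fractions) that unrelated protein
#' peaks may not enter; metabolites without a planted partner elute only
#' in the post-protein ("free pool") fractions.
#'
#' @param n_proteins,n_metabolites Feature counts.
#' @param n_planted Number of planted PMIs (metabolite-protein pairs), or a
#'   data frame with columns `metabolite_id`, `protein_id` naming the pairs
#'   explicitly (ids must exist given the counts above; pairs sharing a
#'   metabolite share its target center).
#' @param pmi_partners Maximum partner proteins per planted metabolite
#'   (default 4) when `n_planted` is a count.
#' @param complexes Number of planted protein complexes (members are drawn
#'   from proteins not used as PMI partners), or a data frame with columns
#'   `complex_id`, `protein_id`, `mass_da`.
#' @param n_fractions Total fractions collected.
#' @param protein_span Number of leading fractions that contain proteins;
#'   scoring and deconvolution are restricted to this span.
#' @param n_replicates Biological replicates.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise (0 = noiseless).
#' @param free_pool_fraction Proportion of a planted metabolite's signal
#'   placed in the free (post-protein) fractions.
#' @param sigma Gaussian peak width, in fractions.
#' @param p_two_peak Probability that a protein elutes with a second peak.
#' @param min_separation Minimum separation between two peaks of the same
#'   feature, in fractions.
#' @param min_clearance Clearance kept between planted PMI target centers
#'   and unrelated protein peaks, in fractions; planted and complex
#'   centers are mutually separated by at least `min_clearance + 0.5`.
#' @param mass_range Masses (Da) at the first and last protein-containing
#'   fraction; defines the log-linear calibration line.
#' @param intensity_floor Intensities below this value are censored to zero
#'   (MS-like missingness); 0 disables censoring.
#' @param seed Integer seed; identical configurations and seeds yield
#'   identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins,
                       n_metabolites,
                       n_planted = 0,
                       pmi_partners = 4L,
                       complexes = 0,
                       n_fractions = 48L,
                       protein_span = 38L,
                       n_replicates = 3L,
                       noise_cv = 0.15,
                       free_pool_fraction = 0.3,
                       sigma = 1.5,
                       p_two_peak = 0.4,
                       min_separation = 6,
                       min_clearance = 2.5,
                       mass_range = c(5.2e6, 2e4),
                       intensity_floor = 0,
                       seed = 1L) {
  stopifnot(
    n_proteins >= 1, n_metabolites >= 0,
    n_fractions >= protein_span, protein_span >= 4,
    n_replicates >= 1, noise_cv >= 0, sigma > 0,
    free_pool_fraction >= 0, free_pool_fraction <= 1,
    length(mass_range) == 2, all(mass_range > 0),
    mass_range[1] > mass_range[2]
  )
  if (is.data.frame(n_planted)) {
    stopifnot(all(c("metabolite_id", "protein_id") %in% names(n_planted)))
  } else {
    stopifnot(n_planted >= 0, n_planted <= n_metabolites, n_planted <= n_proteins)
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_metabolites = as.integer(n_metabolites),
    n_planted = n_planted,
    pmi_partners = as.integer(pmi_partners),
    complexes = complexes,
    n_fractions = as.integer(n_fractions),
    protein_span = as.integer(protein_span),
    n_replicates = as.integer(n_replicates),
    noise_cv = noise_cv,
    free_pool_fraction = free_pool_fraction,
    sigma = sigma,
    p_two_peak = p_two_peak,
    min_separation = min_separation,
    min_clearance = min_clearance,
    mass_range = mass_range,
    intensity_floor = intensity_floor,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Standard synthetic benchmark configuration
#'
#' The fixed benchmark the pipeline is validated on: 200 proteins, 30
#' metabolites, 20 planted PMIs, 5 planted complexes, 3 replicates and 15%
#' intensity noise over a 48-fraction run with a 38-fraction protein span.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
benchmark_config <- function(seed = 1L, ...) {
  sim_config(
    n_proteins = 200, n_metabolites = 30, n_planted = 20,
    complexes = 5, noise_cv = 0.15, seed = seed, ...
  )
}

# Log-linear calibration line through the span endpoints:
# log10(mass) = slope * fraction + intercept.
cal_line <- function(mass_range, span = c(1, 38)) {
  slope <- (log10(mass_range[2]) - log10(mass_range[1])) / (span[2] - span[1])
  intercept <- log10(mass_range[1]) - slope * span[1]
  list(slope = slope, intercept = intercept)
}

cal_mass_at <- function(fraction, line) 10^(line$slope * fraction + line$intercept)
cal_fraction_of <- function(mass, line) (log10(mass) - line$intercept) / line$slope

#' Generate reference-protein calibration points
#'
#' Reference points lie exactly on the log-linear mass-versus-fraction line
#' through the endpoints of `mass_range`, with optional lognormal mass
#' noise. Used to emulate the set of known-mass standards a molecular
#' weight calibration is fitted to.
#'
#' @param n_refs Number of reference proteins (at least 2).
#' @param mass_range Masses (Da) at the first and last fraction of `span`,
#'   decreasing.
#' @param span Fraction index range covered by the references.
#' @param noise_sd Standard deviation of Gaussian noise added on log10 mass
#'   (0 = exact line).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return Data frame with columns `fraction`, `mass_da`.
#' @export
generate_calibration_refs <- function(n_refs, mass_range = c(5.2e6, 2e4),
                                      span = c(1, 38), noise_sd = 0, seed = 1L) {
  if (n_refs < 2) {
    stop("at least 2 reference proteins are required to determine the calibration line")
  }
  stopifnot(length(mass_range) == 2, all(mass_range > 0), mass_range[1] > mass_range[2],
            length(span) == 2, span[2] > span[1])
  line <- cal_line(mass_range, span)
  fraction <- seq(span[1], span[2], length.out = n_refs)
  log_mass <- line$slope * fraction + line$intercept
  if (noise_sd > 0) {
    log_mass <- with_seed(seed, log_mass + stats::rnorm(n_refs, 0, noise_sd))
  }
  data.frame(fraction = fraction, mass_da = 10^log_mass)
}

# Rejection-sample a peak center in [lo, hi] keeping `clearance` fractions
# away from every reserved center and `own_sep` from the feature's own peaks.
draw_center <- function(lo, hi, reserved = numeric(), clearance = 0,
                        own = numeric(), own_sep = 0, max_tries = 5000L) {
  for (i in seq_len(max_tries)) {
    x <- stats::runif(1, lo, hi)
    ok <- (length(reserved) == 0 || all(abs(x - reserved) >= clearance)) &&
      (length(own) == 0 || all(abs(x - own) >= own_sep))
    if (ok) return(x)
  }
  stop("could not place a peak center honouring the clearance constraints; ",
       "reduce feature density or clearance")
}

#' Simulate a co-fractionation dataset with planted ground truth
#'
#' Builds protein and metabolite elution profiles over the configured
#' fraction grid: every protein receives 1-2 Gaussian peaks, members of a
#' planted complex share a peak at the fraction implied by the complex mass
#' through the calibration line, and each planted PMI metabolite receives a
#' bound peak exactly co-located (pre-noise) with a dedicated partner peak,
#' plus an optional free-pool peak beyond the protein span. Replicates are
#' perturbed by multiplicative lognormal noise at the configured CV.
#'
#' @param config A [sim_config()].
#' @return List with elements `dataset` (class `fractionation_dataset`) and
#'   `truth` (class `sim_truth`: planted PMIs, complexes, all generating
#'   peaks, and per-protein oligomeric state).
#' @export
simulate_fractionation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_fractionation_impl(config))
}

simulate_fractionation_impl <- function(cfg) {
  span <- cfg$protein_span
  line <- cal_line(cfg$mass_range, c(1, span))
  center_lo <- 3
  center_hi <- span - 2

  protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  metabolite_ids <- sprintf("M%03d", seq_len(cfg$n_metabolites))

  slot_min <- cfg$min_clearance + 0.5  # spacing among planted/complex centers

  ## -- planted complexes and PMI groups -------------------------------------
  # Centers that anchor ground truth (complex positions, PMI target peaks)
  # are laid out on a jittered even grid so they keep `slot_min` mutual
  # separation; unrelated protein peaks are later kept `min_clearance` away
  # from the PMI centers only.
  explicit_cpx <- is.data.frame(cfg$complexes)
  if (explicit_cpx) {
    complexes <- cfg$complexes
    stopifnot(all(c("complex_id", "protein_id", "mass_da") %in% names(complexes)))
    if (!all(complexes$protein_id %in% protein_ids)) {
      stop("complex membership references unknown protein ids")
    }
    n_cpx <- length(unique(complexes$complex_id))
  } else {
    n_cpx <- as.integer(cfg$complexes)
  }

  if (is.data.frame(cfg$n_planted)) {
    pmis <- cfg$n_planted[c("metabolite_id", "protein_id")]
    if (!all(pmis$metabolite_id %in% metabolite_ids) ||
        !all(pmis$protein_id %in% protein_ids)) {
      stop("planted PMI references unknown feature ids")
    }
    group_mets <- unique(pmis$metabolite_id)
  } else if (cfg$n_planted > 0) {
    n_groups <- ceiling(cfg$n_planted / cfg$pmi_partners)
    group_mets <- sample(metabolite_ids, n_groups)
    eligible <- if (explicit_cpx) setdiff(protein_ids, cfg$complexes$protein_id) else
      protein_ids[seq_len(cfg$n_proteins - 3L * n_cpx)]  # complex members from the tail
    if (length(eligible) < cfg$n_planted) {
      stop("not enough non-complex proteins for the planted PMIs")
    }
    partners <- sample(eligible, cfg$n_planted)
    pmis <- data.frame(
      metabolite_id = rep(group_mets, length.out = cfg$n_planted)[
        order(rep(seq_along(group_mets), length.out = cfg$n_planted))],
      protein_id = partners
    )
  } else {
    pmis <- data.frame(metabolite_id = character(), protein_id = character())
    group_mets <- character()
  }
  n_groups <- length(group_mets)

  # joint placement of complex and PMI-group centers
  place_slots <- function(n) {
    if (n == 0) return(numeric())
    if (n == 1) return(stats::runif(1, center_lo, center_hi))
    spacing <- (center_hi - center_lo) / (n - 1)
    if (spacing < slot_min) {
      stop("too many planted complexes/PMI groups for the clearance constraints; ",
           "reduce their number or min_clearance")
    }
    jitter <- min((spacing - slot_min) / 2, 0.5)
    pos <- seq(center_lo, center_hi, length.out = n) +
      stats::runif(n, -jitter, jitter)
    sample(pos)
  }

  if (explicit_cpx) {
    cpx_info <- unique(complexes[c("complex_id", "mass_da")])
    cpx_info$center <- cal_fraction_of(cpx_info$mass_da, line)
    if (any(cpx_info$center < center_lo | cpx_info$center > center_hi)) {
      stop("complex mass outside the calibrated fraction range")
    }
    group_centers <- numeric(n_groups)
    taken <- cpx_info$center
    for (g in seq_len(n_groups)) {
      group_centers[g] <- draw_center(center_lo, center_hi, taken, slot_min)
      taken <- c(taken, group_centers[g])
    }
  } else {
    slots <- place_slots(n_cpx + n_groups)
    cpx_centers <- slots[seq_len(n_cpx)]
    group_centers <- slots[n_cpx + seq_len(n_groups)]
    if (n_cpx > 0) {
      sizes <- sample(2:3, n_cpx, replace = TRUE)
      members <- rev(protein_ids)[seq_len(sum(sizes))]
      complexes <- data.frame(
        complex_id = rep(sprintf("CPX%02d", seq_len(n_cpx)), sizes),
        protein_id = members,
        mass_da = rep(cal_mass_at(cpx_centers, line), sizes)
      )
      cpx_info <- data.frame(complex_id = sprintf("CPX%02d", seq_len(n_cpx)),
                             mass_da = cal_mass_at(cpx_centers, line),
                             center = cpx_centers)
    } else {
      complexes <- data.frame(complex_id = character(), protein_id = character(),
                              mass_da = numeric())
      cpx_info <- data.frame(complex_id = character(), mass_da = numeric(),
                             center = numeric())
    }
  }
  complexes <- merge(complexes, cpx_info, by = c("complex_id", "mass_da"), sort = FALSE)
  cpx_members <- table(complexes$complex_id)

  pmis$center <- group_centers[match(pmis$metabolite_id, group_mets)]
  planted_centers <- group_centers

  ## -- protein peaks --------------------------------------------------------
  peaks <- vector("list", cfg$n_proteins + cfg$n_metabolites)
  oligo <- data.frame(protein_id = protein_ids, monomeric_mass_da = NA_real_,
                      true_factor = NA_real_)
  for (i in seq_len(cfg$n_proteins)) {
    id <- protein_ids[i]
    centers <- numeric()
    in_cpx <- complexes$protein_id == id
    if (any(in_cpx)) {
      centers <- complexes$center[in_cpx][1]
      factor <- as.numeric(cpx_members[complexes$complex_id[in_cpx][1]])
      mono <- complexes$mass_da[in_cpx][1] / factor
    } else if (id %in% pmis$protein_id) {
      centers <- pmis$center[match(id, pmis$protein_id)]
      factor <- sample(c(1, 2, 4), 1, prob = c(0.5, 0.3, 0.2))
      mono <- cal_mass_at(centers[1], line) / factor
    } else {
      centers <- draw_center(center_lo, center_hi, planted_centers, cfg$min_clearance)
      factor <- sample(c(1, 2, 4), 1, prob = c(0.5, 0.3, 0.2))
      mono <- cal_mass_at(centers[1], line) / factor
    }
    if (stats::runif(1) < cfg$p_two_peak) {
      extra <- try(draw_center(center_lo, center_hi, planted_centers,
                               cfg$min_clearance, own = centers,
                               own_sep = cfg$min_separation), silent = TRUE)
      if (!inherits(extra, "try-error")) centers <- c(centers, extra)
    }
    amps <- c(1, stats::runif(length(centers) - 1, 0.4, 0.9))
    peaks[[i]] <- data.frame(feature_id = id, kind = "protein",
                             center = centers, sigma = cfg$sigma, rel_amplitude = amps)
    oligo$monomeric_mass_da[i] <- mono
    oligo$true_factor[i] <- factor
  }

  ## -- metabolite peaks -----------------------------------------------------
  free_lo <- min(span + 2, cfg$n_fractions)
  free_hi <- max(free_lo, cfg$n_fractions - 1)
  has_free_zone <- cfg$n_fractions > span + 2
  for (j in seq_len(cfg$n_metabolites)) {
    id <- metabolite_ids[j]
    planted_at <- unique(pmis$center[pmis$metabolite_id == id])
    rows <- NULL
    if (length(planted_at)) {
      bound_amp <- if (has_free_zone) 1 - cfg$free_pool_fraction else 1
      rows <- data.frame(feature_id = id, kind = "metabolite",
                         center = planted_at, sigma = cfg$sigma,
                         rel_amplitude = bound_amp / length(planted_at))
      if (has_free_zone && cfg$free_pool_fraction > 0) {
        rows <- rbind(rows, data.frame(
          feature_id = id, kind = "metabolite",
          center = stats::runif(1, free_lo, free_hi), sigma = cfg$sigma,
          rel_amplitude = cfg$free_pool_fraction
        ))
      }
    } else if (has_free_zone) {
      rows <- data.frame(feature_id = id, kind = "metabolite",
                         center = stats::runif(1, free_lo, free_hi),
                         sigma = cfg$sigma, rel_amplitude = 1)
    }
    peaks[[cfg$n_proteins + j]] <- rows
  }
  peak_table <- do.call(rbind, peaks)

  ## -- intensity matrices ---------------------------------------------------
  feature_ids <- c(protein_ids, metabolite_ids)
  base_intensity <- 10^stats::runif(length(feature_ids), 6.5, 8.5)
  names(base_intensity) <- feature_ids
  x <- seq_len(cfg$n_fractions)
  clean <- matrix(0, nrow = length(feature_ids), ncol = cfg$n_fractions,
                  dimnames = list(feature_ids, sprintf("F%02d", x)))
  for (k in seq_len(nrow(peak_table))) {
    id <- peak_table$feature_id[k]
    clean[id, ] <- clean[id, ] + base_intensity[id] * peak_table$rel_amplitude[k] *
      exp(-(x - peak_table$center[k])^2 / (2 * peak_table$sigma[k]^2))
  }

  replicates <- lapply(seq_len(cfg$n_replicates), function(r) {
    m <- clean * matrix(lognormal_factors(length(clean), cfg$noise_cv),
                        nrow = nrow(clean))
    if (cfg$intensity_floor > 0) m[m < cfg$intensity_floor] <- 0
    dimnames(m) <- dimnames(clean)
    m
  })
  names(replicates) <- sprintf("rep%d", seq_len(cfg$n_replicates))

  features <- data.frame(
    feature_id = feature_ids,
    kind = c(rep("protein", cfg$n_proteins), rep("metabolite", cfg$n_metabolites)),
    monomeric_mass_da = c(oligo$monomeric_mass_da, rep(NA_real_, cfg$n_metabolites))
  )

  dataset <- structure(list(
    replicates = replicates,
    features = features,
    fraction_labels = colnames(clean),
    n_fractions = cfg$n_fractions,
    protein_span = cfg$protein_span
  ), class = "fractionation_dataset")

  truth <- structure(list(
    pmis = pmis,
    complexes = complexes,
    peaks = peak_table,
    oligomers = oligo,
    config = cfg
  ), class = "sim_truth")

  list(dataset = dataset, truth = truth)
}

#' @export
print.fractionation_dataset <- function(x, ...) {
  cat(sprintf(
    "<fractionation_dataset> %d proteins + %d metabolites x %d fractions (%d protein-containing), %d replicate(s)\n",
    sum(x$features$kind == "protein"), sum(x$features$kind == "metabolite"),
    x$n_fractions, x$protein_span, length(x$replicates)
  ))
  invisible(x)
}
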