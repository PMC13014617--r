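# Synthetic coupled abundance/production cohorts with known ground truth.
# The generator embodies the premise the scoring method rests on: metabolite
# change tracks the abundance change of its producing species.

#' Specify a synthetic cohort simulation
#'
#' Parameters of the generator. Defaults are the strong-signal study
#' conditions used throughout the package's validation: 50 species, 20
#' metabolites, 20 samples per arm, production density 0.2, 10 affected
#' species with a log-scale effect of 2, and log-normal per-sample noise of
#' sd 0.5.
#'
#' @param n_species,n_metabolites Numbers of species and metabolites.
#' @param n_samples_disease,n_samples_healthy Samples per cohort arm.
#' @param production_density Probability that a given species produces a
#'   given metabolite (independent coin flips).
#' @param n_affected_species Number of species whose disease-cohort mean is
#'   shifted.
#' @param effect_size Magnitude of the planted log-scale shift; each affected
#'   species receives a random sign.
#' @param noise_sd Standard deviation of the per-sample log-normal noise.
#' @param baseline_log_sd Spread of the per-species baseline log abundances;
#'   the default 1.5 spans roughly three orders of magnitude across species,
#'   as species-level gut profiles do.
#' @param dropout Probability that a (species, sample) observation is zeroed
#'   before closure (optional zero-inflation; default 0).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(n_species = 50L, n_metabolites = 20L,
                            n_samples_disease = 20L, n_samples_healthy = 20L,
                            production_density = 0.2,
                            n_affected_species = 10L, effect_size = 2,
                            noise_sd = 0.5, baseline_log_sd = 1.5,
                            dropout = 0, seed = 1L) {
  spec <- list(n_species = as.integer(n_species),
               n_metabolites = as.integer(n_metabolites),
               n_samples_disease = as.integer(n_samples_disease),
               n_samples_healthy = as.integer(n_samples_healthy),
               production_density = production_density,
               n_affected_species = as.integer(n_affected_species),
               effect_size = effect_size, noise_sd = noise_sd,
               baseline_log_sd = baseline_log_sd,
               dropout = dropout, seed = as.integer(seed))
  with(spec, stopifnot(
    n_species >= 1L, n_metabolites >= 1L,
    n_samples_disease >= 1L, n_samples_healthy >= 1L,
    production_density > 0, production_density < 1,
    n_affected_species >= 0L, n_affected_species <= n_species,
    is.finite(effect_size), noise_sd > 0, baseline_log_sd >= 0,
    dropout >= 0, dropout < 1))
  structure(spec, class = "simulation_spec")
}

pad_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))
}

#' Generate a synthetic disease/healthy cohort with known truth
#'
#' Draws per-species baseline log abundances once, adds the planted log-scale
#' effect to the affected species in the disease arm, adds independent
#' log-normal per-sample noise, optionally zeroes observations at the dropout
#' rate, and renormalizes every sample to sum to one (compositional closure).
#' The production map is drawn as independent coin flips at
#' \code{production_density}. Ground truth is computed from the realized
#' post-closure medians — the per-metabolite expected direction is the sign of
#' the sum, over its producers, of the realized median abundance change — so
#' recovery statements about the generated data are exact rather than
#' asymptotic. Pre-closure medians are also recorded for construction checks.
#'
#' @param spec A [simulation_spec()].
#' @param disease_id Label used for the single simulated disease.
#' @return A list of class \code{"synthetic_cohort"} with components
#'   \code{samples} (per-sample abundance table), \code{production}
#'   (species-rank production map) and \code{truth} (class
#'   \code{"synthetic_truth"}: per-species and per-metabolite tables).
#' @examples
#' sim <- generate_cohort(simulation_spec(n_species = 10, n_metabolites = 4,
#'                                        n_samples_disease = 5,
#'                                        n_samples_healthy = 5, seed = 42))
#' head(sim$samples)
#' sim$truth$metabolites
#' @export
generate_cohort <- function(spec, disease_id = "D1") {
  stopifnot(inherits(spec, "simulation_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  species <- pad_ids("sp", spec$n_species)
  mets <- pad_ids("met", spec$n_metabolites)
  dz_samples <- pad_ids("dz", spec$n_samples_disease)
  hl_samples <- pad_ids("hc", spec$n_samples_healthy)

  baseline <- stats::rnorm(spec$n_species, 0, spec$baseline_log_sd)
  affected_idx <- if (spec$n_affected_species > 0L) {
    sort(sample.int(spec$n_species, spec$n_affected_species))
  } else integer(0)
  effect_sign <- integer(spec$n_species)
  effect_sign[affected_idx] <- sample(c(-1L, 1L), length(affected_idx),
                                      replace = TRUE)
  shift <- effect_sign * spec$effect_size

  draw <- function(n_samples, shifted) {
    mu <- baseline + if (shifted) shift else 0
    m <- exp(matrix(stats::rnorm(spec$n_species * n_samples, 0,
                                 spec$noise_sd),
                    nrow = spec$n_species) + mu)
    if (spec$dropout > 0) {
      m[matrix(stats::runif(length(m)) < spec$dropout,
               nrow = spec$n_species)] <- 0
    }
    m
  }
  raw_d <- draw(spec$n_samples_disease, shifted = TRUE)
  raw_h <- draw(spec$n_samples_healthy, shifted = FALSE)
  closed_d <- sweep(raw_d, 2L, colSums(raw_d), "/")
  closed_h <- sweep(raw_h, 2L, colSums(raw_h), "/")

  production <- matrix(stats::runif(spec$n_species * spec$n_metabolites) <
                         spec$production_density,
                       nrow = spec$n_species,
                       dimnames = list(species, mets))

  to_rows <- function(m, cohort, sample_ids) {
    data.frame(cohort = cohort,
               disease_id = disease_id,
               sample_id = rep(sample_ids, each = spec$n_species),
               species_id = rep(species, times = length(sample_ids)),
               relative_abundance = as.vector(m),
               stringsAsFactors = FALSE)
  }
  samples <- rbind(to_rows(closed_d, "disease", dz_samples),
                   to_rows(closed_h, "healthy", hl_samples))
  samples <- samples[samples$relative_abundance > 0, , drop = FALSE]
  rownames(samples) <- NULL

  med <- function(m) apply(m, 1L, stats::median)
  species_truth <- data.frame(
    species_id = species,
    affected = seq_len(spec$n_species) %in% affected_idx,
    effect_sign = effect_sign,
    delta_pre = med(raw_d) - med(raw_h),
    delta_post = med(closed_d) - med(closed_h),
    stringsAsFactors = FALSE)

  # nominal (planted) per-species change in the noise-free closed
  # composition: what the planted effects alone imply for relative
  # abundance, independent of the realized noise
  nominal_delta <- exp(baseline + shift) / sum(exp(baseline + shift)) -
    exp(baseline) / sum(exp(baseline))
  met_truth <- do.call(rbind, lapply(mets, function(m) {
    producers_mask <- production[, m]
    producers <- species[producers_mask]
    s <- sum(species_truth$delta_post[match(producers,
                                            species_truth$species_id)])
    nom <- sum(nominal_delta[producers_mask])
    data.frame(metabolite_id = m,
               n_producers = length(producers),
               n_affected_producers = sum(producers %in%
                                            species[affected_idx]),
               expected_sum = if (length(producers)) s else NA_real_,
               direction = if (!length(producers)) "null"
                           else score_direction(s),
               planted_sum = if (length(producers)) nom else NA_real_,
               planted_direction = if (!length(producers)) "null"
                                   else score_direction(nom),
               stringsAsFactors = FALSE)
  }))

  prod_pairs <- which(production, arr.ind = TRUE)
  production_map <- data.frame(
    taxon_id = species[prod_pairs[, 1L]],
    taxon_rank = "species",
    metabolite_id = mets[prod_pairs[, 2L]],
    stringsAsFactors = FALSE)
  production_map <- production_map[order(production_map$taxon_id,
                                         production_map$metabolite_id), ,
                                   drop = FALSE]
  rownames(production_map) <- NULL

  structure(
    list(samples = samples,
         production = production_map,
         truth = structure(list(disease_id = disease_id,
                                species = species_truth,
                                metabolites = met_truth,
                                spec = spec),
                           class = "synthetic_truth")),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  spec <- x$truth$spec
  cat(sprintf(
    "Synthetic cohort: %d species, %d metabolites, %d+%d samples, seed %d\n",
    spec$n_species, spec$n_metabolites, spec$n_samples_disease,
    spec$n_samples_healthy, spec$seed))
  cat(sprintf("  affected species: %d (log-effect %.3g), production pairs: %d\n",
              spec$n_affected_species, spec$effect_size, nrow(x$production)))
  invisible(x)
}

#' Evaluate direction recovery against synthetic truth
#'
#' Converts the generator's per-metabolite directions into a validation table
#' and scores the records against it with [direction_consistency()].
#' \code{against = "realized"} targets the directions computed from the
#' generated table itself (exact recovery statements);
#' \code{against = "planted"} targets the nominal directions implied by the
#' planted effects alone, which the realized noise can contradict — the
#' relevant target when asking how recovery improves with effect size.
#' Metabolites without producers carry a \code{"null"} truth direction and are
#' excluded (no direction to recover).
#'
#' @param x A \code{"gmassoc"} fit (or record data.frame) computed on the
#'   generated cohort.
#' @param truth A \code{"synthetic_truth"} (or a cohort's \code{$truth}).
#' @param against Which ground truth to compare with (see above).
#' @param require_significant,config Passed to [direction_consistency()].
#' @return A \code{"consistency_report"}.
#' @export
evaluate_recovery <- function(x, truth, against = c("realized", "planted"),
                              require_significant = FALSE,
                              config = scoring_config()) {
  against <- match.arg(against)
  if (inherits(truth, "synthetic_cohort")) truth <- truth$truth
  stopifnot(inherits(truth, "synthetic_truth"))
  mt <- truth$metabolites
  dir_col <- if (against == "realized") mt$direction else mt$planted_direction
  mt$eval_direction <- dir_col
  mt <- mt[mt$eval_direction %in% c("increased", "decreased"), , drop = FALSE]
  vt <- data.frame(disease_id = truth$disease_id,
                   metabolite_id = mt$metabolite_id,
                   direction = mt$eval_direction,
                   evidence_id = "synthetic",
                   stringsAsFactors = FALSE)
  direction_consistency(x, vt, require_significant = require_significant,
                        config = config)
}

#' Write the three simulated tables plus ground truth to a directory
#'
#' @param sim A \code{"synthetic_cohort"}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_abundances(sim$samples, file.path(dir, "samples.tsv"))
  write_production_map(sim$production, file.path(dir, "production.tsv"))
  write_tsv(sim$truth$species, file.path(dir, "truth_species.tsv"))
  write_tsv(sim$truth$metabolites, file.path(dir, "truth_metabolites.tsv"))
  invisible(dir)
}
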