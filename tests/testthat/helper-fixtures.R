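# In-code fixtures shared across test files.

toy_samples <- function() {
  data.frame(
    cohort = c(rep("disease", 5), rep("healthy", 4)),
    disease_id = "d1",
    sample_id = c("s1", "s1", "s2", "s2", "s3", "c1", "c1", "c2", "c2"),
    species_id = c("spA", "spB", "spA", "spB", "spA",
                   "spA", "spB", "spA", "spB"),
    relative_abundance = c(0.1, 0.5, 0.3, 0.4, 0.2,
                           0.2, 0.1, 0.2, 0.3),
    stringsAsFactors = FALSE)
}

# summary with controllable medians; n defaults large enough to pass filters
toy_summary <- function(disease_id, species, d, h, n_d = 10L, n_h = 10L) {
  data.frame(disease_id = disease_id, species_id = species,
             median_disease = d, median_healthy = h,
             n_disease = n_d, n_healthy = n_h,
             stringsAsFactors = FALSE)
}

toy_map <- function(species, metabolites) {
  data.frame(taxon_id = species, taxon_rank = "species",
             metabolite_id = metabolites, stringsAsFactors = FALSE)
}

# random small scoring instance for oracle comparisons
random_instance <- function(n_species, n_metabolites) {
  species <- sprintf("sp%02d", seq_len(n_species))
  mets <- sprintf("m%02d", seq_len(n_metabolites))
  summary <- toy_summary("dz", species,
                         d = round(runif(n_species, 0, 0.5), 6),
                         h = round(runif(n_species, 0, 0.5), 6))
  prod <- expand.grid(taxon_id = species, metabolite_id = mets,
                      stringsAsFactors = FALSE)
  prod <- prod[runif(nrow(prod)) < 0.4, , drop = FALSE]
  prod$taxon_rank <- rep("species", nrow(prod))
  list(summary = summary,
       map = prod[c("taxon_id", "taxon_rank", "metabolite_id")])
}

# brute-force oracle: evaluate the score formula term by term over every
# (disease, metabolite) pair, mirroring the documented filters independently
# of the production scorer's vectorized path
brute_force_scores <- function(summary, map, config = scoring_config()) {
  out <- list()
  for (dz in sort(unique(summary$disease_id))) {
    sub <- summary[summary$disease_id == dz, ]
    if (max(sub$n_disease) < config$min_group_samples ||
        max(sub$n_healthy) < config$min_group_samples) next
    delta <- abs(sub$median_disease - sub$median_healthy)
    ord <- order(-delta, sub$species_id)
    retained <- sub$species_id[ord][seq_len(min(config$n_top_microbes,
                                                nrow(sub)))]
    retained <- sort(retained)
    for (met in sort(unique(map$metabolite_id))) {
      producers <- map$taxon_id[map$metabolite_id == met]
      s <- 0
      k <- 0L
      for (sp in retained) {
        i <- which(sub$species_id == sp)
        m_i <- as.numeric(sp %in% producers)
        s <- s + (sub$median_disease[i] - sub$median_healthy[i]) * m_i
        k <- k + as.integer(m_i == 1)
      }
      if (k >= 1L) {
        out[[length(out) + 1L]] <- data.frame(
          disease_id = dz, metabolite_id = met, score = s, k_producers = k,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(disease_id = character(0),
                      metabolite_id = character(0),
                      score = numeric(0), k_producers = integer(0)))
  }
  do.call(rbind, out)
}

# compact null-cohort conditions used for calibration studies
null_sim_spec <- function(seed, n_species = 40L, n_metabolites = 12L,
                          n_samples = 8L) {
  simulation_spec(n_species = n_species, n_metabolites = n_metabolites,
                  n_samples_disease = n_samples, n_samples_healthy = n_samples,
                  production_density = 0.25, n_affected_species = 0L,
                  effect_size = 0, noise_sd = 0.5, seed = seed)
}
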