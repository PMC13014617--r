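test_that("generation is deterministic in the seed and compositional", {
  spec <- simulation_spec(n_species = 15, n_metabolites = 6,
                          n_samples_disease = 5, n_samples_healthy = 5,
                          seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c <- generate_cohort(simulation_spec(n_species = 15, n_metabolites = 6,
                                       n_samples_disease = 5,
                                       n_samples_healthy = 5, seed = 124))
  expect_false(identical(a$samples, c$samples))

  # every sample sums to 1 after closure
  sums <- tapply(a$samples$relative_abundance,
                 paste(a$samples$cohort, a$samples$sample_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # generation does not disturb the caller's RNG stream
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(generate_cohort(spec))
  expect_identical(runif(1), before)
})

test_that("planted positive effects raise all pre-closure disease medians", {
  spec <- simulation_spec(n_species = 12, n_metabolites = 4,
                          n_samples_disease = 10, n_samples_healthy = 10,
                          n_affected_species = 12, effect_size = 3,
                          noise_sd = 0.5, seed = 31)
  sim <- generate_cohort(spec)
  st <- sim$truth$species
  up <- st[st$effect_sign > 0, ]
  expect_true(all(up$delta_pre > 0))
  down <- st[st$effect_sign < 0, ]
  expect_true(all(down$delta_pre < 0))
})

test_that("truth directions are exact statements about the generated table", {
  sim <- generate_cohort(simulation_spec(n_species = 20, n_metabolites = 8,
                                         n_samples_disease = 6,
                                         n_samples_healthy = 6, seed = 8))
  summary <- summarize_medians(sim$samples)
  st <- sim$truth$species
  delta <- summary$median_disease[match(st$species_id, summary$species_id)] -
    summary$median_healthy[match(st$species_id, summary$species_id)]
  expect_equal(delta, st$delta_post, tolerance = 1e-12)

  mt <- sim$truth$metabolites
  for (i in seq_len(nrow(mt))) {
    producers <- sim$production$taxon_id[
      sim$production$metabolite_id == mt$metabolite_id[i]]
    if (!length(producers)) {
      expect_equal(mt$direction[i], "null")
    } else {
      s <- sum(st$delta_post[st$species_id %in% producers])
      expect_equal(mt$expected_sum[i], s, tolerance = 1e-12)
    }
  }
})

test_that("metabolites without producers never appear in records or truth", {
  set.seed(42)
  found <- FALSE
  for (seed in 1:20) {
    sim <- generate_cohort(simulation_spec(n_species = 8, n_metabolites = 6,
                                           n_samples_disease = 5,
                                           n_samples_healthy = 5,
                                           production_density = 0.1,
                                           n_affected_species = 4,
                                           seed = seed))
    mt <- sim$truth$metabolites
    orphan <- mt$metabolite_id[mt$n_producers == 0]
    if (!length(orphan)) next
    found <- TRUE
    fit <- gmassoc(sim$samples, sim$production)
    expect_false(any(orphan %in% fit$records$metabolite_id))
    rep <- evaluate_recovery(fit, sim$truth)
    expect_false(any(orphan %in% rep$per_pair$metabolite_id))
  }
  expect_true(found)  # the regime actually produced orphan metabolites
})

test_that("recovery of the planted direction improves monotonically with effect size", {
  # against the noise-free planted direction (not the realized one, which the
  # scorer recovers tautologically when every species is retained) recovery
  # should climb toward certainty as the planted effect grows
  grid <- c(0.3, 1, 2.5)
  mean_consistency <- vapply(grid, function(eff) {
    mean(vapply(1:8, function(seed) {
      sim <- generate_cohort(simulation_spec(
        n_species = 40, n_metabolites = 12, n_samples_disease = 10,
        n_samples_healthy = 10, production_density = 0.25,
        n_affected_species = 20, effect_size = eff, noise_sd = 0.5,
        seed = 1000 + seed))
      fit <- gmassoc(sim$samples, sim$production)
      evaluate_recovery(fit, sim$truth,
                        against = "planted")$consistency_percent
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_consistency) >= 0))
  expect_gte(mean_consistency[3], 90)
})

test_that("dropout zero-inflates the table without breaking closure", {
  sim <- generate_cohort(simulation_spec(n_species = 20, n_metabolites = 5,
                                         n_samples_disease = 6,
                                         n_samples_healthy = 6,
                                         dropout = 0.3, seed = 17))
  n_expected <- 20 * 12
  expect_lt(nrow(sim$samples), n_expected)   # zero rows are omitted
  sums <- tapply(sim$samples$relative_abundance,
                 paste(sim$samples$cohort, sim$samples$sample_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # the sparse table still summarizes: absent rows are zeros by convention
  expect_silent(summarize_medians(sim$samples))
})

test_that("cohort tables write and read back", {
  sim <- generate_cohort(simulation_spec(n_species = 8, n_metabolites = 3,
                                         n_samples_disease = 5,
                                         n_samples_healthy = 5,
                                         n_affected_species = 4, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  expect_equal(read_sample_abundances(file.path(dir, "samples.tsv")),
               sim$samples)
  expect_equal(read_production_map(file.path(dir, "production.tsv")),
               sim$production)
})
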