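test_that("association_score is the producer-masked sum of differences", {
  expect_equal(association_score(c(0.30, 0.20, 0.10),
                                 c(0.10, 0.20, 0.30),
                                 c(1, 1, 0)), 0.2)
  d <- runif(6)
  expect_equal(association_score(d, d, rep(1, 6)), 0)
  expect_equal(association_score(d, rev(d), rep(0, 6)), 0)
  expect_error(association_score(1:3, 1:2, 1:3), "dimension")
})

test_that("top-changed species are ranked by |delta| with lexicographic ties", {
  s <- toy_summary("d1", c("spA", "spB", "spC"),
                   d = c(0.4, 0.3, 0.2), h = c(0.1, 0.1, 0.1))
  expect_equal(select_top_changed_species(s, "d1", 2), c("spA", "spB"))
  expect_equal(select_top_changed_species(s, "d1", 10),
               c("spA", "spB", "spC"))
  # tie for the last slot: lexicographically smaller id kept
  s2 <- toy_summary("d1", c("spC", "spB", "spA"),
                    d = c(0.3, 0.3, 0.5), h = c(0.1, 0.1, 0.1))
  expect_equal(select_top_changed_species(s2, "d1", 2), c("spA", "spB"))
  expect_error(select_top_changed_species(s, "nope", 2), "unknown disease")
})

test_that("score_all_pairs applies sample-size, top-N and producer filters", {
  # disease below the sample-size threshold yields no records
  s_small <- toy_summary("d1", c("spA", "spB"), d = c(0.3, 0.1),
                         h = c(0.1, 0.1), n_d = 4L, n_h = 10L)
  map <- toy_map(c("spA", "spB"), c("M1", "M1"))
  expect_equal(nrow(score_all_pairs(s_small, map)), 0L)

  # hand-computed: 3 retained species, metabolite produced by two of them,
  # deltas (+0.2, 0, -0.2): score 0.2, k = 2, p undefined below min_producers
  s <- toy_summary("d1", c("sp1", "sp2", "sp3"),
                   d = c(0.4, 0.2, 0.1), h = c(0.2, 0.2, 0.3))
  map2 <- toy_map(c("sp1", "sp2"), c("M1", "M1"))
  fit <- gmassoc(s, map2)
  expect_equal(nrow(fit$records), 1L)
  expect_equal(fit$records$score, 0.2)
  expect_equal(fit$records$k_producers, 2L)
  expect_true(is.na(fit$records$p_value))
  expect_true(is.na(fit$records$fdr))
  expect_equal(fit$records$direction, "increased")

  # metabolite whose only producer falls outside the top-N has no record
  cfg <- scoring_config(n_top_microbes = 2, min_group_samples = 5)
  s3 <- toy_summary("d1", c("sp1", "sp2", "sp3"),
                    d = c(0.5, 0.4, 0.21), h = c(0.1, 0.1, 0.2))
  map3 <- toy_map("sp3", "M9")
  expect_equal(nrow(score_all_pairs(s3, map3, cfg)), 0L)

  # strain-rank maps are refused until collapsed
  strain_map <- data.frame(taxon_id = "str1", taxon_rank = "strain",
                           metabolite_id = "M1")
  expect_error(score_all_pairs(s, strain_map), "collapse")
})

test_that("pipeline scores equal a brute-force term-by-term evaluation", {
  set.seed(401)
  for (i in 1:60) {
    inst <- random_instance(sample(3:12, 1), sample(1:6, 1))
    if (!nrow(inst$map)) next
    got <- score_all_pairs(inst$summary, inst$map)
    want <- brute_force_scores(inst$summary, inst$map)
    got <- got[order(got$disease_id, got$metabolite_id), ]
    want <- want[order(want$disease_id, want$metabolite_id), ]
    expect_equal(got$metabolite_id, want$metabolite_id)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$k_producers, want$k_producers)
  }
})

test_that("scores are antisymmetric under cohort swap and linear in differences", {
  set.seed(402)
  for (i in 1:20) {
    inst <- random_instance(8, 4)
    if (!nrow(inst$map)) next
    sw <- inst$summary
    tmp <- sw$median_disease
    sw$median_disease <- sw$median_healthy
    sw$median_healthy <- tmp
    a <- score_all_pairs(inst$summary, inst$map)
    b <- score_all_pairs(sw, inst$map)
    key <- function(x) paste(x$disease_id, x$metabolite_id)
    b <- b[match(key(a), key(b)), ]
    expect_equal(b$score, -a$score, tolerance = 1e-12)

    # scale all differences by c about the healthy profile
    cc <- 0.5
    sc <- inst$summary
    sc$median_disease <- sc$median_healthy +
      cc * (sc$median_disease - sc$median_healthy)
    d <- score_all_pairs(sc, inst$map)
    d <- d[match(key(a), key(d)), ]
    expect_equal(d$score, cc * a$score, tolerance = 1e-12)
  }
})

test_that("tightening filters never adds records", {
  set.seed(403)
  inst <- random_instance(12, 6)
  base <- score_all_pairs(inst$summary, inst$map,
                          scoring_config(n_top_microbes = 12,
                                         min_group_samples = 5))
  fewer_top <- score_all_pairs(inst$summary, inst$map,
                               scoring_config(n_top_microbes = 6,
                                              min_group_samples = 5))
  more_samples <- score_all_pairs(inst$summary, inst$map,
                                  scoring_config(n_top_microbes = 12,
                                                 min_group_samples = 11))
  key <- function(x) paste(x$disease_id, x$metabolite_id)
  expect_true(all(key(fewer_top) %in% key(base)))
  expect_lte(nrow(fewer_top), nrow(base))
  expect_equal(nrow(more_samples), 0L)
})

test_that("gmassoc methods expose the fit", {
  sim <- generate_cohort(simulation_spec(n_species = 15, n_metabolites = 6,
                                         n_samples_disease = 6,
                                         n_samples_healthy = 6, seed = 5))
  fit <- gmassoc(sim$samples, sim$production)
  expect_s3_class(fit, "gmassoc")
  expect_named(coef(fit))
  expect_equal(unname(coef(fit)), fit$records$score)
  expect_output(print(fit), "association records")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.gmassoc")
  expect_output(print(sm), "significant")
  expect_identical(as.data.frame(fit), fit$records)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))

  # associations TSV round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations(fit, path)
  back <- read_associations(path)
  expect_equal(back$score, fit$records$score)
  expect_equal(back$p_value, fit$records$p_value)
})
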