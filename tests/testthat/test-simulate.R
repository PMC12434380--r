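test_that("the same seed reproduces a cohort exactly", {
  cfg <- cpm_sim_config(n_participants = 120, n_regions = 12, n_sites = 4,
                        planted_edges = 5, planted_r = 0.2, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$edges, b$edges)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- simulate_cohort(cfg, seed = 32)
  expect_false(identical(a$edges, c2$edges))
})

test_that("presets carry the published cohort structure", {
  ab <- cpm_preset("abcd_like")
  expect_equal(ab$n_participants, 3718L)
  expect_equal(ab$n_sites, 21L)
  expect_equal(ab$n_regions, 352L)
  expect_equal(ab$score_base_mean, 53.51)
  expect_equal(ab$base_y1_r, 0.68)
  ba <- cpm_preset("banda_like")
  expect_equal(ba$n_participants, 150L)
  expect_equal(ba$n_sites, 1L)
  expect_equal(ba$base_y1_r, 0.63)
  expect_equal(ba$sex_prop_f, 0.613)
  expect_identical(cpm_preset("abcd_like"), cpm_preset("abcd_like"))
  expect_error(cpm_preset("nonsense"))
})

test_that("a null cohort has no edge-outcome association", {
  co <- simulate_cohort(cpm_sim_config(n_participants = 2000, n_regions = 12,
                                       n_sites = 4, planted_edges = 10,
                                       gamma = 0, seed = 41))
  rhos <- apply(co$edges[, co$ground_truth$edge, drop = FALSE], 2, function(e)
    cor(e, co$phenotypes$score_y1, method = "spearman"))
  expect_true(all(abs(rhos) < 3 / sqrt(2000)))
})

test_that("planted edges reach the analytically implied marginal correlation", {
  # closed-form prediction checked against a large Monte-Carlo draw
  cfg <- cpm_sim_config(n_participants = 20000, n_regions = 10, n_sites = 5,
                        planted_edges = 5, planted_r = 0.15, seed = 42)
  co <- simulate_cohort(cfg)
  emp <- apply(co$edges[, co$ground_truth$edge, drop = FALSE], 2, function(e)
    cor(e, co$phenotypes$score_y1))
  expect_equal(mean(emp), 0.15, tolerance = 0.03)
  g <- gamma_for_edge_r(cfg, 0.15)
  expect_equal(implied_edge_r(cfg, g), 0.15, tolerance = 1e-12)
  expect_equal(unique(co$ground_truth$gamma), g, tolerance = 1e-12)
})

test_that("score calibration matches the preset targets at large n", {
  co <- simulate_cohort(cpm_preset("abcd_like", n_regions = 12), seed = 5)
  ph <- co$phenotypes
  expect_equal(mean(ph$score_base), 53.51, tolerance = 0.3)
  expect_equal(sd(ph$score_base), 6.02, tolerance = 0.3)
  expect_equal(mean(ph$score_y1), 53.48, tolerance = 0.3)
  expect_equal(cor(ph$score_base, ph$score_y1), 0.68, tolerance = 0.04)
  # positive skew, as configured
  z <- (ph$score_base - mean(ph$score_base)) / sd(ph$score_base)
  expect_gt(mean(z^3), 0.2)
})

test_that("the clinical/control mixture reproduces group and pooled moments", {
  cfg <- cpm_preset("banda_like", n_participants = 6000L, n_regions = 10)
  co <- simulate_cohort(cfg, seed = 9)
  ph <- co$phenotypes
  expect_setequal(unique(ph$group), c("clinical", "control"))
  expect_equal(mean(ph$score_base), 49.11, tolerance = 0.6)
  expect_equal(sd(ph$score_base), 15.28, tolerance = 0.6)
  expect_equal(mean(ph$score_y1), 44.62, tolerance = 0.6)
  expect_equal(cor(ph$score_base, ph$score_y1), 0.63, tolerance = 0.04)
  clin <- ph[ph$group == "clinical", ]
  expect_equal(mean(clin$score_base), 56.47, tolerance = 0.8)
  expect_equal(sd(clin$score_base), 14.26, tolerance = 0.8)
})

test_that("families share sites and have the configured latent correlation", {
  co <- simulate_cohort(cpm_sim_config(n_participants = 4000, n_regions = 10,
                                       n_sites = 8, family_rate = 0.5,
                                       planted_edges = 0, gamma = 0,
                                       seed = 77))
  ph <- co$phenotypes
  # no family straddles two sites
  expect_true(all(tapply(ph$site_id, ph$family_id,
                         function(s) length(unique(s))) == 1))
  # sibling-pair correlation of the latent vulnerability ~ 0.5
  fam <- split(seq_len(nrow(ph)), ph$family_id)
  pairs <- fam[lengths(fam) == 2]
  expect_gt(length(pairs), 500)
  v1 <- sapply(pairs, function(ix) co$vulnerability[ix[1]])
  v2 <- sapply(pairs, function(ix) co$vulnerability[ix[2]])
  expect_equal(cor(v1, v2), 0.5, tolerance = 0.1)
})

test_that("impossible configurations are rejected", {
  expect_error(cpm_sim_config(n_regions = 5, planted_edges = 11), "exceeds")
  expect_error(cpm_sim_config(motion_outcome_r = 1.5), "motion_outcome_r")
  expect_error(cpm_sim_config(base_y1_r = 1.2), "base_y1_r")
  expect_error(cpm_sim_config(family_rate = -0.1), "family_rate")
  cfg <- cpm_sim_config(n_regions = 10)
  expect_error(gamma_for_edge_r(cfg, 0.9), "unreachable")
  expect_error(cpm_sim_config(n_regions = 10, planted_edges = 3,
                              planted_edge_set = c(1, 2)), "length")
})

test_that("a nonzero motion confound induces the requested correlation", {
  co <- simulate_cohort(cpm_sim_config(n_participants = 5000, n_regions = 10,
                                       planted_edges = 0, gamma = 0,
                                       motion_outcome_r = 0.4, seed = 13))
  expect_equal(cor(co$phenotypes$mean_fd, co$phenotypes$score_y1), 0.4,
               tolerance = 0.05)
})

test_that("simulated cohorts round-trip through the on-disk layout", {
  co <- simulate_cohort(cpm_sim_config(n_participants = 40, n_regions = 8,
                                       n_sites = 2, planted_edges = 3,
                                       planted_r = 0.2, seed = 91))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir, format = "csv")
  back <- align_cohort(read_edge_matrix(paths$edges),
                       read_phenotypes(paths$phenotypes))
  expect_equal(unclass(back$edges), unclass(co$edges), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$phenotypes$score_y1, co$phenotypes$score_y1,
               tolerance = 1e-12)
  gt <- read.csv(paths$ground_truth)
  expect_equal(gt$edge, co$ground_truth$edge)
})
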