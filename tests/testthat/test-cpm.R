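test_that("site splits are disjoint, exhaustive, and reproducible", {
  sites2 <- rep(c("a", "b"), c(10, 15))
  sp <- split_half_sites(sites2, seed = 1)
  expect_setequal(c(sp$train, sp$test), 1:25)
  expect_length(intersect(sp$train, sp$test), 0)

  sites21 <- sample(sprintf("site-%02d", 1:21), 500, replace = TRUE)
  sp21 <- split_half_sites(sites21, seed = 2)
  expect_length(sp21$train_sites, 11)
  expect_length(sp21$test_sites, 10)
  expect_setequal(c(sp21$train_sites, sp21$test_sites), unique(sites21))
  expect_length(intersect(sp21$train_sites, sp21$test_sites), 0)
  expect_identical(split_half_sites(sites21, seed = 9),
                   split_half_sites(sites21, seed = 9))

  expect_error(split_half_sites(rep("only", 30)), "participant_split")
})

test_that("no family straddles the two sides of a split", {
  co <- simulate_cohort(cpm_sim_config(n_participants = 300, n_regions = 10,
                                       n_sites = 6, family_rate = 0.6,
                                       planted_edges = 0, gamma = 0,
                                       seed = 8))
  fam <- co$phenotypes$family_id
  for (s in 1:10) {
    sp <- split_half_sites(co$phenotypes$site_id, seed = s)
    expect_length(intersect(fam[sp$train], fam[sp$test]), 0)
  }
})

test_that("cpm fits are deterministic under a fixed seed", {
  co <- planted_cohort(n = 400, n_regions = 16, planted_r = 0.25,
                       planted_edges = 8, seed = 51)
  f1 <- cpm(co, n_iterations = 6, alpha = 0.01, seed = 5)
  f2 <- cpm(co, n_iterations = 6, alpha = 0.01, seed = 5)
  expect_identical(f1$rhos, f2$rhos)
  expect_identical(f1$masks, f2$masks)
  expect_identical(f1$mean_rho, f2$mean_rho)
  f3 <- cpm(co, n_iterations = 6, alpha = 0.01, seed = 6)
  expect_false(identical(f1$rhos, f3$rhos))
})

test_that("planted signal yields positive cross-validated prediction", {
  co <- planted_cohort(n = 1200, n_regions = 20, planted_r = 0.2,
                       planted_edges = 10, seed = 52)
  fit <- cpm(co, n_iterations = 10, seed = 7)
  expect_gt(fit$mean_rho, 0.05)
  expect_equal(fit$mean_rho, mean(fit$rhos, na.rm = TRUE))
  # most iterations recover mostly planted edges
  hit <- vapply(fit$masks[lengths(fit$masks) > 0], function(ix)
    mean(ix %in% co$ground_truth$edge), numeric(1))
  expect_gt(median(hit), 0.5)
})

test_that("iterations with zero selected edges are excluded and counted", {
  co <- null_cohort(n = 300, n_regions = 12, seed = 53)
  expect_message(fit <- suppressWarnings(
    cpm(co, n_iterations = 5, alpha = 1e-12, seed = 3)), "zero edges")
  expect_equal(fit$n_zero_edge, 5)
  expect_true(is.nan(fit$mean_rho))
  expect_true(all(is.na(fit$rhos)))
})

test_that("permutation p-values follow the strict-proportion definition", {
  co <- planted_cohort(n = 300, n_regions = 12, planted_r = 0.3,
                       planted_edges = 6, seed = 54)
  fit <- cpm(co, n_iterations = 4, alpha = 0.01, seed = 11)
  fit <- cpm_permute(fit, n_permutations = 25, perm_iterations = 2, seed = 12)
  pr <- fit$permutation
  expect_equal(pr$p_perm,
               sum(pr$null_rhos > fit$mean_rho, na.rm = TRUE) / 25)
  expect_true(pr$p_perm >= 0 && pr$p_perm <= 1)
  # plus-one variant is strictly positive
  fit2 <- cpm_permute(fit, n_permutations = 10, perm_iterations = 2,
                      seed = 13, plus_one = TRUE)
  expect_gt(fit2$permutation$p_perm, 0)
  expect_error(cpm_permute(fit, n_permutations = 0), ">= 1")
})

test_that("consensus network recovers planted edges and honours alpha", {
  co <- planted_cohort(n = 1500, n_regions = 16, planted_r = 0.25,
                       planted_edges = 20, seed = 55)
  net <- consensus_network(co, alpha = 0.001)
  missed <- setdiff(co$ground_truth$edge, net$edge)
  expect_lte(length(missed), 2)

  all_net <- consensus_network(co, alpha = 1.0)
  expect_equal(nrow(all_net), n_edges(16))

  nul <- null_cohort(n = 500, n_regions = 46, seed = 56)
  suppressWarnings(nnet <- consensus_network(nul, alpha = 0.001))
  expect_lte(nrow(nnet), 8)

  # region pairs are unique with i < j, signs match rho
  expect_true(all(net$region_i < net$region_j))
  expect_equal(anyDuplicated(net[c("region_i", "region_j")]), 0)
  expect_equal(net$sign, ifelse(net$rho >= 0, "+", "-"))
})

test_that("cpm model methods are coherent", {
  co <- planted_cohort(n = 600, n_regions = 14, planted_r = 0.3,
                       planted_edges = 8, seed = 57)
  fit <- cpm(co, n_iterations = 4, seed = 21)
  expect_s3_class(fit, "cpm")
  expect_output(print(fit), "mean test-set partial Spearman")
  s <- summary(fit)
  expect_s3_class(s, "summary.cpm")
  expect_output(print(s), "consensus network")

  cf <- coef(fit)
  expect_named(cf, c("intercept", "slope"))
  pred <- predict(fit)
  expect_length(pred, 600)
  expect_equal(pred, fitted(fit))
  expect_equal(residuals(fit), co$phenotypes$score_y1 - pred)
  # predictions are an affine map of consensus strengths
  st <- apply_network(fit$consensus, co)
  expect_equal(pred, cf["intercept"] + cf["slope"] * st, ignore_attr = TRUE)

  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("single-site cohorts require the participant-level split", {
  co <- simulate_cohort(cpm_sim_config(n_participants = 240, n_regions = 10,
                                       n_sites = 1, planted_edges = 4,
                                       planted_r = 0.3, seed = 58))
  expect_error(cpm(co, n_iterations = 2), "participant_split")
  fit <- cpm(co, n_iterations = 4, alpha = 0.01, participant_split = TRUE,
             seed = 3)
  expect_true(is.finite(fit$mean_rho))
})

test_that("prediction strengthens as the planted loading grows", {
  gammas <- c(0, 0.05, 0.12)
  means <- sapply(gammas, function(g) {
    reps <- sapply(1:3, function(r) {
      co <- simulate_cohort(cpm_sim_config(n_participants = 700,
                                           n_regions = 20, n_sites = 6,
                                           planted_edges = 10, gamma = g,
                                           seed = 600 + 10 * r))
      suppressWarnings(suppressMessages(
        cpm(co, n_iterations = 6, alpha = 0.01, seed = 700 + r)$mean_rho))
    })
    mean(reps, na.rm = TRUE)
  })
  # monotone up to simulation error
  expect_gt(means[3], means[1] + 0.03)
  expect_gt(means[3], means[2] - 0.05)
  expect_gt(means[2], means[1] - 0.05)
})

test_that("network masks round-trip through CSV with provenance", {
  co <- planted_cohort(n = 400, n_regions = 12, planted_r = 0.35,
                       planted_edges = 6, seed = 59)
  net <- consensus_network(co, alpha = 0.01)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_network_mask(net, tmp)
  back <- read_network_mask(tmp)
  expect_equal(back$edge, net$edge)
  expect_equal(back$rho, net$rho, tolerance = 1e-12)
  expect_equal(attr(back, "alpha"), attr(net, "alpha"))
  expect_equal(attr(back, "n_regions"), attr(net, "n_regions"))
})
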