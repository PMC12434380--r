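test_that("rank transform uses midranks and matches a sort-based oracle", {
  expect_equal(rank_transform(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_transform(c(5, 5, 1)), c(2.5, 2.5, 1))
  set.seed(21)
  x <- rnorm(100)
  expect_equal(rank_transform(x), order(order(x)))  # no ties: double-order
  expect_error(rank_transform(numeric(0)), "empty")
  expect_error(rank_transform(c(1, NA)), "non-finite")
})

test_that("partial Spearman reduces to classic Spearman without covariates", {
  set.seed(22)
  for (rep in 1:10) {
    x <- rnorm(40)
    y <- rnorm(40)
    if (rep %% 2 == 0) x[1:5] <- x[6]  # exercise ties
    ps <- partial_spearman(x, y)
    expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  # invariance under strictly monotone maps
  x <- rnorm(50)
  expect_equal(partial_spearman(exp(x), x^3 + 10)$rho, 1)
  expect_lt(partial_spearman(exp(x), x^3)$p, 1e-10)
})

test_that("partialling removes signal shared with a covariate", {
  set.seed(23)
  z <- rnorm(50)
  x <- rnorm(50)
  y <- z  # outcome is exactly the covariate
  ps <- partial_spearman(x, y, cbind(z))
  expect_lt(abs(ps$rho), 0.3)
})

test_that("partial Spearman matches the normal-equations oracle", {
  set.seed(24)
  for (k in c(0, 1, 2, 4)) {
    for (rep in 1:5) {
      x <- rnorm(30); y <- 0.3 * x + rnorm(30)
      cv <- if (k > 0) matrix(rnorm(30 * k), 30) else NULL
      got <- partial_spearman(x, y, cv)
      want <- oracle_partial_spearman(x, y, cv)
      expect_equal(got$rho, want$rho, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  }
})

test_that("degenerate partial-correlation inputs raise errors", {
  expect_error(partial_spearman(rep(1, 20), rnorm(20)), "constant")
  expect_error(partial_spearman(rnorm(20), rep(2, 20)), "constant")
  cv <- cbind(a = 1:20, b = 1:20)  # collinear after ranking
  expect_error(partial_spearman(rnorm(20), rnorm(20), cv), "rank-deficient")
  expect_error(partial_spearman(rnorm(4), rnorm(4), matrix(rnorm(8), 4)),
               "n > k")
})

test_that("edge screening agrees edge-by-edge with partial_spearman", {
  set.seed(25)
  co <- planted_cohort(n = 120, n_regions = 8, n_sites = 3, planted_r = 0.3,
                       planted_edges = 4, seed = 3)
  y <- co$phenotypes$score_y1
  for (adjust in c(TRUE, FALSE)) {
    scr <- screen_edges(co, alpha = 0.05, adjust = adjust)
    for (j in seq_len(ncol(co$edges))) {
      want <- partial_spearman(co$edges[, j], y,
                               if (adjust) co$covariates)
      expect_equal(scr$rho[j], want$rho, tolerance = 1e-10)
      expect_equal(scr$p[j], want$p, tolerance = 1e-10)
    }
    expect_identical(scr$mask, scr$p < 0.05)
  }
  # subset screening equals screening the manually subset cohort
  rows <- which(co$phenotypes$site_id %in% c("site-01", "site-02"))
  sub <- manual_cohort(co$edges[rows, ], y[rows], 8,
                       score_base = co$phenotypes$score_base[rows])
  sub$covariates <- co$covariates[rows, ]
  scr_rows <- screen_edges(co, alpha = 0.05, adjust = TRUE, rows = rows)
  scr_sub <- screen_edges(sub, alpha = 0.05, adjust = TRUE)
  expect_equal(scr_rows$rho, scr_sub$rho, tolerance = 1e-10)
})

test_that("a perfect monotone edge is the one retained", {
  set.seed(26)
  n <- 200
  edges <- matrix(rnorm(n * 45), n)
  y <- rnorm(n, 50, 5)
  edges[, 7] <- y
  co <- manual_cohort(edges, y, 10)
  scr <- screen_edges(co, alpha = 0.001, adjust = FALSE)
  expect_true(scr$mask[7])
  expect_equal(scr$rho[7], 1)
  expect_equal(scr$sign[7], 1)
  expect_lt(sum(scr$mask), 4)
})

test_that("null screening selects edges at roughly the binomial rate", {
  sel <- sapply(1:3, function(s) {
    co <- null_cohort(n = 500, n_regions = 46, seed = 100 + s)
    sum(screen_edges(co, alpha = 0.001, adjust = FALSE)$mask)
  })
  # E = 1035, alpha = 0.001: mean ~ 1 selected edge; 8 is > 5 SDs out
  expect_true(all(sel <= 8))
})

test_that("network strength sums |z| and ignores edge sign", {
  expect_equal(network_strength(c(0.5, -0.5, 1), c(TRUE, TRUE, TRUE)), 2)
  expect_equal(network_strength(rnorm(10), rep(FALSE, 10)), 0)
  set.seed(27)
  z <- rnorm(30)
  m <- runif(30) < 0.4
  expect_equal(network_strength(z, m), sum(abs(z[m])))  # loop oracle
  zf <- z; zf[m] <- -zf[m]
  expect_equal(network_strength(zf, m), network_strength(z, m))
  # matrix form matches per-row application
  x <- matrix(rnorm(5 * 30), 5, dimnames = list(letters[1:5], NULL))
  expect_equal(network_strength(x, m), apply(x, 1, function(r) sum(abs(r[m]))))
  z[which(m)[1]] <- Inf
  expect_error(network_strength(z, m), "non-finite")
})

test_that("the strength model is ordinary least squares with prediction", {
  m <- fit_strength_model(c(0, 1, 2), c(10, 12, 14))
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 10)
  expect_equal(predict(m, 0), 10)
  expect_equal(predict(m, 3), 16)
  expect_equal(predict(m, c(0, 3)), c(10, 16))

  m0 <- fit_strength_model(c(1, 2, 3, 4), rep(7, 4))
  expect_equal(m0$slope, 0)
  expect_equal(m0$intercept, 7)

  set.seed(28)
  s <- rnorm(100); y <- 3 + 0.5 * s + rnorm(100)
  mf <- fit_strength_model(s, y)
  expect_equal(mf$slope, cov(s, y) / var(s), tolerance = 1e-12)
  expect_equal(mf$intercept, mean(y) - mf$slope * mean(s), tolerance = 1e-12)

  expect_error(fit_strength_model(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_strength_model(1:2, 1:2), "at least 3")
})
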