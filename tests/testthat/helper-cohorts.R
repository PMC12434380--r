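# Small cohorts used across test files. Everything is generated in code.

# Aligned cohort built from an explicit edge matrix and minimal phenotypes,
# for tests that need exact control over edge values.
manual_cohort <- function(edges, score_y1, n_regions,
                          score_base = NULL, site = NULL, seed = 99) {
  n <- nrow(edges)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ph <- data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    site_id = if (is.null(site)) sprintf("s%d", rep_len(1:3, n)) else site,
    family_id = sprintf("f%03d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 9, 11),
    mean_fd = runif(n, 0.05, 0.3),
    score_base = if (is.null(score_base)) rnorm(n, 50, 5) else score_base,
    score_y1 = score_y1,
    stringsAsFactors = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  rownames(edges) <- ph$participant_id
  em <- cpmnet:::as_edge_matrix(edges, n_regions)
  align_cohort(em, ph)
}

null_cohort <- function(n = 500, n_regions = 46, n_sites = 6, seed = 1) {
  simulate_cohort(cpm_sim_config(n_participants = n, n_sites = n_sites,
                                 n_regions = n_regions, planted_edges = 0,
                                 gamma = 0, seed = seed))
}

planted_cohort <- function(n = 2000, n_regions = 46, n_sites = 6,
                           planted_r = 0.15, planted_edges = 20, seed = 1,
                           ...) {
  simulate_cohort(cpm_sim_config(n_participants = n, n_sites = n_sites,
                                 n_regions = n_regions,
                                 planted_edges = planted_edges,
                                 planted_r = planted_r, seed = seed, ...))
}

# Independent oracle for the partial Spearman statistic: rank everything,
# residualize through explicit normal equations, correlate residuals.
oracle_partial_spearman <- function(x, y, covariates = NULL) {
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariates)) {
    rc <- apply(as.matrix(covariates), 2, rank)
    C <- cbind(1, rc)
    bx <- solve(t(C) %*% C, t(C) %*% rx)
    by <- solve(t(C) %*% C, t(C) %*% ry)
    rx <- rx - as.numeric(C %*% bx)
    ry <- ry - as.numeric(C %*% by)
  }
  k <- if (is.null(covariates)) 0 else ncol(as.matrix(covariates))
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  df <- length(x) - 2 - k
  tval <- abs(rho) * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(tval, df, lower.tail = FALSE))
}
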