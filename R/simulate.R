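# Moments of the sinh-arcsinh skewing map s(Z) = sinh(asinh(Z) + eps)
# for Z ~ N(0,1). Using sinh(asinh(z)+e) = z cosh(e) + sqrt(1+z^2) sinh(e):
#   E[s]      = sinh(e) * E[sqrt(1+Z^2)]
#   Var[s]    = cosh(e)^2 + 2 sinh(e)^2 - E[s]^2
#   Cov[s, Z] = cosh(e)
# E[sqrt(1+Z^2)] has no elementary closed form; it is computed once by
# quadrature (deterministic, seed-free).
sas_moments <- function(eps) {
  m1 <- integrate(function(z) sqrt(1 + z^2) * stats::dnorm(z), -Inf, Inf,
                  rel.tol = 1e-12)$value
  mu <- sinh(eps) * m1
  v <- cosh(eps)^2 + 2 * sinh(eps)^2 - mu^2
  list(mean = mu, sd = sqrt(v), kappa = cosh(eps) / sqrt(v))
}

# Standardized positively-skewed variate built from a standard normal input.
sas_standardize <- function(z, eps) {
  if (eps == 0) return(z)
  m <- sas_moments(eps)
  (sinh(asinh(z) + eps) - m$mean) / m$sd
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generative model behind
#' [simulate_cohort()]. The model draws a latent vulnerability per
#' participant (shared within families with intra-family correlation
#' `intra_family_r`), maps it to a calibrated, optionally skewed baseline
#' severity score, propagates it to the 1-year follow-up score with a target
#' baseline-to-follow-up Pearson correlation, and plants the same latent
#' into `planted_edges` connectome edges with loading `gamma` (z-units per
#' SD of vulnerability). All remaining edges are background noise around
#' `edge_mu` with per-site offsets of SD `site_sd`.
#'
#' @param n_participants cohort size.
#' @param n_sites number of MRI sites; families never straddle sites.
#' @param n_regions parcellation size (default 352; small values are fine
#'   for testing).
#' @param family_rate fraction of participants who share a family with one
#'   other participant (sibling pairs).
#' @param intra_family_r correlation of the latent vulnerability within a
#'   family (default 0.5).
#' @param planted_edges number K of outcome-linked edges.
#' @param gamma loading of the vulnerability on each planted edge (one
#'   shared sign: the strength feature sums absolute z-values, under which
#'   mixed-sign loadings would cancel). Ignored when `planted_r` is given.
#' @param planted_r optional target marginal Pearson correlation between a
#'   planted edge and the follow-up score; when set, `gamma` is solved from
#'   it at simulation time (see [gamma_for_edge_r()]).
#' @param edge_mu,edge_sigma mean and residual SD of background edge values
#'   (Fisher-z units).
#' @param site_sd SD of the additive per-site, per-edge offset.
#' @param score_base_mean,score_base_sd,score_y1_mean,score_y1_sd calibration
#'   targets for the severity scores (t-score-like units).
#' @param base_y1_r target Pearson correlation between baseline and
#'   follow-up scores.
#' @param skew sinh-arcsinh skewness of the baseline score (0 = symmetric;
#'   positive values give a right tail). Must be 0 when `mixture` is used.
#' @param v_loading correlation between the baseline latent and the
#'   vulnerability (a in the model).
#' @param v_outcome direct loading of the vulnerability on the follow-up
#'   latent (c in the model); this is what planted edges can predict beyond
#'   the baseline score.
#' @param motion_mean,motion_sd mean framewise displacement distribution (mm).
#' @param motion_outcome_r correlation between motion and the follow-up
#'   score (0 by default; nonzero values stress-test covariate adjustment).
#' @param sex_prop_f proportion of female participants.
#' @param age_range range (years) of the uniform age distribution.
#' @param planted_edge_set optional integer edge indices to plant into
#'   (overrides random placement; lets two cohorts share one ground truth,
#'   e.g. a discovery and an external-validation cohort).
#' @param mixture optional clinical/control mixture: a list with `prob`
#'   (clinical fraction) and per-group score moments `clinical` and
#'   `control`, each `c(base_mean, base_sd, y1_mean, y1_sd)`. When set, the
#'   overall score moments and `base_y1_r` are induced by the mixture and
#'   the within-group correlation is solved to match `base_y1_r`.
#' @param seed integer seed making the cohort reproducible.
#' @return A `cpm_sim_config` list.
#' @export
cpm_sim_config <- function(n_participants = 500L, n_sites = 6L,
                           n_regions = 60L, family_rate = 0.2,
                           intra_family_r = 0.5, planted_edges = 20L,
                           gamma = 0, planted_r = NULL,
                           edge_mu = 0.25, edge_sigma = 0.15, site_sd = 0.05,
                           score_base_mean = 53.51, score_base_sd = 6.02,
                           score_y1_mean = 53.48, score_y1_sd = 6.06,
                           base_y1_r = 0.68, skew = 0.35,
                           v_loading = 0.5, v_outcome = 0.3,
                           motion_mean = 0.15, motion_sd = 0.06,
                           motion_outcome_r = 0,
                           sex_prop_f = 0.5, age_range = c(9, 11),
                           mixture = NULL, planted_edge_set = NULL,
                           seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_sites = as.integer(n_sites),
              n_regions = as.integer(n_regions),
              family_rate = family_rate, intra_family_r = intra_family_r,
              planted_edges = as.integer(planted_edges),
              gamma = gamma, planted_r = planted_r,
              edge_mu = edge_mu, edge_sigma = edge_sigma, site_sd = site_sd,
              score_base_mean = score_base_mean, score_base_sd = score_base_sd,
              score_y1_mean = score_y1_mean, score_y1_sd = score_y1_sd,
              base_y1_r = base_y1_r, skew = skew,
              v_loading = v_loading, v_outcome = v_outcome,
              motion_mean = motion_mean, motion_sd = motion_sd,
              motion_outcome_r = motion_outcome_r,
              sex_prop_f = sex_prop_f, age_range = age_range,
              mixture = mixture,
              planted_edge_set = planted_edge_set,
              seed = as.integer(seed))
  class(cfg) <- "cpm_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 2) stopf("n_participants must be >= 2")
    if (family_rate < 0 || family_rate > 1)
      stopf("family_rate must be in [0, 1]")
    if (intra_family_r < 0 || intra_family_r > 1)
      stopf("intra_family_r must be in [0, 1]")
    E <- n_edges(n_regions)
    if (planted_edges > E)
      stopf("planted_edges (%d) exceeds the number of edges E = %d",
            planted_edges, E)
    if (score_base_sd <= 0 || score_y1_sd <= 0) stopf("score SDs must be > 0")
    if (abs(base_y1_r) >= 1) stopf("base_y1_r must lie in (-1, 1)")
    if (abs(motion_outcome_r) > 1) stopf("|motion_outcome_r| must be <= 1")
    if (abs(v_loading) > 1) stopf("|v_loading| must be <= 1")
    if (edge_sigma <= 0) stopf("edge_sigma must be > 0")
    if (!is.null(mixture) && skew != 0)
      stopf("skew must be 0 when a clinical/control mixture is used")
    if (!is.null(planted_edge_set)) {
      if (length(planted_edge_set) != planted_edges)
        stopf("planted_edge_set length must equal planted_edges")
      if (any(planted_edge_set < 1 | planted_edge_set > E))
        stopf("planted_edge_set indices must lie in 1..E (E = %d)", E)
    }
  })
  cfg
}

# Structural coefficients of the phenotype model implied by a config.
# Non-mixture: score_base = affine(skewed(a v + e1)); the follow-up latent is
#   y = beta * base_std + c * v + sigma * e2 with unit variance, where beta is
#   solved so that cor(base, y) equals the target:
#   cor = beta + c * a * kappa, with kappa the skew attenuation of cor(s, Z).
# Mixture: the same within each group with skew 0, with the within-group
#   correlation solved so the pooled correlation matches the target.
sim_coefs <- function(cfg) {
  a <- cfg$v_loading
  cc <- cfg$v_outcome
  if (is.null(cfg$mixture)) {
    kappa <- if (cfg$skew == 0) 1 else sas_moments(cfg$skew)$kappa
    beta <- cfg$base_y1_r - cc * a * kappa
    s2 <- 1 - beta^2 - cc^2 - 2 * beta * cc * a * kappa
    if (s2 <= 0)
      stopf("impossible correlation parameters: base_y1_r = %.2f with v_loading %.2f, v_outcome %.2f",
            cfg$base_y1_r, a, cc)
    rho_vy <- beta * a * kappa + cc
    list(beta = beta, sigma = sqrt(s2), kappa = kappa, rho_vy = rho_vy,
         sd_y1 = cfg$score_y1_sd)
  } else {
    mx <- cfg$mixture
    p <- c(clinical = mx$prob, control = 1 - mx$prob)
    g <- rbind(clinical = mx$clinical, control = mx$control)
    colnames(g) <- c("base_mean", "base_sd", "y1_mean", "y1_sd")
    mu_b <- sum(p * g[, "base_mean"]); mu_y <- sum(p * g[, "y1_mean"])
    var_b <- sum(p * (g[, "base_sd"]^2 + (g[, "base_mean"] - mu_b)^2))
    var_y <- sum(p * (g[, "y1_sd"]^2 + (g[, "y1_mean"] - mu_y)^2))
    cov_between <- sum(p * (g[, "base_mean"] - mu_b) * (g[, "y1_mean"] - mu_y))
    denom <- sum(p * g[, "base_sd"] * g[, "y1_sd"])
    r_w <- (cfg$base_y1_r * sqrt(var_b * var_y) - cov_between) / denom
    if (abs(r_w) >= 1)
      stopf("impossible correlation parameters: mixture cannot reach base_y1_r = %.2f",
            cfg$base_y1_r)
    beta <- r_w - cc * a
    s2 <- 1 - beta^2 - cc^2 - 2 * beta * cc * a
    if (s2 <= 0) stopf("impossible correlation parameters in mixture groups")
    # cov(v, score_y1) pools the per-group latent covariances
    rho_vy <- sum(p * g[, "y1_sd"] * (beta * a + cc)) / sqrt(var_y)
    list(beta = beta, sigma = sqrt(s2), kappa = 1, rho_vy = rho_vy,
         r_within = r_w, p_clinical = mx$prob, groups = g,
         mix_mean_b = mu_b, mix_sd_b = sqrt(var_b),
         mix_mean_y = mu_y, mix_sd_y = sqrt(var_y), sd_y1 = sqrt(var_y))
  }
}

#' Marginal edge-outcome correlation implied by a simulation config
#'
#' For a planted edge with loading `gamma`, the marginal Pearson correlation
#' with the follow-up score is
#' \deqn{r = \gamma\,\rho_{vy} / \sqrt{\gamma^2 + \sigma_e^2 + \sigma_s^2}}
#' where \eqn{\rho_{vy}} is the vulnerability-outcome correlation implied by
#' the phenotype model, \eqn{\sigma_e} the edge noise SD and \eqn{\sigma_s}
#' the site-offset SD. `gamma_for_edge_r` inverts the relation.
#'
#' @param config a [cpm_sim_config()].
#' @param gamma edge loading (defaults to the config's).
#' @return Implied marginal Pearson r (or, for `gamma_for_edge_r`, the
#'   loading that achieves `target_r`).
#' @export
implied_edge_r <- function(config, gamma = config$gamma) {
  co <- sim_coefs(config)
  s0sq <- config$edge_sigma^2 + config$site_sd^2
  gamma * co$rho_vy / sqrt(gamma^2 + s0sq)
}

#' @rdname implied_edge_r
#' @param target_r desired marginal edge-outcome Pearson correlation.
#' @export
gamma_for_edge_r <- function(config, target_r) {
  co <- sim_coefs(config)
  if (abs(target_r) >= abs(co$rho_vy))
    stopf("target edge r = %.3f is unreachable: |r| must be below rho_vy = %.3f",
          target_r, co$rho_vy)
  s0 <- sqrt(config$edge_sigma^2 + config$site_sd^2)
  target_r * s0 / sqrt(co$rho_vy^2 - target_r^2)
}

#' Calibrated presets for two reference cohort profiles
#'
#' `"abcd_like"` targets a large multi-site children's cohort: n = 3718
#' across 21 sites, positively skewed t-score-like severity with baseline
#' mean 53.51 / SD 6.02, follow-up mean 53.48 / SD 6.06, and
#' baseline-follow-up r = 0.68. `"banda_like"` targets a small single-site
#' clinical adolescent cohort: n = 150, 61.3% female, a clinical/control
#' mixture with overall baseline mean 49.11 / SD 15.28, follow-up mean
#' 44.62 / SD 11.39, and r = 0.63.
#'
#' @param name `"abcd_like"` or `"banda_like"`.
#' @param ... overrides passed to [cpm_sim_config()] on top of the preset.
#' @return A [cpm_sim_config()].
#' @examples
#' cpm_preset("abcd_like")$n_participants  # 3718
#' @export
cpm_preset <- function(name = c("abcd_like", "banda_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    abcd_like = list(n_participants = 3718L, n_sites = 21L, n_regions = 352L,
                     family_rate = 0.2, planted_edges = 20L, planted_r = 0.08,
                     score_base_mean = 53.51, score_base_sd = 6.02,
                     score_y1_mean = 53.48, score_y1_sd = 6.06,
                     base_y1_r = 0.68, skew = 0.35,
                     sex_prop_f = 0.529, age_range = c(9, 11)),
    banda_like = list(n_participants = 150L, n_sites = 1L, n_regions = 352L,
                      family_rate = 0, planted_edges = 20L, planted_r = 0.08,
                      base_y1_r = 0.63, skew = 0,
                      sex_prop_f = 0.613, age_range = c(14, 17),
                      mixture = list(prob = (49.11 - 36.04) / (56.47 - 36.04),
                                     clinical = c(56.47, 14.26, 49.07, 11.50),
                                     control = c(36.04, 4.43, 36.70, 5.25))))
  args <- utils::modifyList(base, list(...))
  do.call(cpm_sim_config, args)
}

#' Simulate a multi-site, family-nested cohort with planted edge signal
#'
#' Generates phenotypes and a participants-by-edges Fisher-z matrix from the
#' generative model described in [cpm_sim_config()]. A per-participant latent
#' vulnerability drives both the severity scores and `planted_edges`
#' connectome edges, so the CPM pipeline has a recoverable ground truth;
#' setting `gamma = 0` (and no `planted_r`) yields a null cohort. The same
#' seed always reproduces the same cohort.
#'
#' @param config a [cpm_sim_config()].
#' @param seed optional override of `config$seed`.
#' @return A `simulated_cohort` (also an `aligned_cohort`) with the extra
#'   element `ground_truth`: a data frame of the planted edges (`edge`, `i`,
#'   `j`, `gamma`).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))

  n <- cfg$n_participants
  co <- sim_coefs(cfg)

  # family units: sibling pairs for family_rate of the cohort, singletons else
  n_pairs <- floor(cfg$family_rate * n / 2)
  unit_sizes <- c(rep(2L, n_pairs), rep(1L, n - 2L * n_pairs))
  n_units <- length(unit_sizes)
  unit_of <- rep(seq_len(n_units), times = unit_sizes)
  # families never straddle sites, preserving site-disjoint CV splits
  unit_site <- sample(rep_len(seq_len(cfg$n_sites), n_units))
  site <- unit_site[unit_of]

  # latent vulnerability, shared within family
  rho_f <- cfg$intra_family_r
  fam_part <- rnorm(n_units)[unit_of]
  v <- sqrt(rho_f) * fam_part + sqrt(1 - rho_f) * rnorm(n)

  a <- cfg$v_loading
  base_lat <- a * v + sqrt(1 - a^2) * rnorm(n)     # N(0,1) baseline latent
  y_noise <- rnorm(n)

  if (is.null(cfg$mixture)) {
    base_std <- sas_standardize(base_lat, cfg$skew)
    y_std <- co$beta * base_std + cfg$v_outcome * v + co$sigma * y_noise
    score_base <- cfg$score_base_mean + cfg$score_base_sd * base_std
    score_y1 <- cfg$score_y1_mean + cfg$score_y1_sd * y_std
    group <- rep("none", n)
    y_unit <- y_std   # unit-variance follow-up latent (for the motion draw)
  } else {
    clin <- runif(n) < co$p_clinical
    group <- ifelse(clin, "clinical", "control")
    g <- co$groups[group, , drop = FALSE]
    y_std <- co$beta * base_lat + cfg$v_outcome * v + co$sigma * y_noise
    score_base <- g[, "base_mean"] + g[, "base_sd"] * base_lat
    score_y1 <- g[, "y1_mean"] + g[, "y1_sd"] * y_std
    y_unit <- (score_y1 - co$mix_mean_y) / co$mix_sd_y
  }

  r_m <- cfg$motion_outcome_r
  mean_fd <- pmax(cfg$motion_mean +
                    cfg$motion_sd * (r_m * y_unit + sqrt(1 - r_m^2) * rnorm(n)),
                  1e-4)
  sex <- ifelse(runif(n) < cfg$sex_prop_f, "F", "M")
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])

  pheno <- phenotype_table(data.frame(
    participant_id = sprintf("sub-%05d", seq_len(n)),
    site_id = sprintf("site-%02d", site),
    family_id = sprintf("fam-%05d", unit_of),
    sex = sex, age = age, mean_fd = mean_fd,
    score_base = score_base, score_y1 = score_y1, group = group,
    stringsAsFactors = FALSE))

  # edges
  E <- n_edges(cfg$n_regions)
  K <- cfg$planted_edges
  gamma <- if (!is.null(cfg$planted_r)) gamma_for_edge_r(cfg, cfg$planted_r)
           else cfg$gamma
  planted <- if (!is.null(cfg$planted_edge_set)) sort(as.integer(cfg$planted_edge_set))
             else if (K > 0) sort(sample.int(E, K)) else integer(0)
  # all planted loadings share one sign: the network-strength feature sums
  # |z|, under which oppositely-signed loadings would cancel
  gamma_k <- rep(gamma, K)

  x <- matrix(rnorm(n * E, sd = cfg$edge_sigma), n, E)
  x <- x + cfg$edge_mu
  if (cfg$site_sd > 0) {
    site_off <- matrix(rnorm(cfg$n_sites * E, sd = cfg$site_sd), cfg$n_sites, E)
    x <- x + site_off[site, , drop = FALSE]
  }
  if (K > 0)
    x[, planted] <- x[, planted] + outer(v, gamma_k)
  rownames(x) <- pheno$participant_id
  edges <- as_edge_matrix(x, cfg$n_regions)

  em <- edge_index_map(cfg$n_regions)
  gt <- data.frame(edge = planted, i = em$i[planted], j = em$j[planted],
                   gamma = gamma_k)
  out <- align_cohort(edges, pheno)
  out$ground_truth <- gt
  out$vulnerability <- setNames(v, pheno$participant_id)
  out$config <- cfg
  class(out) <- c("simulated_cohort", class(out))
  out
}

#' Write a simulated cohort to disk
#'
#' Writes the phenotype CSV, the edge-matrix container (with its JSON
#' sidecar), and — for simulated cohorts — the ground-truth planted-edge
#' CSV, into one directory.
#'
#' @param cohort an `aligned_cohort` or `simulated_cohort`.
#' @param dir output directory (created if missing).
#' @param format edge-matrix format passed to [write_edge_matrix()].
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, format = "auto") {
  check_aligned(cohort)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(phenotypes = file.path(dir, "phenotypes.csv"),
                edges = file.path(dir, "edges.bin"))
  write.csv(cohort$phenotypes, paths$phenotypes, row.names = FALSE)
  em <- cohort$edges
  if (is.null(attr(em, "n_regions")))
    attr(em, "n_regions") <- cohort$n_regions
  write_edge_matrix(em, paths$edges, format = format)
  if (!is.null(cohort$ground_truth)) {
    paths$ground_truth <- file.path(dir, "ground_truth_edges.csv")
    write.csv(cohort$ground_truth, paths$ground_truth, row.names = FALSE)
  }
  invisible(paths)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  NextMethod()
  cat(sprintf("  planted edges: %d (|gamma| = %.4g), seed %d\n",
              nrow(x$ground_truth),
              if (nrow(x$ground_truth)) abs(x$ground_truth$gamma[1]) else 0,
              x$config$seed))
  invisible(x)
}
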