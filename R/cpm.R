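#' Split a cohort by randomly halving acquisition sites
#'
#' Partitions the distinct sites at random, assigning \eqn{\lceil S/2\rceil}
#' sites (and every participant acquired at them) to the training set and
#' the rest to the test set. Splitting whole sites, rather than
#' participants, prevents site- and family-level information leaking between
#' the two sets.
#'
#' @param site_ids character vector, one site id per participant.
#' @param seed optional seed; the same seed reproduces the split.
#' @return List with integer participant indices `train` and `test`, and the
#'   site ids `train_sites` and `test_sites`.
#' @export
split_half_sites <- function(site_ids, seed = NULL) {
  old <- local_seed(seed)
  if (!is.null(seed)) on.exit(restore_seed(old))
  sites <- unique(site_ids)
  s <- length(sites)
  if (s < 2L)
    stopf(paste0("only one site present; site-based splitting is impossible. ",
                 "Use participant_split = TRUE for a family-preserving ",
                 "participant-level split"))
  shuffled <- sample(sites)
  n_train <- ceiling(s / 2)
  train_sites <- shuffled[seq_len(n_train)]
  test_sites <- shuffled[-seq_len(n_train)]
  list(train = which(site_ids %in% train_sites),
       test = which(site_ids %in% test_sites),
       train_sites = sort(train_sites), test_sites = sort(test_sites))
}

# Family-preserving participant-level split for single-site cohorts:
# whole families are assigned to one side or the other.
split_half_families <- function(family_ids) {
  fams <- unique(family_ids)
  shuffled <- sample(fams)
  n_train <- ceiling(length(fams) / 2)
  train_f <- shuffled[seq_len(n_train)]
  list(train = which(family_ids %in% train_f),
       test = which(!(family_ids %in% train_f)),
       train_sites = NA_character_, test_sites = NA_character_)
}

# One pass of n_iterations CPM cross-validation iterations over a cohort.
# Returns per-iteration rho (NA where no edge survived screening or the
# split degenerated), selected-edge index lists, and split bookkeeping.
cv_run <- function(cohort, n_iterations, alpha, adjust, participant_split,
                   min_split_n, collect_masks = TRUE) {
  y <- cohort$phenotypes$score_y1
  cm <- cohort$covariates
  site <- cohort$phenotypes$site_id
  fam <- cohort$phenotypes$family_id
  rhos <- rep(NA_real_, n_iterations)
  masks <- if (collect_masks) vector("list", n_iterations) else NULL
  splits <- vector("list", n_iterations)
  n_zero_edge <- 0L
  n_degenerate <- 0L
  for (it in seq_len(n_iterations)) {
    sp <- if (participant_split) split_half_families(fam)
          else split_half_sites(site)
    splits[[it]] <- list(train_sites = sp$train_sites,
                         test_sites = sp$test_sites,
                         n_train = length(sp$train), n_test = length(sp$test))
    if (length(sp$train) < max(min_split_n, 20L) ||
        length(sp$test) < max(min_split_n, 7L)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    sc <- screen_core(cohort, adjust, sp$train)
    # p < alpha is equivalent to |rho| above the critical correlation
    tcrit <- stats::qt(1 - alpha / 2, sc$df)
    rcrit <- tcrit / sqrt(sc$df + tcrit^2)
    idx <- which(sc$ok & abs(sc$rho) > rcrit)
    if (collect_masks) masks[[it]] <- idx
    if (!length(idx)) {
      n_zero_edge <- n_zero_edge + 1L
      next
    }
    str_all <- .strength_sums(cohort$edges, idx)
    str_tr <- str_all[sp$train]
    if (var(str_tr) == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    model <- fit_strength_model(str_tr, y[sp$train])
    pred <- predict(model, str_all[sp$test])
    if (var(pred) == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    rhos[it] <- partial_spearman(y[sp$test], pred,
                                 cm[sp$test, , drop = FALSE])$rho
  }
  list(rhos = rhos, masks = masks, splits = splits,
       n_zero_edge = n_zero_edge, n_degenerate = n_degenerate)
}

#' Fit a connectome-based predictive model
#'
#' The CPM procedure under leave-half-sites-out cross-validation. Each
#' iteration (i) randomly halves the sites into a training and a test set;
#' (ii) retains, within the training set only, the edges whose (partial)
#' Spearman correlation with the follow-up score has `p < alpha`;
#' (iii) sums the absolute Fisher-z values of the retained edges into a
#' per-participant network strength and fits a linear strength-to-outcome
#' model on the training set; (iv) applies the training mask and fitted line
#' to the test set and scores the prediction as the partial Spearman
#' correlation between observed and predicted scores, adjusted for baseline
#' score, sex, age, and mean head motion. The per-iteration correlations are
#' averaged into `mean_rho`. Iterations in which no edge survives screening
#' are excluded from the mean and counted.
#'
#' The fit also derives the consensus network — the edges passing the screen
#' on the full cohort, without splitting — together with a full-cohort
#' strength model, which [predict.cpm()] and [apply_network()] use for new
#' cohorts. Optional permutation testing (`n_permutations > 0`) reruns the
#' cross-validation on datasets whose connectome-to-phenotype linkage has
#' been shuffled (outcome and covariates move together), and reports
#' `p_perm`, the proportion of permuted mean correlations strictly larger
#' than the observed one.
#'
#' @param cohort an `aligned_cohort` (see [align_cohort()] or
#'   [simulate_cohort()]).
#' @param n_iterations cross-validation iterations (default 100).
#' @param alpha edge-retention threshold (default 0.001).
#' @param adjust screen edges with covariate adjustment? (default TRUE; the
#'   test-set evaluation is always covariate-adjusted).
#' @param n_permutations permutations for the significance test (default 0 =
#'   skip; see [cpm_permute()] to add one later).
#' @param perm_iterations cross-validation iterations per permutation.
#'   The default (`n_iterations`) keeps the permuted and observed statistics
#'   exchangeable and the test exactly calibrated; smaller values are faster
#'   but inflate the null spread (split-to-split variability shrinks with
#'   the number of iterations averaged), making the test conservative.
#' @param participant_split use a family-preserving participant-level split
#'   instead of the site split (required for single-site cohorts).
#' @param min_split_n smallest acceptable training-set size per iteration.
#' @param seed seed for split and permutation randomness.
#' @param keep_masks store per-iteration selected-edge indices? (default
#'   TRUE).
#' @return A `cpm` object with per-iteration `rhos`, `mean_rho`, the
#'   `consensus` network mask, the full-cohort `strength_model`, split
#'   bookkeeping, and (if requested) the `permutation` results.
#' @examples
#' cfg <- cpm_sim_config(n_participants = 200, n_regions = 20,
#'                       planted_edges = 5, planted_r = 0.25, seed = 7)
#' fit <- cpm(simulate_cohort(cfg), n_iterations = 5, alpha = 0.01, seed = 1)
#' fit$mean_rho
#' @export
cpm <- function(cohort, n_iterations = 100L, alpha = 0.001, adjust = TRUE,
                n_permutations = 0L, perm_iterations = n_iterations,
                participant_split = FALSE, min_split_n = 30L, seed = NULL,
                keep_masks = TRUE) {
  check_aligned(cohort)
  if (n_iterations < 1L) stopf("n_iterations must be >= 1")
  n_sites <- length(unique(cohort$phenotypes$site_id))
  if (n_sites < 2L && !participant_split)
    stopf("cohort has a single site; set participant_split = TRUE")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  cohort <- prepare_cohort_cache(cohort)

  res <- cv_run(cohort, n_iterations, alpha, adjust, participant_split,
                min_split_n, collect_masks = keep_masks)
  mean_rho <- mean(res$rhos, na.rm = TRUE)
  if (res$n_zero_edge > 0)
    message(sprintf("%d of %d iterations selected zero edges and were excluded from the mean",
                    res$n_zero_edge, n_iterations))

  consensus <- consensus_network(cohort, alpha = alpha, adjust = adjust)
  sm <- NULL
  if (nrow(consensus) > 0) {
    strengths <- network_strength(cohort$edges, attr(consensus, "edge_idx"))
    if (var(strengths) > 0)
      sm <- fit_strength_model(strengths, cohort$phenotypes$score_y1)
  }

  fit <- structure(list(
    call = match.call(),
    settings = list(n_iterations = n_iterations, alpha = alpha,
                    adjust = adjust, participant_split = participant_split,
                    min_split_n = min_split_n, seed = seed),
    rhos = res$rhos, mean_rho = mean_rho,
    masks = res$masks, splits = res$splits,
    n_zero_edge = res$n_zero_edge, n_degenerate = res$n_degenerate,
    consensus = consensus, strength_model = sm,
    cohort = cohort, permutation = NULL), class = "cpm")

  if (n_permutations > 0)
    fit <- cpm_permute(fit, n_permutations = n_permutations,
                       perm_iterations = perm_iterations)
  fit
}

#' Permutation significance test for a fitted CPM
#'
#' Reruns the cross-validation on permuted datasets in which each
#' participant's connectome is relinked to another participant's complete
#' phenotype record (outcome and covariates stay together), building an
#' empirical null distribution of mean correlations. Significance is the
#' proportion of permuted values strictly larger than the observed
#' `mean_rho`.
#'
#' @param object a fitted [cpm()] model.
#' @param n_permutations number of permutations (default 1000).
#' @param perm_iterations cross-validation iterations per permutation.
#' @param seed optional seed for the permutation stream.
#' @param plus_one use the (1 + #larger) / (1 + P) estimator instead of the
#'   strict proportion (default FALSE).
#' @return The model with a `permutation` element: `null_rhos`, `p_perm`,
#'   and the permutation settings.
#' @export
cpm_permute <- function(object, n_permutations = 1000L,
                        perm_iterations = object$settings$n_iterations,
                        seed = NULL, plus_one = FALSE) {
  if (!inherits(object, "cpm")) stopf("object must be a fitted cpm model")
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  cohort <- object$cohort
  if (is.null(cohort)) stopf("the fitted model does not retain its cohort")
  old <- local_seed(seed)
  if (!is.null(seed)) on.exit(restore_seed(old))
  n <- cohort_n(cohort)
  st <- object$settings
  cohort <- prepare_cohort_cache(cohort)
  null_rhos <- rep(NA_real_, n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    shuffled <- cohort
    shuffled$edges <- cohort$edges[perm, , drop = FALSE]
    rownames(shuffled$edges) <- cohort$phenotypes$participant_id
    # the column sort order survives a row permutation up to relabelling
    inv <- integer(n); inv[perm] <- seq_len(n)
    shuffled$col_order <- matrix(inv[cohort$col_order], n)
    res <- cv_run(shuffled, perm_iterations, st$alpha, st$adjust,
                  st$participant_split, st$min_split_n, collect_masks = FALSE)
    null_rhos[b] <- mean(res$rhos, na.rm = TRUE)
  }
  ok <- is.finite(null_rhos)
  n_larger <- sum(null_rhos[ok] > object$mean_rho)
  p_perm <- if (plus_one) (1 + n_larger) / (1 + sum(ok))
            else n_larger / n_permutations
  object$permutation <- list(null_rhos = null_rhos, p_perm = p_perm,
                             n_permutations = n_permutations,
                             perm_iterations = perm_iterations,
                             plus_one = plus_one)
  object
}

#' Consensus network: full-cohort edge screen
#'
#' Screens every edge on the complete cohort (no cross-validation split) and
#' returns the retained edges — the consensus "symptoms network" — with each
#' edge's correlation and association sign.
#'
#' @inheritParams screen_edges
#' @return A `network_mask` data frame with columns `edge`, `region_i`,
#'   `region_j` (1-based), `rho`, `sign` (`"+"`/`"-"`), and provenance
#'   attributes (`alpha`, `adjust`, `n`, `n_regions`, `edge_idx`).
#' @export
consensus_network <- function(cohort, alpha = 0.001, adjust = TRUE) {
  check_aligned(cohort)
  scr <- screen_edges(cohort, alpha = alpha, adjust = adjust)
  idx <- which(scr$mask)
  if (!length(idx))
    warning("no edge passed the screen; returning an empty network mask")
  em <- edge_index_map(cohort$n_regions)
  out <- data.frame(edge = idx, region_i = em$i[idx], region_j = em$j[idx],
                    rho = scr$rho[idx],
                    sign = ifelse(scr$rho[idx] >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  attr(out, "n") <- scr$n
  attr(out, "n_regions") <- cohort$n_regions
  attr(out, "edge_idx") <- idx
  class(out) <- c("network_mask", "data.frame")
  out
}

#' Write or read a network mask
#'
#' CSV with 1-based region indices plus a JSON provenance sidecar
#' (`<path>.json`) recording the screen settings and cohort size.
#'
#' @param mask a `network_mask`.
#' @param path CSV path.
#' @export
write_network_mask <- function(mask, path) {
  write.csv(as.data.frame(mask)[c("region_i", "region_j", "rho", "sign")],
            path, row.names = FALSE, quote = FALSE)
  prov <- list(alpha = attr(mask, "alpha"), adjust = attr(mask, "adjust"),
               n = attr(mask, "n"), n_regions = attr(mask, "n_regions"),
               n_edges_selected = nrow(mask),
               region_index_base = 1)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_mask
#' @export
read_network_mask <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  prov <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nr <- prov$n_regions
  em <- edge_index_map(nr)
  key <- paste(df$region_i, df$region_j)
  idx <- match(key, paste(em$i, em$j))
  if (anyNA(idx)) stopf("network mask contains region pairs outside the edge map")
  out <- data.frame(edge = idx, region_i = df$region_i, region_j = df$region_j,
                    rho = df$rho, sign = df$sign, stringsAsFactors = FALSE)
  attr(out, "alpha") <- prov$alpha
  attr(out, "adjust") <- prov$adjust
  attr(out, "n") <- prov$n
  attr(out, "n_regions") <- nr
  attr(out, "edge_idx") <- idx
  class(out) <- c("network_mask", "data.frame")
  out
}

#' @export
print.cpm <- function(x, ...) {
  cat("Connectome-based predictive model (leave-half-sites-out CV)\n")
  cat(sprintf("  iterations: %d   edge threshold: p < %g (%s screen)\n",
              x$settings$n_iterations, x$settings$alpha,
              if (x$settings$adjust) "adjusted" else "plain"))
  cat(sprintf("  mean test-set partial Spearman rho: %.4f\n", x$mean_rho))
  if (x$n_zero_edge > 0)
    cat(sprintf("  zero-edge iterations excluded: %d\n", x$n_zero_edge))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p (P = %d): %.4f\n",
                x$permutation$n_permutations, x$permutation$p_perm))
  cat(sprintf("  consensus network: %d edges\n", nrow(x$consensus)))
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  r <- object$rhos
  sel <- lengths(object$masks)
  out <- list(
    mean_rho = object$mean_rho,
    rho_quantiles = quantile(r, c(0, .25, .5, .75, 1), na.rm = TRUE),
    n_iterations = object$settings$n_iterations,
    n_zero_edge = object$n_zero_edge,
    n_degenerate = object$n_degenerate,
    edges_selected = if (length(sel)) quantile(sel, c(0, .5, 1)) else NULL,
    consensus_size = nrow(object$consensus),
    p_perm = if (!is.null(object$permutation)) object$permutation$p_perm,
    settings = object$settings)
  class(out) <- "summary.cpm"
  out
}

#' @export
print.summary.cpm <- function(x, ...) {
  cat("CPM summary\n")
  cat(sprintf("  mean rho: %.4f over %d iterations (%d zero-edge, %d degenerate)\n",
              x$mean_rho, x$n_iterations, x$n_zero_edge, x$n_degenerate))
  cat("  per-iteration rho quantiles:\n")
  print(round(x$rho_quantiles, 4))
  if (!is.null(x$edges_selected)) {
    cat("  edges selected per iteration (min/median/max): ")
    cat(paste(x$edges_selected, collapse = " / "), "\n")
  }
  cat(sprintf("  consensus network: %d edges\n", x$consensus_size))
  if (!is.null(x$p_perm)) cat(sprintf("  p_perm: %.4f\n", x$p_perm))
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) {
  if (is.null(object$strength_model))
    return(c(intercept = NA_real_, slope = NA_real_))
  c(intercept = object$strength_model$intercept,
    slope = object$strength_model$slope)
}

#' Predict follow-up scores from a fitted CPM
#'
#' Applies the consensus network mask and the full-cohort strength model to
#' a cohort: per-participant strengths are the sum of absolute z-values over
#' the consensus edges, mapped through the fitted line.
#'
#' @param object a fitted [cpm()] model.
#' @param newdata an `aligned_cohort`; defaults to the discovery cohort.
#' @param ... unused.
#' @return Named numeric vector of predicted scores.
#' @export
predict.cpm <- function(object, newdata = NULL, ...) {
  cohort <- if (is.null(newdata)) object$cohort else newdata
  check_aligned(cohort)
  if (is.null(object$strength_model))
    stopf("the consensus network is empty; no strength model was fit")
  strengths <- apply_network(object$consensus, cohort)
  predict(object$strength_model, strengths)
}

#' @export
fitted.cpm <- function(object, ...) predict(object)

#' @export
residuals.cpm <- function(object, ...) {
  object$cohort$phenotypes$score_y1 - predict(object)
}

#' Diagnostic plots for a fitted CPM
#'
#' Base-graphics histogram of the per-iteration test-set correlations and,
#' when a permutation test is attached, the permutation null distribution
#' with the observed mean marked.
#'
#' @param x a fitted [cpm()] model.
#' @param ... passed to [graphics::hist()].
#' @export
plot.cpm <- function(x, ...) {
  has_perm <- !is.null(x$permutation)
  if (has_perm) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::hist(x$rhos, main = "Test-set correlations",
                 xlab = expression(rho), col = "grey80", border = "white", ...)
  graphics::abline(v = x$mean_rho, col = "firebrick", lwd = 2)
  if (has_perm) {
    graphics::hist(x$permutation$null_rhos, main = "Permutation null",
                   xlab = expression(bar(rho)), col = "grey80",
                   border = "white", ...)
    graphics::abline(v = x$mean_rho, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
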