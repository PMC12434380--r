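#' Rank transform with midranks for ties
#'
#' Thin, validated wrapper over `base::rank(x, ties.method = "average")`,
#' the rank transform underlying every Spearman statistic in the package.
#'
#' @param x numeric vector.
#' @return Ranks in `[1, length(x)]`; tied values receive their average rank.
#' @examples
#' rank_transform(c(5, 5, 1))  # 2.5 2.5 1
#' @export
rank_transform <- function(x) {
  if (!length(x)) stopf("cannot rank an empty vector")
  if (any(!is.finite(x))) stopf("cannot rank non-finite values")
  rank(x, ties.method = "average")
}


#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y`, and each covariate column, residualizes the
#' ranked `x` and `y` on the ranked covariates (plus an intercept) by least
#' squares, and correlates the residuals. With no covariates this reduces
#' exactly to the classic Spearman rank correlation. The p-value uses the
#' t approximation \eqn{t = \rho\sqrt{(n-2-k)/(1-\rho^2)}} on
#' \eqn{n-2-k} degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix with one row per observation.
#' @return List with `rho`, `p`, `n`, and `df`.
#' @examples
#' x <- rnorm(30); y <- x^3 + rnorm(30, sd = .1)
#' partial_spearman(x, y)$rho        # close to 1
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2L) stopf("need n > k + 2 observations (n = %d, k = %d)", n, k)
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  if (var(rx) == 0) stopf("x is constant after ranking")
  if (var(ry) == 0) stopf("y is constant after ranking")
  if (k > 0) {
    cm <- as.matrix(covariates)
    if (nrow(cm) != n) stopf("covariate rows do not match observations")
    rc <- apply(cm, 2L, rank_transform)
    qc <- qr(cbind(1, rc))
    if (qc$rank < k + 1L) stopf("covariates are rank-deficient after ranking")
    rx <- qr.resid(qc, rx)
    ry <- qr.resid(qc, ry)
  }
  rho <- cor(rx, ry)
  df <- n - 2L - k
  p <- rho_pvalue(rho, df)
  list(rho = rho, p = p, n = n, df = df)
}

rho_pvalue <- function(rho, df) {
  r2 <- pmin(rho^2, 1 - 1e-15)
  tval <- abs(rho) * sqrt(df / (1 - r2))
  2 * pt(tval, df, lower.tail = FALSE)
}

#' Screen connectome edges against the follow-up outcome
#'
#' Computes, for every edge, the (partial) Spearman correlation between the
#' edge's Fisher-z values and the follow-up severity score, and retains
#' edges with `p < alpha` (strict inequality). With `adjust = TRUE`
#' (default) the correlation is adjusted for the four covariates (baseline
#' score, sex, age, mean FD); with `adjust = FALSE` it is the plain Spearman
#' correlation. The computation is vectorized across edges: subset ranks
#' come from cached per-column sort orders and one fused pass accumulates
#' the residual cross-products, so the screen costs the same inside a
#' cross-validation split or a permutation as on the full cohort.
#'
#' @param cohort an `aligned_cohort`.
#' @param alpha retention threshold on the per-edge p-value (default 0.001).
#' @param adjust adjust for covariates? (default TRUE).
#' @param rows optional integer subset of participants (used by the
#'   cross-validation loop to screen the training set only).
#' @return An `edge_screen`: list with per-edge `rho`, `p`, logical `mask`,
#'   `sign` (+1/-1 where selected, NA elsewhere), and the screen settings.
#' @export
screen_edges <- function(cohort, alpha = 0.001, adjust = TRUE, rows = NULL) {
  check_aligned(cohort)
  if (is.null(rows)) rows <- seq_len(nrow(cohort$edges))
  sc <- screen_core(cohort, adjust, rows)
  p <- rep(1, length(sc$rho))
  p[sc$ok] <- rho_pvalue(sc$rho[sc$ok], sc$df)
  mask <- p < alpha
  structure(list(rho = sc$rho, p = p, mask = mask,
                 sign = ifelse(mask, sign(sc$rho), NA_real_),
                 alpha = alpha, adjust = adjust, n = sc$n, df = sc$df),
            class = "edge_screen")
}

# Precompute per-column sort orders and tie flags for a cohort's edges and
# phenotype columns. The cache is reused across every cross-validation
# split and permutation, replacing per-split sorting with a linear scan.
prepare_cohort_cache <- function(cohort) {
  if (is.null(cohort$col_order)) {
    cohort$col_order <- .order_columns(cohort$edges)
    cohort$col_ties <- .column_has_ties(cohort$edges, cohort$col_order)
  }
  if (is.null(cohort$pheno_src)) {
    cohort$pheno_src <- cbind(y = cohort$phenotypes$score_y1,
                              cohort$covariates)
    cohort$pheno_ord <- .order_columns(cohort$pheno_src)
    cohort$pheno_ties <- .column_has_ties(cohort$pheno_src, cohort$pheno_ord)
  }
  cohort
}

# Shared computational core of the edge screen: subset ranks via cached
# column orders, then residual cross-products against the ranked covariates
# without ever residualizing the full edge matrix:
#   <x_res, y_res> = <x, y_res>,  ||x_res||^2 = x'x - (C'x)'(C'C)^-1(C'x).
screen_core <- function(cohort, adjust, rows) {
  rows <- as.integer(rows)
  n <- length(rows)
  if (n < 20L) stopf("edge screening needs at least 20 participants, got %d", n)
  x <- cohort$edges
  ord <- cohort$col_order
  ties <- cohort$col_ties
  if (is.null(ord)) {
    ord <- .order_columns(x)
    ties <- .column_has_ties(x, ord)
  }
  if (is.null(ties)) ties <- .column_has_ties(x, ord)
  if (!is.null(cohort$pheno_ord)) {
    pr <- .subset_rank_columns(cohort$pheno_src, cohort$pheno_ord, rows,
                               cohort$pheno_ties)
  } else {
    pm <- cbind(cohort$phenotypes$score_y1, cohort$covariates)
    pr <- apply(pm[rows, , drop = FALSE], 2L, rank_transform)
  }
  ry <- pr[, 1L]
  if (var(ry) == 0) stopf("outcome is constant; cannot screen edges")
  k <- if (adjust) ncol(pr) - 1L else 0L
  C <- if (adjust) cbind(1, pr[, -1L, drop = FALSE]) else matrix(1, n, 1L)
  G <- crossprod(C)
  Ginv <- tryCatch(solve(G), error = function(e)
    stopf("covariates are rank-deficient after ranking"))
  ye <- ry - as.numeric(C %*% (Ginv %*% crossprod(C, ry)))
  st <- .screen_stats(x, ord, rows, ties, ye, C, Ginv)
  num <- st$num
  ssx <- st$ssx
  ssx_raw <- st$ssx_raw
  ssy <- sum(ye^2)
  ok <- ssx > 1e-10 * ssx_raw + 1e-12
  rho <- rep(0, length(ok))
  rho[ok] <- num[ok] / sqrt(ssx[ok] * ssy)
  rho <- pmin(pmax(rho, -1), 1)
  list(rho = rho, ok = ok, n = n, k = k, df = n - 2L - k)
}

#' @export
print.edge_screen <- function(x, ...) {
  cat(sprintf("Edge screen: %d of %d edges at p < %g (%s), n = %d\n",
              sum(x$mask), length(x$mask), x$alpha,
              if (x$adjust) "covariate-adjusted Spearman" else "plain Spearman",
              x$n))
  invisible(x)
}

#' Network strength: sum of absolute Fisher-z values over a mask
#'
#' The scalar CPM feature: for each participant, the sum of the absolute
#' z-values of the selected edges. An empty mask gives strength 0.
#'
#' @param edges numeric edge vector (one participant) or a
#'   participants-by-edges matrix.
#' @param mask logical vector over edges, or integer edge indices.
#' @return A numeric scalar (vector input) or per-participant vector.
#' @examples
#' network_strength(c(0.5, -0.5, 1), c(TRUE, TRUE, TRUE))  # 2
#' @export
network_strength <- function(edges, mask) {
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (is.matrix(edges)) {
    if (is.logical(mask) && length(mask) != ncol(edges))
      stopf("mask length %d does not match %d edges", length(mask), ncol(edges))
    out <- .strength_sums(unclass(edges), idx)
    names(out) <- rownames(edges)
    out
  } else {
    if (is.logical(mask) && length(mask) != length(edges))
      stopf("mask length %d does not match %d edges", length(mask), length(edges))
    if (!length(idx)) return(0)
    v <- edges[idx]
    if (any(!is.finite(v))) stopf("non-finite edge value inside the mask")
    sum(abs(v))
  }
}

#' Fit and apply the strength-to-outcome linear model
#'
#' Ordinary least squares of the outcome on the per-participant network
#' strength; the fitted line converts test-set strengths into predicted
#' scores.
#'
#' @param strengths numeric vector of network strengths.
#' @param outcomes numeric vector of observed scores.
#' @return A `strength_model` with `intercept` and `slope`.
#' @examples
#' m <- fit_strength_model(c(0, 1, 2), c(10, 12, 14))
#' predict(m, 3)  # 16
#' @export
fit_strength_model <- function(strengths, outcomes) {
  strengths <- as.numeric(strengths); outcomes <- as.numeric(outcomes)
  n <- length(strengths)
  if (length(outcomes) != n) stopf("strengths and outcomes lengths differ")
  if (n < 3L) stopf("need at least 3 observations, got %d", n)
  if (any(!is.finite(strengths)) || any(!is.finite(outcomes)))
    stopf("non-finite values in strengths or outcomes")
  if (var(strengths) == 0) stopf("strengths are constant; cannot fit a line")
  fit <- lm.fit(cbind(1, strengths), outcomes)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]), n = n),
            class = "strength_model")
}

#' @rdname fit_strength_model
#' @param object a `strength_model`.
#' @param newdata numeric vector of strengths to predict from.
#' @param ... unused.
#' @export
predict.strength_model <- function(object, newdata, ...) {
  if (any(!is.finite(newdata))) stopf("non-finite strengths")
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
print.strength_model <- function(x, ...) {
  cat(sprintf("Strength model: score = %.4g + %.4g * strength (n = %d)\n",
              x$intercept, x$slope, x$n))
  invisible(x)
}
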