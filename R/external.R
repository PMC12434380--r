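#' Apply a fixed network mask to a cohort
#'
#' Computes per-participant network strengths (sum of absolute Fisher-z
#' values) over the edges of a previously derived mask, e.g. to carry a
#' discovery cohort's network into an independent validation cohort.
#'
#' @param mask a `network_mask` (see [consensus_network()] or
#'   [read_network_mask()]).
#' @param cohort an `aligned_cohort` whose parcellation contains every
#'   region the mask references.
#' @return Named numeric vector of strengths, one per participant.
#' @export
apply_network <- function(mask, cohort) {
  check_aligned(cohort)
  if (!nrow(mask)) return(setNames(rep(0, cohort_n(cohort)),
                                   cohort$phenotypes$participant_id))
  if (max(mask$region_j) > cohort$n_regions)
    stopf("mask references region %d but the cohort has %d regions",
          max(mask$region_j), cohort$n_regions)
  em <- edge_index_map(cohort$n_regions)
  idx <- match(paste(mask$region_i, mask$region_j), paste(em$i, em$j))
  if (anyNA(idx))
    stopf("mask contains region pairs not in the edge map (is i < j?)")
  network_strength(cohort$edges, idx)
}

#' Evaluate a network's predictive association in an external cohort
#'
#' Scores how well fixed network strengths predict the follow-up severity
#' score in an independent cohort: the plain Spearman correlation, the
#' partial Spearman correlation adjusted for the four covariates (baseline
#' score, sex, age, mean FD), and MAE/RMSE of the predicted scores. The
#' predicted scores come from the supplied strength-to-outcome calibration
#' model, or from a line refit on the external cohort itself when none is
#' supplied; which one was used is recorded in the result.
#'
#' @param strengths per-participant network strengths (see
#'   [apply_network()]).
#' @param cohort the external `aligned_cohort`.
#' @param calibration optional `strength_model` from the discovery cohort.
#' @return An `extension_result` list: `rho_plain`, `p_plain`,
#'   `rho_partial`, `p_partial`, `mae`, `rmse`, `n`, `calibration_source`.
#' @export
evaluate_extension <- function(strengths, cohort, calibration = NULL) {
  check_aligned(cohort)
  n <- cohort_n(cohort)
  if (length(strengths) != n)
    stopf("got %d strengths for %d participants", length(strengths), n)
  if (n <= 6L) stopf("external evaluation needs more than 6 participants")
  y <- cohort$phenotypes$score_y1
  plain <- partial_spearman(strengths, y)
  part <- partial_spearman(strengths, y, cohort$covariates)
  if (is.null(calibration)) {
    calibration <- fit_strength_model(strengths, y)
    source <- "refit on the external cohort"
  } else {
    if (!inherits(calibration, "strength_model"))
      stopf("calibration must be a strength_model")
    source <- "supplied discovery-cohort model"
  }
  pred <- predict(calibration, strengths)
  err <- y - pred
  out <- list(rho_plain = plain$rho, p_plain = plain$p,
              rho_partial = part$rho, p_partial = part$p,
              mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
              n = n, calibration_source = source)
  class(out) <- "extension_result"
  out
}

#' @export
print.extension_result <- function(x, ...) {
  cat(sprintf("External validation (n = %d)\n", x$n))
  cat(sprintf("  Spearman rho = %.3f (p = %.4g)\n", x$rho_plain, x$p_plain))
  cat(sprintf("  partial Spearman rho = %.3f (p = %.4g)\n",
              x$rho_partial, x$p_partial))
  cat(sprintf("  MAE = %.3f, RMSE = %.3f  [calibration: %s]\n",
              x$mae, x$rmse, x$calibration_source))
  invisible(x)
}

#' Specificity scan across alternative outcomes
#'
#' Correlates the network strengths with each candidate outcome (partial
#' Spearman, adjusted for the supplied covariates) and ranks outcomes by
#' absolute correlation. The ranking is descriptive: no multiplicity
#' correction is applied.
#'
#' @param strengths per-participant network strengths.
#' @param outcomes data frame of numeric outcome columns (>= 2).
#' @param covariates optional covariate matrix passed to
#'   [partial_spearman()].
#' @return Data frame with one row per outcome (`outcome`, `rho_partial`,
#'   `p`, `flag`), sorted by `abs(rho_partial)` descending. Constant
#'   outcomes are flagged, not fatal.
#' @export
specificity_scan <- function(strengths, outcomes, covariates = NULL) {
  outcomes <- as.data.frame(outcomes)
  if (ncol(outcomes) < 2L) stopf("need at least 2 outcome columns")
  rows <- lapply(names(outcomes), function(nm) {
    o <- outcomes[[nm]]
    if (!is.numeric(o) || length(unique(o[is.finite(o)])) < 2L)
      return(data.frame(outcome = nm, rho_partial = NA_real_, p = NA_real_,
                        flag = "constant or non-numeric",
                        stringsAsFactors = FALSE))
    ps <- partial_spearman(strengths, o, covariates)
    data.frame(outcome = nm, rho_partial = ps$rho, p = ps$p, flag = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$rho_partial), na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
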