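PHENO_REQUIRED <- c("participant_id", "site_id", "family_id", "sex", "age",
                    "mean_fd", "score_base", "score_y1")

#' Validate a phenotype table
#'
#' Checks the columns the pipeline needs (participant, site and family ids,
#' sex, age, mean framewise displacement, baseline and 1-year-follow-up
#' severity scores), drops records with missing required fields, and records
#' the drop count in the `"drop_log"` attribute.
#'
#' @param x data frame of phenotype records.
#' @return A `phenotype_table` data frame. The optional `group` column
#'   (`control`/`clinical`/`none`) is preserved when present.
#' @export
phenotype_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  miss <- setdiff(PHENO_REQUIRED, names(x))
  if (length(miss))
    stopf("phenotype table is missing required column(s): %s",
          paste(miss, collapse = ", "))
  complete <- stats::complete.cases(x[PHENO_REQUIRED])
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(sprintf("Dropping %d phenotype record(s) with missing required fields",
                    dropped))
    x <- x[complete, , drop = FALSE]
  }
  if (!nrow(x)) stopf("no complete phenotype records")
  x$participant_id <- as.character(x$participant_id)
  if (anyDuplicated(x$participant_id))
    stopf("duplicate participant_id: %s",
          paste(unique(x$participant_id[duplicated(x$participant_id)]),
                collapse = ", "))
  if (!all(x$sex %in% c("F", "M")))
    stopf("sex must be 'F' or 'M'")
  if (any(x$mean_fd < 0)) stopf("mean_fd must be >= 0")
  if (any(x$age <= 0)) stopf("age must be positive")
  rownames(x) <- NULL
  attr(x, "drop_log") <- list(n_dropped = dropped)
  class(x) <- c("phenotype_table", "data.frame")
  x
}

#' Read a phenotype CSV
#'
#' @param path CSV with columns `participant_id`, `site_id`, `family_id`,
#'   `sex` (F/M), `age` (years), `mean_fd` (mm), `score_base`, `score_y1`,
#'   and optionally `group`.
#' @return A validated [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(participant_id = "character")))
}

# Covariate matrix in the fixed order used everywhere:
# baseline score, sex (F = 1, M = 0), age, mean head motion.
covariate_matrix <- function(pheno) {
  cbind(score_base = pheno$score_base,
        sex = as.numeric(pheno$sex == "F"),
        age = pheno$age,
        mean_fd = pheno$mean_fd)
}

#' Align a cohort edge matrix with phenotype records
#'
#' Restricts both sides to the intersection of participant ids, in identical
#' order, and bundles them with the covariate matrix used for adjustment
#' (baseline score, sex coded F=1/M=0, age, mean FD — in that fixed order).
#'
#' @param edges a `cohort_edge_matrix` (participants x edges, row names are
#'   participant ids).
#' @param phenotypes a [phenotype_table()] or data frame coercible to one.
#' @param mean_fd_max optional motion filter: participants with
#'   `mean_fd >= mean_fd_max` are excluded before alignment.
#' @return An `aligned_cohort`: list with `edges`, `phenotypes`, `covariates`,
#'   `n_regions`, and alignment counts in `align_log`.
#' @export
align_cohort <- function(edges, phenotypes, mean_fd_max = NULL) {
  if (!inherits(phenotypes, "phenotype_table"))
    phenotypes <- phenotype_table(phenotypes)
  if (is.null(rownames(edges)))
    stopf("edge matrix must carry participant ids as row names")
  if (!is.null(mean_fd_max))
    phenotypes <- phenotypes[phenotypes$mean_fd < mean_fd_max, , drop = FALSE]
  ids <- intersect(rownames(edges), phenotypes$participant_id)
  if (!length(ids)) stopf("no participant ids shared between edges and phenotypes")
  log <- list(n_aligned = length(ids),
              edges_dropped = nrow(edges) - length(ids),
              phenotypes_dropped = nrow(phenotypes) - length(ids))
  ph <- phenotypes[match(ids, phenotypes$participant_id), , drop = FALSE]
  rownames(ph) <- NULL
  ed <- edges[ids, , drop = FALSE]
  nr <- attr(edges, "n_regions")
  if (is.null(nr)) {
    # infer N from E = N(N-1)/2
    nr <- as.integer(round((1 + sqrt(1 + 8 * ncol(ed))) / 2))
    if (n_edges(nr) != ncol(ed))
      stopf("cannot infer region count from %d edge columns", ncol(ed))
  }
  structure(list(edges = ed, phenotypes = ph,
                 covariates = covariate_matrix(ph),
                 n_regions = nr, align_log = log),
            class = "aligned_cohort")
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat(sprintf(paste0("Aligned cohort: %d participants, %d regions (%d edges), ",
                     "%d site(s)\n"),
              nrow(x$edges), x$n_regions, ncol(x$edges),
              length(unique(x$phenotypes$site_id))))
  invisible(x)
}

cohort_n <- function(cohort) nrow(cohort$edges)

check_aligned <- function(cohort) {
  if (!inherits(cohort, "aligned_cohort"))
    stopf("expected an 'aligned_cohort' (see align_cohort or simulate_cohort)")
  if (!identical(rownames(cohort$edges), cohort$phenotypes$participant_id))
    stopf("cohort rows are out of alignment")
  invisible(cohort)
}
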