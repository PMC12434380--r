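#' Build a synthetic parcellation table
#'
#' Creates a region bookkeeping table in the format the pipeline expects:
#' region labels, hemisphere, anatomical lobe (used only for grouping in
#' summaries), canonical-network assignment, and a cortical/subcortical flag.
#' The default mirrors the 352-region space used throughout the package
#' (333 cortical regions assigned round-robin to the seven canonical cortical
#' networks, plus 19 subcortical regions). The assignment is deterministic
#' and synthetic: it preserves the combinatorial structure (network sizes,
#' cortical/subcortical split) without reproducing any published atlas.
#'
#' @param n_regions total number of regions (default 352).
#' @param n_subcortical number of subcortical regions (default 19 when
#'   `n_regions >= 40`, otherwise `max(2, round(n_regions/18))`).
#' @return A `parcellation` data frame with columns `region_id` (1-based),
#'   `label`, `hemisphere`, `lobe`, `canonical_network`, `is_cortical`.
#' @examples
#' p <- make_parcellation(40)
#' table(p$canonical_network)
#' @export
make_parcellation <- function(n_regions = 352L, n_subcortical = NULL) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 4L) stopf("n_regions must be >= 4, got %d", n_regions)
  if (is.null(n_subcortical)) {
    n_subcortical <- if (n_regions >= 40L) 19L else max(2L, round(n_regions / 18))
  }
  n_subcortical <- as.integer(n_subcortical)
  if (n_subcortical >= n_regions)
    stopf("n_subcortical (%d) must be smaller than n_regions (%d)",
          n_subcortical, n_regions)
  n_cortical <- n_regions - n_subcortical

  cortical_networks <- c("DMN", "FPN", "DAN", "VAN", "SMN", "limbic", "visual")
  lobes <- c("frontal", "parietal", "temporal", "occipital", "insular")

  network <- c(rep_len(cortical_networks, n_cortical),
               rep("subcortical", n_subcortical))
  is_cortical <- c(rep(TRUE, n_cortical), rep(FALSE, n_subcortical))
  hemi <- rep_len(c("L", "R"), n_regions)
  lobe <- c(rep_len(lobes, n_cortical), rep("subcortical", n_subcortical))
  label <- sprintf("%s_%s_%03d",
                   ifelse(is_cortical, "ctx", "sub"), hemi, seq_len(n_regions))

  out <- data.frame(region_id = seq_len(n_regions), label = label,
                    hemisphere = hemi, lobe = lobe,
                    canonical_network = network, is_cortical = is_cortical,
                    stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  validate_parcellation(out)
}

validate_parcellation <- function(x) {
  req <- c("region_id", "label", "hemisphere", "lobe", "canonical_network",
           "is_cortical")
  miss <- setdiff(req, names(x))
  if (length(miss)) stopf("parcellation is missing column(s): %s",
                          paste(miss, collapse = ", "))
  n <- nrow(x)
  if (!identical(as.integer(x$region_id), seq_len(n)))
    stopf("region_id must be 1..%d with no gaps", n)
  if (anyNA(x)) stopf("parcellation contains missing values")
  if (!all(x$hemisphere %in% c("L", "R", "none")))
    stopf("hemisphere must be one of L, R, none")
  x$is_cortical <- as.logical(x$is_cortical)
  if (!inherits(x, "parcellation")) class(x) <- c("parcellation", "data.frame")
  x
}

#' Read or write a parcellation TSV
#'
#' The file stores 1-based `region_id` values; the column layout matches
#' [make_parcellation()].
#'
#' @param path file path.
#' @return `read_parcellation` returns a validated `parcellation` data frame.
#' @export
read_parcellation <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_parcellation(x)
}

#' @rdname read_parcellation
#' @param parcellation a `parcellation` data frame.
#' @export
write_parcellation <- function(parcellation, path) {
  validate_parcellation(parcellation)
  write.table(parcellation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
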