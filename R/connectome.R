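#' Edge index map for the upper triangle of a connectome
#'
#' Enumerates the \eqn{E = N(N-1)/2} unordered region pairs of an
#' \eqn{N \times N} symmetric connectome in row-major upper-triangle order:
#' (1,2), (1,3), ..., (1,N), (2,3), ... Region indices are 1-based, matching
#' every file the package reads or writes.
#'
#' @param n_regions number of regions \eqn{N \ge 2}.
#' @return A data frame with columns `edge` (1..E), `i`, `j` (`i < j`).
#' @examples
#' edge_index_map(3)
#' nrow(edge_index_map(352))  # 61776
#' @export
edge_index_map <- function(n_regions) {
  n <- as.integer(n_regions)
  if (n < 2L) stopf("n_regions must be >= 2, got %d", n)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Number of unique edges for an N-region parcellation
#' @param n_regions number of regions.
#' @return `n_regions * (n_regions - 1) / 2`.
#' @export
n_edges <- function(n_regions) {
  n <- as.integer(n_regions)
  if (n < 2L) stopf("n_regions must be >= 2, got %d", n)
  as.integer(n * (n - 1L) / 2)
}

# Fisher r-to-z with the correlation clipped away from +/-1 so that
# perfectly (anti)correlated series still yield finite z.
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Read one participant's parcellated time series
#'
#' Delimited text, regions in rows and timepoints in columns, with an
#' optional header row. Whitespace-, comma-, or tab-delimited files are
#' handled by the default `sep = ""` / explicit `sep` respectively.
#'
#' @param path file path.
#' @param header does the file start with a header row? (default FALSE).
#' @param sep field separator, as in [utils::read.table()].
#' @return Numeric matrix, regions x timepoints.
#' @export
read_time_series <- function(path, header = FALSE, sep = "") {
  x <- as.matrix(utils::read.table(path, header = header, sep = sep))
  if (!is.numeric(x)) stopf("time series file %s is not numeric", path)
  dimnames(x) <- NULL
  x
}

#' Build a Fisher-z functional connectome from parcellated time series
#'
#' Computes the Pearson correlation between the time series of every pair of
#' regions and applies the Fisher r-to-z transform. Correlations are clipped
#' to \eqn{\pm(1 - 10^{-7})} before `atanh` so that identical or
#' anti-identical series produce large but finite edge values; downstream
#' network-strength sums therefore stay finite.
#'
#' @param ts numeric matrix, regions in rows, timepoints in columns.
#' @param participant_id optional participant identifier stored on the result.
#' @return A `connectome` object: list with `z` (N x N symmetric matrix,
#'   zero diagonal) and `participant_id`.
#' @examples
#' ts <- matrix(rnorm(4 * 50), nrow = 4)
#' conn <- build_connectome(ts, "sub-01")
#' conn$z[1, 2] == atanh(cor(ts[1, ], ts[2, ]))
#' @export
build_connectome <- function(ts, participant_id = NA_character_) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stopf("time series must be numeric")
  if (any(!is.finite(ts))) stopf("time series contains non-finite values")
  if (ncol(ts) < 3L) stopf("need at least 3 timepoints, got %d", ncol(ts))
  v <- apply(ts, 1L, var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stopf("region(s) with zero variance: %s", paste(bad, collapse = ", "))
  }
  z <- fisher_z(cor(t(ts)))
  diag(z) <- 0
  structure(list(z = z, participant_id = participant_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Fisher-z connectome: %d regions, participant %s\n",
              nrow(x$z), x$participant_id))
  invisible(x)
}

#' Convert between symmetric connectome matrices and edge vectors
#'
#' `vectorize_connectome` extracts the upper triangle of a symmetric
#' connectome in the package's canonical edge order ([edge_index_map()]);
#' `devectorize_connectome` reverses the operation, producing a symmetric
#' matrix with zero diagonal. The two are exact inverses on the off-diagonal.
#'
#' @param conn a `connectome` object or a symmetric numeric matrix.
#' @param edge_map optional edge map; defaults to `edge_index_map(N)`.
#' @return A numeric vector of length \eqn{N(N-1)/2}.
#' @export
vectorize_connectome <- function(conn, edge_map = NULL) {
  z <- if (inherits(conn, "connectome")) conn$z else as.matrix(conn)
  n <- nrow(z)
  if (ncol(z) != n) stopf("connectome matrix must be square")
  if (is.null(edge_map)) edge_map <- edge_index_map(n)
  if (max(edge_map$j) > n)
    stopf("edge map expects %d regions but connectome has %d",
          max(edge_map$j), n)
  if (n_edges(n) != nrow(edge_map))
    stopf("edge map length %d does not match %d regions",
          nrow(edge_map), n)
  z[cbind(edge_map$i, edge_map$j)]
}

#' @rdname vectorize_connectome
#' @param edges numeric edge vector of length \eqn{N(N-1)/2}.
#' @param n_regions number of regions N.
#' @export
devectorize_connectome <- function(edges, n_regions) {
  n <- as.integer(n_regions)
  if (length(edges) != n_edges(n))
    stopf("edge vector length %d does not match N=%d (expected %d)",
          length(edges), n, n_edges(n))
  em <- edge_index_map(n)
  z <- matrix(0, n, n)
  z[cbind(em$i, em$j)] <- edges
  z[cbind(em$j, em$i)] <- edges
  z
}

#' Assemble a cohort edge matrix from per-participant connectomes
#'
#' Stacks vectorized connectomes into the participants-by-edges matrix used
#' as the CPM predictor space.
#'
#' @param connectomes list of `connectome` objects (or symmetric matrices).
#' @param participant_ids character vector of ids; defaults to the ids stored
#'   on the connectomes.
#' @return A `cohort_edge_matrix`: numeric matrix with participant ids as row
#'   names and attribute `n_regions`.
#' @export
cohort_edge_matrix <- function(connectomes, participant_ids = NULL) {
  if (!length(connectomes)) stopf("no connectomes supplied")
  if (is.null(participant_ids))
    participant_ids <- vapply(connectomes, function(c)
      as.character(c$participant_id), character(1))
  if (anyDuplicated(participant_ids))
    stopf("duplicate participant ids in connectome list")
  rows <- lapply(connectomes, vectorize_connectome)
  n <- nrow(if (inherits(connectomes[[1]], "connectome"))
    connectomes[[1]]$z else connectomes[[1]])
  x <- do.call(rbind, rows)
  rownames(x) <- participant_ids
  as_edge_matrix(x, n)
}

as_edge_matrix <- function(x, n_regions) {
  x <- as.matrix(x)
  if (ncol(x) != n_edges(n_regions))
    stopf("matrix has %d columns; expected %d for N=%d",
          ncol(x), n_edges(n_regions), n_regions)
  if (is.null(rownames(x))) stopf("edge matrix must have participant row names")
  attr(x, "n_regions") <- as.integer(n_regions)
  class(x) <- c("cohort_edge_matrix", class(matrix()))
  x
}

#' Write or read a cohort edge matrix
#'
#' The matrix is stored as a columnar file with a JSON sidecar
#' (`<path>.json`) recording the region count, edge count, participant order,
#' and the edge-order convention. The `"feather"` format (Apache Arrow)
#' is used when the arrow package is available and `format = "auto"`; the
#' `"csv"` fallback is plain text and suitable for small region counts.
#'
#' @param x a `cohort_edge_matrix`.
#' @param path output path (sidecar written next to it).
#' @param format `"auto"`, `"feather"`, or `"csv"`.
#' @return `read_edge_matrix` returns a `cohort_edge_matrix`.
#' @export
write_edge_matrix <- function(x, path, format = c("auto", "feather", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (requireNamespace("arrow", quietly = TRUE)) "feather" else "csv"
  n <- attr(x, "n_regions")
  meta <- list(n_regions = n, n_edges = ncol(x),
               participant_ids = rownames(x), format = format,
               edge_order = "row-major upper triangle, i < j, 1-based region ids")
  if (format == "feather") {
    df <- as.data.frame(unclass(x))
    names(df) <- sprintf("e%d", seq_len(ncol(x)))
    arrow::write_feather(df, path)
  } else {
    write.table(format(unclass(x), digits = 17, trim = TRUE, scientific = NA),
                path, sep = ",", quote = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_edge_matrix
#' @export
read_edge_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$format, "feather")) {
    df <- arrow::read_feather(path)
    x <- as.matrix(df)
  } else {
    raw <- read.csv(path, header = FALSE, row.names = 1)
    x <- as.matrix(raw)
  }
  dimnames(x) <- list(meta$participant_ids, NULL)
  as_edge_matrix(x, meta$n_regions)
}
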