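# Canonical-network label per region for the edges of a mask, with the
# unordered pair collapsed into a stable "A-B" key (alphabetical order).
pair_key <- function(a, b) {
  swap <- a > b
  key <- paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "-")
  key
}

#' Canonical network-pair counts for a network mask
#'
#' Counts the mask's edges within and between every pair of canonical
#' networks and normalizes each count by the pair's share of all possible
#' edges: `normalized = (observed / |mask|) / (possible / E)`. Values above
#' 1 mark pairs holding more of the selected edges than their size alone
#' would predict ("overrepresented"). The raw `observed / possible` ratio
#' is also reported.
#'
#' @param mask a `network_mask`.
#' @param parcellation a `parcellation` covering every region in the mask;
#'   each mask region must carry a canonical-network assignment.
#' @return A `pair_count_table` data frame with one row per unordered
#'   network pair: `network_a`, `network_b`, `observed`, `possible`,
#'   `normalized`, `raw_ratio`, `overrepresented`. Rows cover all pairs so
#'   that `sum(observed) == nrow(mask)` and `sum(possible) ==` E.
#' @export
pair_counts <- function(mask, parcellation) {
  parcellation <- validate_parcellation(parcellation)
  nets <- parcellation$canonical_network
  n <- nrow(parcellation)
  if (nrow(mask)) {
    if (max(mask$region_j) > n)
      stopf("mask references region %d beyond the parcellation (%d regions)",
            max(mask$region_j), n)
    mask_nets <- cbind(nets[mask$region_i], nets[mask$region_j])
    bad <- unique(c(mask$region_i, mask$region_j)[
      c(mask_nets[, 1], mask_nets[, 2]) %in% c("none", NA)])
    if (length(bad))
      stopf("region(s) without canonical-network assignment: %s",
            paste(sort(bad), collapse = ", "))
  }
  levels <- sort(unique(nets))
  sizes <- table(factor(nets, levels = levels))
  grid <- expand.grid(a = levels, b = levels, stringsAsFactors = FALSE)
  grid <- grid[grid$a <= grid$b, , drop = FALSE]
  possible <- ifelse(grid$a == grid$b,
                     sizes[grid$a] * (sizes[grid$a] - 1) / 2,
                     sizes[grid$a] * sizes[grid$b])
  E <- n_edges(n)
  observed <- if (nrow(mask)) {
    keys <- pair_key(nets[mask$region_i], nets[mask$region_j])
    tab <- table(keys)
    as.numeric(tab[match(pair_key(grid$a, grid$b), names(tab))])
  } else rep(NA_real_, nrow(grid))
  observed[is.na(observed)] <- 0
  m <- max(nrow(mask), 1L)
  normalized <- (observed / m) / (possible / E)
  out <- data.frame(network_a = grid$a, network_b = grid$b,
                    observed = observed, possible = as.numeric(possible),
                    normalized = normalized,
                    raw_ratio = observed / possible,
                    overrepresented = normalized > 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pair_count_table", "data.frame")
  out
}

#' Region degree within a network mask
#'
#' Number of mask edges incident to each region. The sum of all degrees is
#' twice the mask size (every edge touches two regions).
#'
#' @inheritParams pair_counts
#' @param display_threshold recorded as metadata only (e.g. a rendering
#'   cutoff); all regions are always reported.
#' @return Data frame `region_id`, `label`, `canonical_network`, `degree`,
#'   with attribute `display_threshold`.
#' @export
region_degree <- function(mask, parcellation, display_threshold = 8L) {
  parcellation <- validate_parcellation(parcellation)
  n <- nrow(parcellation)
  deg <- tabulate(c(mask$region_i, mask$region_j), nbins = n)
  out <- data.frame(region_id = parcellation$region_id,
                    label = parcellation$label,
                    canonical_network = parcellation$canonical_network,
                    degree = deg, stringsAsFactors = FALSE)
  attr(out, "display_threshold") <- display_threshold
  out
}

#' Per-participant functional-connectivity profiles of a network mask
#'
#' Splits the mask's edges by canonical network pair and by the sign of
#' each edge's association with the outcome, then averages each
#' participant's Fisher-z values within every (pair, sign) cell. Cells with
#' no edges are absent from the result rather than reported as zero.
#'
#' @param cohort an `aligned_cohort`.
#' @param mask a `network_mask` carrying a `sign` column.
#' @param parcellation a `parcellation` for the cohort's regions.
#' @return Long data frame: `participant_id`, `network_pair`, `sign`,
#'   `mean_z`, `n_edges`.
#' @export
fc_profiles <- function(cohort, mask, parcellation) {
  check_aligned(cohort)
  parcellation <- validate_parcellation(parcellation)
  if (!nrow(mask)) return(data.frame(participant_id = character(0),
                                     network_pair = character(0),
                                     sign = character(0), mean_z = numeric(0),
                                     n_edges = integer(0)))
  if (is.null(mask$sign)) stopf("mask has no per-edge association signs")
  nets <- parcellation$canonical_network
  em <- edge_index_map(cohort$n_regions)
  idx <- match(paste(mask$region_i, mask$region_j), paste(em$i, em$j))
  if (anyNA(idx)) stopf("mask contains region pairs outside the edge map")
  cell <- paste(pair_key(nets[mask$region_i], nets[mask$region_j]), mask$sign,
                sep = "|")
  cells <- unique(cell)
  ids <- cohort$phenotypes$participant_id
  blocks <- lapply(cells, function(cl) {
    cols <- idx[cell == cl]
    parts <- strsplit(cl, "|", fixed = TRUE)[[1]]
    data.frame(participant_id = ids, network_pair = parts[1], sign = parts[2],
               mean_z = rowMeans(cohort$edges[, cols, drop = FALSE]),
               n_edges = length(cols), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
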