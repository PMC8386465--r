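# Pairwise distances between aligned sequences under explicit gap policies,
# and the sparse neighbor set consumed by clustering.

GAP_MODES <- c("gap-run-single-difference" = 2L,
               "each-gap-a-difference" = 1L,
               "ignore-gap-columns" = 3L)

#' Gap-handling policy for pairwise distances
#'
#' Three modes: `"gap-run-single-difference"` (a maximal run of gaps in one
#' sequence counts as a single difference and a single compared unit — the
#' default, matching the common distance calculator's default behaviour),
#' `"each-gap-a-difference"` (every gap-vs-base column is one difference),
#' and `"ignore-gap-columns"` (only columns where both sequences carry a
#' base are compared).  Columns where both sequences have gaps are never
#' counted.  With `count_terminal_gaps = FALSE`, leading/trailing columns
#' where either sequence has a gap overhang are excluded before counting.
#'
#' @param mode one of the three mode names.
#' @param count_terminal_gaps logical, default `TRUE`.
#' @return an `rrn_gap_policy` object.
#' @export
gap_policy <- function(mode = c("gap-run-single-difference",
                                "each-gap-a-difference",
                                "ignore-gap-columns"),
                       count_terminal_gaps = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, mode_code = unname(GAP_MODES[mode]),
                 count_terminal_gaps = isTRUE(count_terminal_gaps)),
            class = "rrn_gap_policy")
}

#' Distance between two aligned sequences
#'
#' Differences divided by compared units under the gap policy; a pair with
#' no comparable columns is maximally distant (1.0).
#'
#' @param a,b aligned sequences of equal length.
#' @param policy an [gap_policy()] object.
#' @return distance in \[0, 1\].
#' @export
pairwise_distance <- function(a, b, policy = gap_policy()) {
  dist_pair_cpp(a, b, policy$mode_code, policy$count_terminal_gaps)
}

new_neighbor_set <- function(pairs, n_items, d_max) {
  structure(list(pairs = pairs, n_items = as.integer(n_items),
                 d_max = d_max), class = "rrn_neighbor_set")
}

#' Sparse neighbor set of aligned sequences
#'
#' All unordered pairs (i < j) with distance at or below `d_max`
#' (inclusive), in deterministic (i, j) order.
#'
#' @param seqs character vector of aligned ASV representatives.
#' @param d_max maximum distance to retain (default 0.10, the top of the
#'   threshold sweep).
#' @param policy an [gap_policy()] object.
#' @return an `rrn_neighbor_set`: list with `pairs` tibble (`i`, `j`,
#'   `distance`), `n_items`, `d_max`.
#' @export
neighbor_pairs <- function(seqs, d_max = 0.10, policy = gap_policy()) {
  res <- neighbor_pairs_cpp(seqs, d_max, policy$mode_code,
                            policy$count_terminal_gaps)
  pairs <- tibble::tibble(i = res$i, j = res$j, distance = res$distance) |>
    dplyr::arrange(.data$i, .data$j)
  new_neighbor_set(pairs, length(seqs), d_max)
}

#' Neighbor set from an explicit pair list
#'
#' Constructor used by tests and by callers that already hold distances.
#'
#' @param pairs data frame with columns `i`, `j`, `distance` (i < j).
#' @param n_items total number of items.
#' @param d_max the sparsity cutoff the pairs satisfy.
#' @return an `rrn_neighbor_set`.
#' @export
neighbor_set <- function(pairs, n_items, d_max) {
  pairs <- tibble::as_tibble(pairs[, c("i", "j", "distance")])
  stopifnot(all(pairs$i < pairs$j), all(pairs$distance <= d_max + 1e-12),
            all(pairs$j <= n_items),
            !anyDuplicated(paste(pairs$i, pairs$j)))
  new_neighbor_set(dplyr::arrange(pairs, .data$i, .data$j), n_items, d_max)
}

#' @export
print.rrn_neighbor_set <- function(x, ...) {
  cat("<rrn_neighbor_set> ", x$n_items, " items, ", nrow(x$pairs),
      " pairs <= ", x$d_max, "\n", sep = "")
  invisible(x)
}

#' Dense distance matrix
#'
#' Full all-vs-all matrix; intended for small inputs and for the
#' furthest-neighbor oracle.
#'
#' @inheritParams neighbor_pairs
#' @return numeric n x n matrix.
#' @export
dist_matrix <- function(seqs, policy = gap_policy()) {
  dist_matrix_cpp(seqs, policy$mode_code, policy$count_terminal_gaps)
}

#' Write a sparse neighbor set as 3-column TSV
#' @param nbrs an `rrn_neighbor_set`.
#' @param path output path.
#' @export
write_neighbor_tsv <- function(nbrs, path) {
  readr::write_tsv(nbrs$pairs, path, progress = FALSE)
  invisible(path)
}
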