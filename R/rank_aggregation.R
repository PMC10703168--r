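#' Normalized rank matrix from ranked lists
#'
#' Turns per-iteration ranked lists (rank 1 = best) into a matrix of
#' normalized ranks in \eqn{(0, 1]}: the item at position j of a list over a
#' universe of U items has normalized rank j/U, and items absent from a list
#' (e.g. outside that iteration's top-k) take the worst value 1. This is the
#' partial-list convention of the robust rank aggregation (RRA) method.
#'
#' @param lists List of character vectors, each a ranked list with unique
#'   items.
#' @param universe Optional character vector of all eligible items (e.g. the
#'   full group set at the rank). Defaults to the union of the lists.
#' @return Numeric matrix, one row per universe item, one column per list.
#' @export
build_rank_matrix <- function(lists, universe = NULL) {
  stopifnot(is.list(lists), length(lists) >= 1L)
  for (i in seq_along(lists)) {
    if (anyDuplicated(lists[[i]]))
      stop("duplicate item in list ", i, ": ",
           paste(unique(lists[[i]][duplicated(lists[[i]])]), collapse = ", "))
  }
  if (is.null(universe)) universe <- unique(unlist(lists))
  unknown <- setdiff(unique(unlist(lists)), universe)
  if (length(unknown))
    stop("ranked items outside the universe: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  U <- length(universe)
  mat <- matrix(1, nrow = U, ncol = length(lists),
                dimnames = list(universe, NULL))
  for (j in seq_along(lists)) {
    pos <- match(lists[[j]], universe)
    mat[pos, j] <- seq_along(pos) / U
  }
  mat
}

#' Order-statistic beta scores of a sorted rank vector
#'
#' For N normalized ranks sorted ascending, the k-th beta score is the
#' probability that the k-th order statistic of N independent Uniform(0,1)
#' variables is at most r(k) — the upper binomial tail
#' \eqn{P(\mathrm{Bin}(N, r_k) \ge k)}. Small values mean the item sits
#' higher in more lists than uniform chance allows.
#'
#' @param r Numeric vector of normalized ranks, sorted ascending, each in
#'   \eqn{(0, 1]}.
#' @return Numeric vector of beta scores, same length as `r`.
#' @export
beta_scores <- function(r) {
  stopifnot(length(r) >= 1L, all(r > 0), all(r <= 1))
  if (is.unsorted(r)) stop("normalized ranks must be sorted ascending")
  n <- length(r)
  stats::pbinom(seq_len(n) - 1L, n, r, lower.tail = FALSE)
}

#' Aggregate ranked lists into per-item significance values
#'
#' Robust rank aggregation: each item's score rho is the minimum of its beta
#' scores over its sorted normalized ranks, and its p-value is the
#' Bonferroni-corrected `min(1, rho * U)` with U the universe size. Items are
#' returned sorted by p-value ascending, ties broken lexicographically.
#'
#' @inheritParams build_rank_matrix
#' @return Data frame with columns `item`, `rho`, `p_value`,
#'   `n_lists_present` (number of lists that actually ranked the item).
#' @export
aggregate_ranks <- function(lists, universe = NULL) {
  mat <- build_rank_matrix(lists, universe)
  U <- nrow(mat)
  rho <- apply(mat, 1L, function(r) min(beta_scores(sort(r))))
  # count by list membership, not by rank value: an item ranked last in a
  # full list has normalized rank 1 yet is still present
  present <- as.integer(table(factor(unlist(lists), levels = rownames(mat))))
  out <- data.frame(item = rownames(mat), rho = unname(rho),
                    p_value = pmin(1, unname(rho) * U),
                    n_lists_present = present)
  out <- out[order(out$p_value, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propagate group significance to member species
#'
#' Each species inherits the aggregated p-value of its taxon group, as the
#' method reports species-level significance by propagation. Species are
#' ordered by group p-value (ascending), then by within-group input order;
#' groups tied on p are ordered by name.
#'
#' @param aggregated Data frame from [aggregate_ranks()] over group lists.
#' @param group_map A [group_features()] partition containing every
#'   aggregated group.
#' @return Data frame with columns `species`, `group`, `rho`, `p_value`.
#' @export
propagate_to_species <- function(aggregated, group_map) {
  if (nrow(aggregated) == 0L)
    return(data.frame(species = character(0), group = character(0),
                      rho = numeric(0), p_value = numeric(0)))
  missing <- setdiff(aggregated$item, names(group_map))
  if (length(missing))
    stop("aggregated groups missing from group map: ",
         paste(utils::head(missing, 3), collapse = ", "))
  ord <- order(aggregated$p_value, aggregated$item)
  rows <- lapply(ord, function(i) {
    sp <- group_map[[aggregated$item[i]]]
    data.frame(species = sp, group = aggregated$item[i],
               rho = aggregated$rho[i], p_value = aggregated$p_value[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
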