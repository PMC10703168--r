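#' Parse a clade string into a lineage
#'
#' Splits a pipe-joined, rank-prefixed clade string
#' (`k__Bacteria|p__...|s__...`) into its seven named rank slots. Prefixes
#' must appear in strictly descending rank order. Missing intermediate ranks
#' are synthesized as `"<deepest_known_ancestor>_unclassified"`, mirroring the
#' MetaPhlAn convention, so every retained species has a name at every rank
#' above it.
#'
#' @param clade A single clade string.
#' @return A named character vector with entries `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species` (species may be `NA` for
#'   higher-rank rows) plus attribute `depth`, the deepest observed rank name.
#' @export
parse_clade_string <- function(clade) {
  stopifnot(is.character(clade), length(clade) == 1L, nzchar(clade))
  tokens <- strsplit(trimws(clade), "|", fixed = TRUE)[[1L]]
  ranks <- names(.rank_prefixes)
  out <- stats::setNames(rep(NA_character_, 7L), ranks[1:7])
  last_idx <- 0L
  for (tok in tokens) {
    if (!grepl("^[a-z]__", tok))
      stop("malformed rank token ", dQuote(tok), " in ", dQuote(clade))
    idx <- match(substr(tok, 1L, 1L), unname(.rank_prefixes))
    if (is.na(idx))
      stop("unknown rank prefix in token ", dQuote(tok), " in ", dQuote(clade))
    if (idx <= last_idx)
      stop("rank prefixes out of order at token ", dQuote(tok), " in ",
           dQuote(clade))
    last_idx <- idx
    if (idx <= 7L) out[ranks[idx]] <- substr(tok, 4L, nchar(tok))
  }
  if (last_idx == 0L) stop("no rank-prefixed tokens in ", dQuote(clade))
  depth <- ranks[min(last_idx, 8L)]
  # gap-fill: ranks above the deepest observed one inherit the nearest named
  # ancestor with an "_unclassified" suffix
  top <- min(last_idx, 7L)
  known_above <- which(!is.na(out[seq_len(top)]))
  if (length(known_above)) {
    for (j in seq_len(top)) {
      if (is.na(out[j])) {
        anc <- known_above[known_above < j]
        out[j] <- if (length(anc))
          paste0(out[max(anc)], "_unclassified") else "unclassified"
      }
    }
  }
  structure(out, depth = depth)
}

#' Parse lineages for a set of species clade strings
#'
#' @param clades Character vector of species-level clade strings (deepest
#'   prefix `s__`).
#' @return A data frame with one row per species: the seven rank columns plus
#'   `species_id` (the original clade string).
#' @export
parse_lineages <- function(clades) {
  rows <- lapply(clades, parse_clade_string)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  df$species_id <- clades
  df
}

#' Partition species into taxon groups at a rank
#'
#' The grouping (G) component: assigns every species to exactly one group
#' named by its taxon at the chosen rank. Matching is case-insensitive;
#' groups are reported in the input's original casing (first occurrence) and
#' iterated in lexicographic order. Species order within a group follows the
#' input order. The gap-fill in [parse_clade_string()] guarantees every
#' species has a name at every grouping rank, so the groups always form a
#' total partition of the feature space.
#'
#' @param lineages Data frame from [parse_lineages()] (or a sidecar lineage
#'   table with the same columns).
#' @param rank One of `"genus"`, `"family"`, `"order"`.
#' @return An object of class `group_map`: a named list of character vectors
#'   of species ids, with attribute `rank`.
#' @export
group_features <- function(lineages, rank = c("genus", "family", "order")) {
  rank <- match.arg(rank)
  stopifnot(is.data.frame(lineages), all(c(rank, "species_id") %in% names(lineages)))
  taxon <- as.character(lineages[[rank]])
  if (anyNA(taxon)) stop("missing ", rank, " name for some species")
  key <- tolower(taxon)
  display <- taxon[!duplicated(key)]
  names(display) <- key[!duplicated(key)]
  groups <- split(as.character(lineages$species_id), key)
  groups <- groups[order(names(groups))]        # lexicographic by taxon
  names(groups) <- unname(display[names(groups)])
  structure(groups, rank = rank, class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  sizes <- lengths(x)
  cat("<group_map> rank=", attr(x, "rank"), ": ", length(x), " groups, ",
      sum(sizes), " species (sizes ", min(sizes), "-", max(sizes), ")\n",
      sep = "")
  invisible(x)
}

#' Restrict a matrix to one group's species
#'
#' Builds the `sub_d` sub-dataset: the same samples and labels, with the
#' feature space cut down to the species of a single taxon group.
#'
#' @param am An [abundance_matrix()].
#' @param group Character vector of species ids (one `group_map` element).
#' @return An `abundance_matrix` over the group's species only.
#' @export
make_subdataset <- function(am, group) {
  missing <- setdiff(group, species_ids(am))
  if (length(missing))
    stop("group references species absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  structure(list(values = am$values[, group, drop = FALSE],
                 labels = am$labels), class = "abundance_matrix")
}
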