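#' Labeled relative-abundance matrix
#'
#' Container for a samples x species matrix of relative abundances in
#' \eqn{[0, 1]}, with each sample (row) summing to 1, and an optional binary
#' label vector aligned to the samples (1 = disease, 0 = healthy).
#'
#' @param values Numeric matrix, samples in rows, species in columns, with
#'   unique row and column names.
#' @param labels Optional integer vector of 0/1 labels, one per sample, in row
#'   order. When present both classes must occur.
#' @param normalized Logical; if `TRUE` (default) each row must sum to 1
#'   within `1e-6`.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values` and `labels`.
#' @export
abundance_matrix <- function(values, labels = NULL, normalized = TRUE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample (row) and species (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate species ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  finite <- values[!is.na(values)]
  if (any(finite < 0 | finite > 1))
    stop("abundances must lie in [0, 1]; call normalize_abundances() first")
  if (normalized) {
    sums <- rowSums(values)
    bad <- which(!is.na(sums) & abs(sums - 1) > 1e-6)
    if (length(bad))
      stop("sample rows do not sum to 1: ",
           paste(rownames(values)[utils::head(bad, 5)], collapse = ", "))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
      stop("labels length (", length(labels), ") != number of samples (",
           nrow(values), ")")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
    if (length(unique(labels)) < 2L)
      stop("labels must contain both classes")
    names(labels) <- rownames(values)
  }
  structure(list(values = values, labels = labels), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " species\n", sep = "")
  if (!is.null(x$labels))
    cat("  labels: ", sum(x$labels == 1L), " positive / ",
        sum(x$labels == 0L), " negative\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Sample and species identifiers of an abundance matrix
#' @param x An `abundance_matrix`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
species_ids <- function(x) colnames(x$values)

#' Parse a MetaPhlAn-style merged abundance table
#'
#' Reads a TSV whose first column holds pipe-joined, rank-prefixed clade
#' strings (`k__...|p__...|...|s__...`) and whose remaining columns hold one
#' numeric abundance column per sample. Lines starting with `#` are treated as
#' comments. Values are returned exactly as read (percent-scale tables are not
#' rescaled here; see [normalize_abundances()]).
#'
#' Empty cells and the tokens `NA`/`NaN` are read as missing values; samples
#' carrying missing values are later removed by [attach_labels_and_clean()].
#' Any other non-numeric cell is a parse error naming the offending row and
#' column.
#'
#' @param path Path to the TSV file (or a connection).
#' @return A list with elements `clades` (character vector of clade strings),
#'   `samples` (character vector of sample ids), and `values` (numeric matrix,
#'   one row per clade, one column per sample).
#' @export
parse_merged_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no data rows in abundance table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  samples <- header[-1L]
  if (length(samples) == 0L) stop("abundance table has no sample columns")
  if (anyDuplicated(samples))
    stop("duplicate sample columns: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- fields[-1L]
  clades <- trimws(vapply(body, `[`, character(1), 1L))
  if (anyDuplicated(clades))
    stop("duplicate clade string: ",
         paste(unique(clades[duplicated(clades)]), collapse = ", "))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                   dimnames = list(clades, samples))
  for (i in seq_along(body)) {
    row <- trimws(body[[i]][-1L])
    length(row) <- length(samples) # right-pad short rows with NA
    missing <- is.na(row) | row == "" | toupper(row) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(row))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value %s in row %s, column %s",
                   dQuote(row[bad[1L]]), dQuote(clades[i]),
                   dQuote(samples[bad[1L]])))
    num[missing] <- NA_real_
    values[i, ] <- num
  }
  list(clades = clades, samples = samples, values = values)
}

# Rank prefixes in descending taxonomic order; t__ marks strain-level rows.
.rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", species = "s", strain = "t")

# Deepest rank prefix of a clade string ("k".."t"), or NA if unprefixed.
.deepest_prefix <- function(clades) {
  last <- vapply(strsplit(clades, "|", fixed = TRUE),
                 function(x) x[length(x)], character(1))
  ifelse(grepl("^[kpcofgst]__", last), substr(last, 1L, 1L), NA_character_)
}

#' Keep only species-level rows of a parsed merged table
#'
#' Retains rows whose deepest rank prefix is `s__` (species). Higher-rank
#' summary rows and strain-level (`t__`) rows are discarded; input order is
#' preserved.
#'
#' @param parsed A list as returned by [parse_merged_table()].
#' @return A list of the same shape restricted to species rows.
#' @export
select_species_rows <- function(parsed) {
  keep <- .deepest_prefix(parsed$clades) %in% "s"
  if (!any(keep)) stop("no species-level (s__) rows in table")
  list(clades = parsed$clades[keep], samples = parsed$samples,
       values = parsed$values[keep, , drop = FALSE])
}

#' Normalize abundances to per-sample relative fractions
#'
#' Divides each sample's species vector by its own sum (compositional
#' closure), so every sample sums to 1. Closure is scale-invariant: tables in
#' percent and in fractions give identical results, so no dialect guessing is
#' performed.
#'
#' @param x Either a list from [select_species_rows()] / [parse_merged_table()]
#'   (species rows x sample columns) or a numeric samples x species matrix.
#' @return An [abundance_matrix()] (without labels).
#' @export
normalize_abundances <- function(x) {
  if (is.list(x) && !is.null(x$values)) {
    m <- t(x$values)               # -> samples x species
  } else if (is.matrix(x)) {
    m <- x
  } else stop("x must be a parsed table or a samples x species matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry sample and species names")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance for sample ", rownames(m)[neg[1L, 1L]])
  sums <- rowSums(m, na.rm = TRUE)
  zero <- sums <= 0
  if (any(zero))
    stop("samples with all-zero abundances: ",
         paste(rownames(m)[zero], collapse = ", "))
  abundance_matrix(m / sums, normalized = FALSE)
}

#' Drop samples sequenced below a read-count threshold
#'
#' Removes samples whose total read count falls below `min_reads`
#' (default one million reads). Merged abundance tables carry no read counts,
#' so when `read_counts` is `NULL` the filter is a logged no-op.
#'
#' @param am An [abundance_matrix()].
#' @param read_counts Optional data frame with columns `sample_id` and
#'   `total_reads`, or `NULL`.
#' @param min_reads Minimum total reads to retain a sample.
#' @param mode `"strict"` (default) errors when a sample has no read-count
#'   entry; `"lenient"` keeps such samples with a warning.
#' @return The filtered `abundance_matrix`.
#' @export
filter_samples_by_reads <- function(am, read_counts = NULL,
                                    min_reads = 1e6,
                                    mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (is.null(read_counts)) {
    message("no read counts supplied; read-count filter skipped")
    return(am)
  }
  stopifnot(all(c("sample_id", "total_reads") %in% names(read_counts)))
  if (any(read_counts$total_reads < 0)) stop("total_reads must be >= 0")
  ids <- sample_ids(am)
  counts <- read_counts$total_reads[match(ids, trimws(read_counts$sample_id))]
  if (anyNA(counts)) {
    absent <- ids[is.na(counts)]
    if (mode == "strict")
      stop("samples missing from read counts: ", paste(absent, collapse = ", "))
    warning("samples missing from read counts kept: ",
            paste(absent, collapse = ", "))
    counts[is.na(counts)] <- Inf
  }
  keep <- counts >= min_reads
  if (!any(keep)) stop("read-count filter removed every sample")
  if (any(!keep))
    message(sum(!keep), " sample(s) removed with < ", format(min_reads),
            " total reads")
  subset_samples(am, ids[keep])
}

# Row-subset an abundance_matrix, keeping labels aligned.
subset_samples <- function(am, ids) {
  labels <- if (!is.null(am$labels)) unname(am$labels[ids]) else NULL
  out <- structure(list(values = am$values[ids, , drop = FALSE],
                        labels = labels), class = "abundance_matrix")
  if (!is.null(labels)) names(out$labels) <- ids
  out
}

#' Attach class labels and remove incomplete samples
#'
#' Joins a sample-id to label table onto the matrix by exact id match (after
#' whitespace trimming), drops samples with no label and samples carrying any
#' missing abundance value, and checks that both classes survive.
#'
#' @param am An [abundance_matrix()].
#' @param label_table Data frame with columns `sample_id` and `label`. Labels
#'   may already be 0/1, or arbitrary two-level text interpreted through
#'   `positive_label`.
#' @param positive_label The label value mapped to class 1 (disease) when
#'   labels are not already 0/1.
#' @return An `abundance_matrix` with labels attached.
#' @export
attach_labels_and_clean <- function(am, label_table, positive_label = NULL) {
  stopifnot(all(c("sample_id", "label") %in% names(label_table)))
  ids <- sample_ids(am)
  lab_raw <- label_table$label[match(ids, trimws(as.character(label_table$sample_id)))]
  unlabeled <- is.na(lab_raw)
  lab01 <- rep(NA_integer_, length(ids))
  lv <- trimws(as.character(lab_raw[!unlabeled]))
  if (all(lv %in% c("0", "1"))) {
    lab01[!unlabeled] <- as.integer(lv)
  } else {
    if (is.null(positive_label))
      stop("labels are not 0/1; supply positive_label")
    lab01[!unlabeled] <- as.integer(lv == as.character(positive_label))
  }
  incomplete <- rowSums(is.na(am$values)) > 0
  drop <- unlabeled | incomplete
  if (any(drop))
    message(sum(unlabeled), " unlabeled and ", sum(incomplete & !unlabeled),
            " incomplete sample(s) removed")
  keep <- ids[!drop]
  if (length(unique(lab01[!drop])) < 2L)
    stop("after cleaning only one class remains")
  abundance_matrix(am$values[keep, , drop = FALSE], labels = lab01[!drop],
                   normalized = FALSE)
}

#' Read a sample-label table (TSV or CSV)
#'
#' @param path Path to a delimited file with columns `sample_id` and `label`
#'   (header required; delimiter sniffed from the header line).
#' @return A data frame with columns `sample_id` and `label`.
#' @export
read_label_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#", quote = "\"")
  names(df) <- trimws(tolower(names(df)))
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("label table must have columns sample_id and label")
  df[c("sample_id", "label")]
}

#' Read, filter, normalize and label a merged abundance table
#'
#' Convenience wrapper running the full input chain:
#' parse -> species rows -> closure normalization -> optional read-count
#' filter -> label attachment and cleaning.
#'
#' @inheritParams attach_labels_and_clean
#' @inheritParams filter_samples_by_reads
#' @param abundance_path MetaPhlAn-style merged abundance TSV.
#' @param labels_path Label TSV/CSV (see [read_label_table()]).
#' @param read_counts_path Optional TSV with columns `sample_id`,
#'   `total_reads`.
#' @return A labeled [abundance_matrix()].
#' @export
read_abundance_dataset <- function(abundance_path, labels_path,
                                   read_counts_path = NULL,
                                   positive_label = NULL, min_reads = 1e6) {
  am <- normalize_abundances(select_species_rows(parse_merged_table(abundance_path)))
  if (!is.null(read_counts_path)) {
    rc <- utils::read.table(read_counts_path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    am <- filter_samples_by_reads(am, rc, min_reads = min_reads)
  }
  attach_labels_and_clean(am, read_label_table(labels_path),
                          positive_label = positive_label)
}
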