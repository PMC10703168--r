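#' Configuration for group scoring
#'
#' Controls the internal cross-validation used to score each taxon group on
#' training data: a random forest (100 trees, default mtry) evaluated by
#' stratified k-fold cross-validation with seeded shuffling, scored by mean
#' fold accuracy.
#'
#' @param n_folds Number of CV folds (default 5). When the minority class has
#'   fewer samples than `n_folds`, the fold count is reduced to that count
#'   (minimum 2) with a warning.
#' @param n_trees Trees per random forest (default 100).
#' @param shuffle Shuffle samples (within class, seeded) before assigning
#'   folds. Default `TRUE`.
#' @param scheme `"kfold"` (default): stratified k-fold partition after a
#'   seeded shuffle. `"shuffle_split"`: `n_folds` independent stratified
#'   splits each holding out `1/n_folds` of the data.
#' @param seed Integer seed for fold assignment and forest fitting.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(n_folds = 5L, n_trees = 100L, shuffle = TRUE,
                           scheme = c("kfold", "shuffle_split"), seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_folds >= 2L, n_trees >= 1L)
  structure(list(n_folds = as.integer(n_folds), n_trees = as.integer(n_trees),
                 shuffle = isTRUE(shuffle), scheme = scheme,
                 seed = as.integer(seed)),
            class = "scoring_config")
}

# Fit a seeded random forest classifier; returns the fitted forest. A
# sub-dataset with zero variance in every feature (e.g. a group of species
# absent from all training samples) cannot support any split: fall back to a
# majority-vote model instead of handing the degenerate matrix to the forest.
fit_rf <- function(x, y, n_trees, seed) {
  varies <- FALSE
  for (j in seq_len(ncol(x))) {
    if (any(x[, j] != x[1L, j])) { varies <- TRUE; break }
  }
  if (!varies)
    return(structure(list(p1 = mean(y == 1L)), class = "majority_vote_fit"))
  yf <- factor(y, levels = c(0L, 1L))
  with_seed(seed, randomForest::randomForest(x, yf, ntree = n_trees))
}

# Predicted class-1 probability from a fitted classifier.
predict_rf_prob <- function(fit, x) {
  if (inherits(fit, "majority_vote_fit")) return(rep(fit$p1, nrow(x)))
  unname(stats::predict(fit, x, type = "prob")[, "1"])
}

# Stratified fold assignment over canonically sorted samples. Returns an
# integer fold id per sample (in the sorted order handed in).
make_stratified_folds <- function(labels, n_folds, shuffle, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (shuffle) idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Score one taxon group by internal cross-validated accuracy
#'
#' The scoring (S) component for a single group: the group's sub-dataset is
#' classified with a random forest under stratified, seeded-shuffle k-fold
#' cross-validation, and the group's score is the mean of the per-fold
#' accuracies. Samples are canonically sorted by id before fold assignment so
#' the score does not depend on input row order.
#'
#' @param sub_d An [abundance_matrix()] restricted to the group's species
#'   (see [make_subdataset()]), with labels.
#' @param cfg A [scoring_config()].
#' @param trace Optional callback `function(stage, ids)` invoked with the
#'   sample ids entering each fold's fit (`"score_fit"`) and evaluation
#'   (`"score_eval"`), for auditing train/test separation.
#' @return A list of class `group_score`: `group_name` (filled by
#'   [score_all_groups()]), `fold_accuracies`, `score` (their mean), and
#'   `n_features`.
#' @export
score_group <- function(sub_d, cfg = scoring_config(), trace = NULL) {
  if (is.null(sub_d$labels)) stop("sub-dataset has no labels")
  ord <- order(rownames(sub_d$values))
  x <- sub_d$values[ord, , drop = FALSE]
  y <- as.integer(sub_d$labels[ord])
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("cannot stratify a single-class sub-dataset")
  n_folds <- cfg$n_folds
  if (min(counts) < n_folds) {
    n_folds <- max(2L, as.integer(min(counts)))
    warning("minority class smaller than fold count; using ", n_folds,
            " folds", call. = FALSE)
  }
  acc <- numeric(n_folds)
  if (cfg$scheme == "kfold") {
    folds <- make_stratified_folds(y, n_folds, cfg$shuffle, cfg$seed)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      if (!is.null(trace)) {
        trace("score_fit", rownames(x)[!test])
        trace("score_eval", rownames(x)[test])
      }
      fit <- fit_rf(x[!test, , drop = FALSE], y[!test], cfg$n_trees,
                    seed_hash(cfg$seed, "fold", f))
      pred <- predict_rf_prob(fit, x[test, , drop = FALSE]) >= 0.5
      acc[f] <- mean(as.integer(pred) == y[test])
    }
  } else { # shuffle_split: n_folds independent stratified 1/n_folds holdouts
    for (f in seq_len(n_folds)) {
      folds <- make_stratified_folds(y, n_folds, TRUE,
                                     seed_hash(cfg$seed, "split", f))
      test <- folds == 1L
      if (!is.null(trace)) {
        trace("score_fit", rownames(x)[!test])
        trace("score_eval", rownames(x)[test])
      }
      fit <- fit_rf(x[!test, , drop = FALSE], y[!test], cfg$n_trees,
                    seed_hash(cfg$seed, "fold", f))
      pred <- predict_rf_prob(fit, x[test, , drop = FALSE]) >= 0.5
      acc[f] <- mean(as.integer(pred) == y[test])
    }
  }
  structure(list(group_name = NA_character_, fold_accuracies = acc,
                 score = mean(acc), n_features = ncol(x)),
            class = "group_score")
}

#' Score every group of a partition on training data
#'
#' Applies [score_group()] to each group's sub-dataset. Each group receives
#' its own deterministic seed derived from `(cfg$seed, iteration, group
#' name)`, so results are reproducible and independent of the order in which
#' groups are scored.
#'
#' @param train A labeled [abundance_matrix()] (training samples only).
#' @param group_map A [group_features()] partition of the matrix's species.
#' @param cfg A [scoring_config()]; its `seed` acts as the global seed.
#' @param iteration Integer tag mixed into each group's seed (the MCCV
#'   iteration number; 0 for standalone use).
#' @param trace Optional audit callback, passed through to [score_group()].
#' @return A list of `group_score` objects, one per group, in group-map
#'   order.
#' @export
score_all_groups <- function(train, group_map, cfg = scoring_config(),
                             iteration = 0L, trace = NULL) {
  scores <- vector("list", length(group_map))
  names(scores) <- names(group_map)
  for (g in names(group_map)) {
    sub_d <- make_subdataset(train, group_map[[g]])
    gcfg <- cfg
    gcfg$seed <- seed_hash(cfg$seed, iteration, g)
    s <- tryCatch(score_group(sub_d, gcfg, trace = trace),
                  error = function(e) stop("scoring group ", dQuote(g), ": ",
                                           conditionMessage(e), call. = FALSE))
    s$group_name <- g
    scores[[g]] <- s
  }
  scores
}

#' Tabulate group scores
#'
#' @param scores List of `group_score` objects from [score_all_groups()].
#' @return Data frame: `group_name`, `n_features`, `fold_1..fold_n`,
#'   `mean_score`, sorted by score descending (ties lexicographic).
#' @export
group_scores_table <- function(scores) {
  nf <- max(vapply(scores, function(s) length(s$fold_accuracies), integer(1)))
  rows <- lapply(scores, function(s) {
    fa <- s$fold_accuracies
    length(fa) <- nf
    data.frame(group_name = s$group_name, n_features = s$n_features,
               t(stats::setNames(fa, paste0("fold_", seq_len(nf)))),
               mean_score = s$score, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$mean_score, df$group_name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select the top-k groups by score
#'
#' Sorts groups by score descending, breaking ties lexicographically by group
#' name, and returns the first `min(k, number of groups)` names.
#'
#' @param scores List of `group_score` objects, or a named numeric vector of
#'   scores.
#' @param k Number of groups to keep (default 10).
#' @return Character vector of group names, best first.
#' @export
rank_groups <- function(scores, k = 10L) {
  stopifnot(length(scores) >= 1L, k >= 1L)
  if (is.list(scores)) {
    v <- vapply(scores, function(s) s$score, numeric(1))
    names(v) <- vapply(scores, function(s) s$group_name, character(1))
  } else v <- scores
  ord <- order(-v, names(v), method = "radix")
  names(v)[ord][seq_len(min(k, length(v)))]
}
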