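#' Configuration for cumulative top-k modeling under MCCV
#'
#' @param n_iterations Monte Carlo cross-validation repeats (default 100).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.8, the 80:20 split).
#' @param k Number of top-scoring groups modeled cumulatively (default 10).
#' @param n_trees Trees per random forest (default 100).
#' @param decision_threshold Probability cutoff for confusion-based metrics
#'   (default 0.5); AUC is threshold-free.
#' @param seed Global seed; all per-iteration, per-group and per-model seeds
#'   are derived from it deterministically.
#' @return A list of class `modeling_config`.
#' @export
modeling_config <- function(n_iterations = 100L, train_fraction = 0.8,
                            k = 10L, n_trees = 100L,
                            decision_threshold = 0.5, seed = 42L) {
  stopifnot(n_iterations >= 1L, train_fraction > 0, train_fraction < 1,
            k >= 1L, n_trees >= 1L,
            decision_threshold >= 0, decision_threshold <= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction, k = as.integer(k),
                 n_trees = as.integer(n_trees),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "modeling_config")
}

#' Stratified train/test split without replacement
#'
#' Splits samples into disjoint train and test sets preserving class
#' proportions: per class, `round(count * train_fraction)` samples
#' (round half up) go to training and the remainder to test. Samples are
#' canonically sorted by id before the seeded shuffle, so the split depends
#' only on the sample ids, labels and seed.
#'
#' @param am A labeled [abundance_matrix()].
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both `abundance_matrix`.
#' @export
stratified_split <- function(am, train_fraction = 0.8, seed = 1L) {
  if (is.null(am$labels)) stop("matrix has no labels")
  ids <- sort(sample_ids(am))
  labels <- am$labels[ids]
  train_ids <- character(0)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      cls_ids <- ids[labels == cls]
      if (length(cls_ids) < 2L)
        stop("class ", cls, " has fewer than 2 samples")
      n_train <- floor(length(cls_ids) * train_fraction + 0.5) # half-up
      n_train <- min(max(n_train, 1L), length(cls_ids) - 1L)
      train_ids <- c(train_ids, cls_ids[sample.int(length(cls_ids))][seq_len(n_train)])
    }
  })
  test_ids <- setdiff(ids, train_ids)
  list(train = subset_samples(am, sort(train_ids)),
       test = subset_samples(am, sort(test_ids)))
}

#' Evaluate cumulative top-m models over ranked groups
#'
#' For m = 1..length(ranked_groups), fits the classifier on the training
#' samples restricted to the union of the top-m groups' species (group-rank
#' order, then within-group order), scores the held-out test samples, and
#' records the metric set. Feature counts are the running sums of group
#' sizes.
#'
#' @param train,test Labeled [abundance_matrix()] objects from
#'   [stratified_split()].
#' @param ranked_groups Character vector of group names, best first.
#' @param group_map A [group_features()] partition.
#' @param cfg A [modeling_config()].
#' @param iteration Integer tag mixed into model seeds.
#' @param trace Optional callback `function(stage, ids)` invoked with the
#'   sample ids used at each classifier fit (stage `"model_fit"`), for
#'   auditing train/test separation.
#' @return List with `metrics` (list of [compute_metrics()] results, one per
#'   m) and `n_features` (integer vector of cumulative feature counts).
#' @export
cumulative_model_eval <- function(train, test, ranked_groups, group_map,
                                  cfg = modeling_config(), iteration = 0L,
                                  trace = NULL) {
  stopifnot(all(ranked_groups %in% names(group_map)))
  features <- character(0)
  metrics <- vector("list", length(ranked_groups))
  n_features <- integer(length(ranked_groups))
  for (m in seq_along(ranked_groups)) {
    features <- c(features, setdiff(group_map[[ranked_groups[m]]], features))
    n_features[m] <- length(features)
    xtr <- train$values[, features, drop = FALSE]
    if (!is.null(trace)) trace("model_fit", rownames(xtr))
    fit <- fit_rf(xtr, as.integer(train$labels), cfg$n_trees,
                  seed_hash(cfg$seed, iteration, "model", m))
    prob <- predict_rf_prob(fit, test$values[, features, drop = FALSE])
    metrics[[m]] <- compute_metrics(as.integer(test$labels), prob,
                                    cfg$decision_threshold)
  }
  list(metrics = metrics, n_features = n_features)
}

#' Run the full G-S-M procedure under Monte Carlo cross-validation
#'
#' The modeling (M) component. Each iteration draws a fresh stratified
#' 80:20 split, scores every taxon group by internal cross-validation on the
#' training samples only, ranks the groups, and evaluates cumulative top-m
#' models (m = 1..k) on the held-out test samples. Per-iteration ranked group
#' and species lists are retained for rank aggregation, and metrics are
#' averaged over iterations.
#'
#' Grouping uses only the species identifiers (it is label- and sample-free),
#' so the partition is computed once and shared by all iterations.
#'
#' @param am A labeled [abundance_matrix()] whose species ids are clade
#'   strings (or supply `group_map`).
#' @param rank Taxonomic rank for grouping: `"genus"`, `"family"`, `"order"`.
#' @param cfg A [modeling_config()].
#' @param scoring_cfg A [scoring_config()]; its seed is overridden by the
#'   global seed in `cfg`.
#' @param group_map Optional precomputed [group_features()] partition
#'   (otherwise parsed from the species ids at `rank`).
#' @param trace Optional callback `function(stage, ids)` receiving the sample
#'   ids used in every scoring fold (`"score_fit"`, `"score_eval"`) and model
#'   fit (`"model_fit"`), plus per-iteration `"train"`/`"test"` id sets.
#' @return An object of class `run_result`: `per_iteration` (list of
#'   iteration records), `summary` (data frame of per-m metric means and
#'   standard deviations over iterations), `rank`, `group_map`, and the
#'   configs.
#' @export
run_mccv <- function(am, rank = c("genus", "family", "order"),
                     cfg = modeling_config(),
                     scoring_cfg = scoring_config(),
                     group_map = NULL, trace = NULL) {
  rank <- match.arg(rank)
  if (is.null(am$labels)) stop("matrix has no labels")
  if (is.null(group_map))
    group_map <- group_features(parse_lineages(species_ids(am)), rank)
  scoring_cfg$seed <- cfg$seed
  per_iteration <- vector("list", cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    res <- tryCatch({
      split <- stratified_split(am, cfg$train_fraction,
                                seed_hash(cfg$seed, i, "split"))
      if (!is.null(trace)) {
        trace("train", sample_ids(split$train))
        trace("test", sample_ids(split$test))
      }
      scores <- score_all_groups(split$train, group_map, scoring_cfg,
                                 iteration = i, trace = trace)
      ranked <- rank_groups(scores, cfg$k)
      ev <- cumulative_model_eval(split$train, split$test, ranked, group_map,
                                  cfg, iteration = i, trace = trace)
      list(iteration = i, ranked_groups = ranked,
           ranked_species = unlist(group_map[ranked], use.names = FALSE),
           metrics = ev$metrics, n_features = ev$n_features,
           test_ids = sample_ids(split$test))
    }, error = function(e)
      stop("MCCV iteration ", i, ": ", conditionMessage(e), call. = FALSE))
    per_iteration[[i]] <- res
  }
  structure(list(per_iteration = per_iteration,
                 summary = summarize_iterations(per_iteration),
                 rank = rank, group_map = group_map,
                 cfg = cfg, scoring_cfg = scoring_cfg),
            class = "run_result")
}

# Per-m means and standard deviations of every metric across iterations.
summarize_iterations <- function(per_iteration) {
  k <- min(vapply(per_iteration, function(it) length(it$metrics), integer(1)))
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1", "auc")
  rows <- lapply(seq_len(k), function(m) {
    vals <- vapply(per_iteration, function(it) {
      c(unlist(it$metrics[[m]][metric_names]), n_features = it$n_features[m])
    }, numeric(length(metric_names) + 1L))
    mu <- rowMeans(vals)
    sdv <- apply(vals, 1L, stats::sd)
    if (length(per_iteration) == 1L) sdv[] <- 0
    out <- data.frame(m = m)
    for (nm in c(metric_names, "n_features")) {
      out[[paste0("mean_", nm)]] <- mu[[nm]]
      out[[paste0("sd_", nm)]] <- sdv[[nm]]
    }
    out
  })
  do.call(rbind, rows)
}

#' @export
print.run_result <- function(x, ...) {
  k <- nrow(x$summary)
  cat("<run_result> rank=", x$rank, ": ", length(x$per_iteration),
      " MCCV iterations, top-", x$cfg$k, " cumulative models\n", sep = "")
  last <- x$summary[k, ]
  cat(sprintf("  m=%d: AUC %.3f +/- %.3f, accuracy %.3f, %d features (mean)\n",
              k, last$mean_auc, last$sd_auc, last$mean_accuracy,
              round(last$mean_n_features)))
  invisible(x)
}

#' Per-iteration ranked group lists from a run
#'
#' @param run A `run_result` from [run_mccv()].
#' @param what `"groups"` (default) or `"species"`.
#' @return A list of character vectors, one ranked list per iteration.
#' @export
ranked_lists <- function(run, what = c("groups", "species")) {
  what <- match.arg(what)
  field <- if (what == "groups") "ranked_groups" else "ranked_species"
  lapply(run$per_iteration, `[[`, field)
}
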