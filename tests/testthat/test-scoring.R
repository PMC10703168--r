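test_that("a perfectly separable sub-dataset scores 1", {
  set.seed(7)
  s <- score_group(separable_subd(20), scoring_config(seed = 3))
  expect_equal(s$score, 1)
  expect_equal(s$fold_accuracies, rep(1, 5))
  expect_equal(s$n_features, 1L)
})

test_that("constant features degrade to the majority-vote rate", {
  v <- matrix(0, 40, 2, dimnames = list(sprintf("S%02d", 1:40), c("a", "b")))
  sub <- structure(list(values = v,
                        labels = stats::setNames(rep(c(1L, 0L), c(30, 10)),
                                                 rownames(v))),
                   class = "abundance_matrix")
  s <- score_group(sub, scoring_config(seed = 5))
  # stratified folds hold 6 pos / 2 neg; majority class is always positive
  expect_equal(s$score, 0.75, tolerance = 1e-12)
})

test_that("score equals an independently coded CV loop on a seeded dataset", {
  set.seed(42)
  v <- matrix(runif(40 * 5), 40, 5,
              dimnames = list(sprintf("S%02d", 1:40), paste0("sp", 1:5)))
  labels <- stats::setNames(sample(rep(0:1, 20)), rownames(v))
  sub <- structure(list(values = v, labels = labels),
                   class = "abundance_matrix")
  cfg <- scoring_config(seed = 99)
  s <- score_group(sub, cfg)

  # reference loop: same fold-assignment rule (canonical sort, per-class
  # seeded shuffle, round-robin) and same per-fold forest seeds, coded here
  # from scratch
  ord <- order(rownames(v))
  x <- v[ord, ]; y <- as.integer(labels[ord])
  folds <- integer(40)
  old_seed <- if (exists(".Random.seed")) .Random.seed else NULL
  set.seed(99)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(1:5, length(idx))
  }
  ref <- numeric(5)
  for (f in 1:5) {
    te <- folds == f
    set.seed(microgsm:::seed_hash(99L, "fold", f))
    fit <- randomForest::randomForest(x[!te, ], factor(y[!te], levels = 0:1),
                                      ntree = 100)
    p <- predict(fit, x[te, ], type = "prob")[, "1"]
    ref[f] <- mean(as.integer(p >= 0.5) == y[te])
  }
  if (!is.null(old_seed)) .Random.seed <<- old_seed
  expect_equal(s$fold_accuracies, ref)
})

test_that("scoring is deterministic and row-order invariant", {
  sub <- separable_subd(10)
  set.seed(1); noise <- matrix(runif(20), 20, 1,
                               dimnames = list(rownames(sub$values), "spB"))
  sub$values <- cbind(sub$values, noise)
  cfg <- scoring_config(seed = 11)
  s1 <- score_group(sub, cfg)
  perm <- sample(nrow(sub$values))
  sub_p <- structure(list(values = sub$values[perm, , drop = FALSE],
                          labels = sub$labels[perm]),
                     class = "abundance_matrix")
  s2 <- score_group(sub_p, cfg)
  expect_identical(s1$fold_accuracies, s2$fold_accuracies)
})

test_that("small minority classes reduce the fold count with a warning", {
  v <- matrix(runif(12), 12, 1, dimnames = list(sprintf("S%02d", 1:12), "a"))
  sub <- structure(list(values = v,
                        labels = stats::setNames(rep(c(1L, 0L), c(9, 3)),
                                                 rownames(v))),
                   class = "abundance_matrix")
  expect_warning(s <- score_group(sub, scoring_config(seed = 2)), "3 folds")
  expect_length(s$fold_accuracies, 3L)

  one_class <- sub
  one_class$labels[] <- 1L
  expect_error(score_group(one_class, scoring_config()), "single-class")
})

test_that("score_all_groups is invariant to group iteration order", {
  am <- toy_matrix(n = 24L, species = paste0("sp", 1:6), seed = 4)
  gm <- structure(list(A = c("sp1", "sp2"), B = c("sp3", "sp4"),
                       C = c("sp5", "sp6")),
                  rank = "genus", class = "group_map")
  gm_rev <- structure(rev(unclass(gm)), rank = "genus", class = "group_map")
  s1 <- score_all_groups(am, gm, scoring_config(seed = 8), iteration = 2L)
  s2 <- score_all_groups(am, gm_rev, scoring_config(seed = 8), iteration = 2L)
  for (g in names(gm))
    expect_identical(s1[[g]]$fold_accuracies, s2[[g]]$fold_accuracies)
})

test_that("the informative group outscores pure-noise groups", {
  ds <- generate_dataset(synth_config(n_samples = 200L, n_genera = 10L,
                                      n_informative_groups = 1L,
                                      effect = 2.0, seed = 21L))
  gm <- group_features(parse_lineages(species_ids(ds$matrix)), "genus")
  scores <- score_all_groups(ds$matrix, gm, scoring_config(seed = 5))
  v <- vapply(scores, function(s) s$score, numeric(1))
  truth <- ds$truth$informative$genus
  expect_gte(v[truth], max(v[setdiff(names(v), truth)]))
})

test_that("rank_groups sorts by score with lexicographic tie-break", {
  expect_equal(rank_groups(c(A = 0.9, B = 0.7, C = 0.8), k = 2), c("A", "C"))
  expect_equal(rank_groups(c(B = 0.8, A = 0.8), k = 1), "A")
  expect_equal(rank_groups(c(A = 0.5, B = 0.4, C = 0.3, D = 0.2), k = 10),
               c("A", "B", "C", "D"))
})

test_that("group_scores_table has the export shape", {
  am <- toy_matrix(n = 20L, species = paste0("sp", 1:4), seed = 2)
  gm <- structure(list(A = c("sp1", "sp2"), B = c("sp3", "sp4")),
                  rank = "genus", class = "group_map")
  df <- group_scores_table(score_all_groups(am, gm, scoring_config(seed = 1)))
  expect_named(df, c("group_name", "n_features", paste0("fold_", 1:5),
                     "mean_score"))
  expect_equal(df$mean_score, sort(df$mean_score, decreasing = TRUE))
  expect_equal(rowMeans(df[paste0("fold_", 1:5)]), df$mean_score,
               ignore_attr = TRUE)
})
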