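test_that("parse_merged_table reads clades, samples and values verbatim", {
  clades <- c(clade_of("Alistipes", "alistipes_shahii"),
              "k__Bacteria|p__Px|c__Cx|o__Aales|f__Aaceae|g__Alistipes",
              clade_of("Prevotella", "prevotella_copri"))
  vals <- matrix(c(20, 30, 50, 80, 70, 50), 3) # percent dialect, max > 1
  path <- write_merged_table(clades, vals, c("S1", "S2"))
  parsed <- parse_merged_table(path)
  expect_equal(parsed$clades, clades)
  expect_equal(parsed$samples, c("S1", "S2"))
  # parsing does not rescale: percent values come back unscaled
  expect_equal(unname(parsed$values), vals)
})

test_that("parse_merged_table rejects malformed tables", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#comment only", empty)
  expect_error(parse_merged_table(empty), "no data rows")

  clades <- c(clade_of("A", "a1"), clade_of("A", "a1"))
  path <- write_merged_table(clades, matrix(1:4, 2), c("S1", "S2"))
  expect_error(parse_merged_table(path), "duplicate clade")

  path2 <- write_merged_table(clade_of("A", "a1"),
                              matrix(c("0.5", "oops"), 1), c("S1", "S2"))
  expect_error(parse_merged_table(path2), "non-numeric.*oops")
})

test_that("empty cells and NA tokens are missing values, not parse errors", {
  path <- write_merged_table(c(clade_of("A", "a1"), clade_of("B", "b1")),
                             matrix(c("0.5", "NA", "", "0.2"), 2),
                             c("S1", "S2"))
  parsed <- parse_merged_table(path)
  expect_equal(is.na(parsed$values), matrix(c(FALSE, TRUE, TRUE, FALSE), 2,
                                            dimnames = dimnames(parsed$values)))
})

test_that("select_species_rows keeps exactly the s__-deep rows", {
  clades <- c("k__Bacteria",
              "k__Bacteria|p__Px|c__Cx|o__Ox|f__Fx|g__Gx",
              clade_of("Gx", "sp1"),
              paste0(clade_of("Gx", "sp2"), "|t__strain1"))
  parsed <- list(clades = clades, samples = "S1",
                 values = matrix(1:4, 4, dimnames = list(clades, "S1")))
  out <- select_species_rows(parsed)
  expect_equal(out$clades, clade_of("Gx", "sp1"))

  all_sp <- list(clades = c(clade_of("A", "a"), clade_of("B", "b")),
                 samples = "S1", values = matrix(1:2, 2))
  expect_equal(select_species_rows(all_sp)$clades, all_sp$clades)

  no_sp <- list(clades = "k__Bacteria", samples = "S1", values = matrix(1, 1))
  expect_error(select_species_rows(no_sp), "no species")
})

test_that("normalize_abundances closes each sample to 1", {
  m <- matrix(c(20, 30, 50, 0.2, 0.3, 0.5), 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  am <- normalize_abundances(m)
  expect_equal(unname(am$values[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(am$values[2, ]), c(0.2, 0.3, 0.5))

  zero <- matrix(0, 1, 3, dimnames = list("S1", c("a", "b", "c")))
  expect_error(normalize_abundances(zero), "all-zero.*S1")
})

test_that("closure is idempotent and scale-invariant (fuzzed)", {
  for (rep in 1:20) {
    set.seed(rep)
    m <- matrix(rexp(5 * 8), 5, 8,
                dimnames = list(paste0("S", 1:5), paste0("sp", 1:8)))
    a1 <- normalize_abundances(m)$values
    expect_equal(normalize_abundances(a1)$values, a1, tolerance = 1e-12)
    c_scale <- runif(1, 0.01, 100)
    expect_equal(normalize_abundances(m * c_scale)$values, a1,
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(a1)), rep(1, 5), tolerance = 1e-9)
  }
})

test_that("read-count filter removes shallow samples and honors modes", {
  am <- toy_matrix(n = 5L)
  rc <- data.frame(sample_id = sample_ids(am),
                   total_reads = c(2e6, 9e5, 3e6, 9e5, 1e6))
  out <- filter_samples_by_reads(am, rc)
  expect_equal(sample_ids(out), sample_ids(am)[c(1, 3, 5)])
  expect_equal(unname(out$labels), unname(am$labels[c(1, 3, 5)]))

  all_deep <- data.frame(sample_id = sample_ids(am), total_reads = rep(2e6, 5))
  expect_equal(filter_samples_by_reads(am, all_deep)$values, am$values)

  expect_message(out2 <- filter_samples_by_reads(am, NULL), "skipped")
  expect_equal(out2$values, am$values)

  partial <- rc[1:3, ]
  expect_error(filter_samples_by_reads(am, partial), "missing from read counts")
  expect_warning(out3 <- filter_samples_by_reads(am, partial, mode = "lenient"),
                 "kept")
  expect_true(all(c("S04", "S05") %in% sample_ids(out3)))
})

test_that("attach_labels_and_clean drops unlabeled and incomplete samples", {
  am <- toy_matrix(n = 10L)
  am$labels <- NULL
  am$values["S03", 2] <- NA # incomplete sample
  lt <- data.frame(sample_id = sample_ids(am)[-5], # S05 unlabeled
                   label = rep(c("1", "0"), length.out = 9))
  expect_message(out <- attach_labels_and_clean(am, lt), "removed")
  expect_equal(nrow(out$values), 8L)
  expect_false(any(c("S03", "S05") %in% sample_ids(out)))
  expect_setequal(unique(out$labels), c(0L, 1L))
})

test_that("text labels map through positive_label", {
  am <- toy_matrix(n = 6L)
  am$labels <- NULL
  lt <- data.frame(sample_id = sample_ids(am),
                   label = rep(c("yes", "no"), 3))
  expect_error(attach_labels_and_clean(am, lt), "positive_label")
  out <- attach_labels_and_clean(am, lt, positive_label = "yes")
  expect_equal(unname(out$labels), rep(c(1L, 0L), 3))

  one_class <- data.frame(sample_id = sample_ids(am), label = rep("yes", 6))
  expect_error(attach_labels_and_clean(am, one_class, positive_label = "yes"),
               "one class")
})
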