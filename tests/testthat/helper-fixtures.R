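# Fixtures are built in code at test time.

# A clade string for one species of a genus, with full lineage.
clade_of <- function(genus, species, family = paste0(genus, "aceae"),
                     order = paste0(genus, "ales")) {
  paste0("k__Bacteria|p__Px|c__Cx|o__", order, "|f__", family,
         "|g__", genus, "|s__", species)
}

# Write a small MetaPhlAn-style merged table to a temp file.
write_merged_table <- function(clades, values, samples,
                               comment = "#mpa_v30 synthetic") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- paste(c("clade_name", samples), collapse = "\t")
  rows <- vapply(seq_along(clades), function(i)
    paste(c(clades[i], values[i, ]), collapse = "\t"), character(1))
  writeLines(c(comment, header, rows), path)
  path
}

# A labeled abundance matrix with named species, rows closed to 1.
toy_matrix <- function(n = 20L, species = paste0("sp", 1:6), seed = 1L,
                       labels = rep(c(1L, 0L), length.out = n)) {
  set.seed(seed)
  v <- matrix(rexp(n * length(species)), n,
              dimnames = list(sprintf("S%02d", 1:n), species))
  abundance_matrix(v / rowSums(v), labels = labels, normalized = FALSE)
}

# A perfectly separable one-feature sub-dataset.
separable_subd <- function(n_per_class = 20L) {
  v <- matrix(c(runif(n_per_class, 0.6, 1), runif(n_per_class, 0, 0.1)),
              ncol = 1,
              dimnames = list(sprintf("S%02d", 1:(2 * n_per_class)), "spA"))
  structure(list(values = v,
                 labels = stats::setNames(rep(c(1L, 0L), each = n_per_class),
                                          rownames(v))),
            class = "abundance_matrix")
}

# Random species clade strings over a random taxonomy, for fuzzing.
random_clades <- function(n_species, seed) {
  set.seed(seed)
  n_gen <- sample(2:8, 1)
  gen <- sprintf("G%02d", seq_len(n_gen))
  fam <- sprintf("F%02d", ceiling(seq_len(n_gen) / 2))
  ord <- sprintf("O%02d", ceiling(ceiling(seq_len(n_gen) / 2) / 2))
  gi <- sample(n_gen, n_species, replace = TRUE)
  # a few clades drop the genus (gap-filled downstream), as MetaPhlAn tables do
  drop_genus <- runif(n_species) < 0.15
  vapply(seq_len(n_species), function(i) {
    base <- paste0("k__Bacteria|p__P01|c__C01|o__", ord[gi[i]],
                   "|f__", fam[gi[i]])
    mid <- if (drop_genus[i]) "" else paste0("|g__", gen[gi[i]])
    paste0(base, mid, "|s__sp", sprintf("%03d", i))
  }, character(1))
}
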