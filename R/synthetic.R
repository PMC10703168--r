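#' Configuration for the taxonomy-structured abundance simulator
#'
#' Defines the simulated study: a two-class cohort of compositional
#' species-abundance profiles in which a minority of genus-level groups carry
#' a class-discriminative abundance shift. Species are nested in genera,
#' genera in families (about three genera each), families in orders (about
#' three families each), so the same ground truth is expressed coherently at
#' every grouping rank.
#'
#' @param n_samples Total samples (default 200).
#' @param n_positive Samples labeled 1/disease (default 100; the rest are
#'   controls).
#' @param n_genera Number of genera (default 30).
#' @param species_per_genus Integer range (length-2 vector) of species counts
#'   drawn per genus (default `c(1, 10)`).
#' @param n_informative_groups Number of genera carrying signal (default 3).
#' @param effect Log-scale abundance shift: weights of species in informative
#'   genera are multiplied by `exp(effect)` in positive samples before
#'   closure (default 2.0; 0 gives a null dataset).
#' @param base_concentration Gamma shape of per-sample species weights
#'   (Dirichlet-style concentration, default 1).
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 200L, n_positive = 100L, n_genera = 30L,
                         species_per_genus = c(1L, 10L),
                         n_informative_groups = 3L, effect = 2.0,
                         base_concentration = 1.0, seed = 1L) {
  stopifnot(n_positive < n_samples, n_positive >= 1L,
            n_informative_groups <= n_genera, effect >= 0,
            base_concentration > 0, length(species_per_genus) == 2L,
            species_per_genus[1] >= 1L,
            species_per_genus[2] >= species_per_genus[1])
  structure(list(n_samples = as.integer(n_samples),
                 n_positive = as.integer(n_positive),
                 n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 n_informative_groups = as.integer(n_informative_groups),
                 effect = effect, base_concentration = base_concentration,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic taxonomy
#'
#' Builds full seven-rank clade strings for a set of species nested in
#' genera, families and orders (about three genera per family, three
#' families per order, and so on upward).
#'
#' @param cfg A [synth_config()].
#' @return Data frame with columns `clade` (the species clade string),
#'   `genus`, `family`, `order` (taxon names at the grouping ranks).
#' @export
generate_taxonomy <- function(cfg = synth_config()) {
  g <- seq_len(cfg$n_genera)
  fam <- ceiling(g / 3); ord <- ceiling(fam / 3)
  cls <- ceiling(ord / 2); phy <- ceiling(cls / 2)
  pad <- function(prefix, i) sprintf("%s%02d", prefix, i)
  n_sp <- with_seed(seed_hash(cfg$seed, "taxonomy"),
                    sample(cfg$species_per_genus[1]:cfg$species_per_genus[2],
                           cfg$n_genera, replace = TRUE))
  rows <- lapply(g, function(i) {
    sp <- sprintf("%s_sp%02d", pad("Genus", i), seq_len(n_sp[i]))
    data.frame(
      clade = paste0("k__Bacteria",
                     "|p__", pad("Phylum", phy[i]),
                     "|c__", pad("Class", cls[i]),
                     "|o__", pad("Order", ord[i]),
                     "|f__", pad("Family", fam[i]),
                     "|g__", pad("Genus", i),
                     "|s__", sp),
      genus = pad("Genus", i), family = pad("Family", fam[i]),
      order = pad("Order", ord[i]))
  })
  do.call(rbind, rows)
}

#' Generate a labeled synthetic abundance dataset with known signal
#'
#' Per sample, species weights are drawn as `gamma(base_concentration, 1)`,
#' i.e. the closed profile is symmetric Dirichlet with the configured
#' concentration. In positive-class samples, the weights of species belonging
#' to the informative genera are multiplied by `exp(effect)` before
#' compositional closure, so the injected signal is relative, exactly as in
#' relative-abundance data (and null species acquire a mild compensatory
#' downshift through closure).
#'
#' @param cfg A [synth_config()].
#' @return List with `matrix` (a labeled [abundance_matrix()] whose species
#'   ids are the clade strings), `taxonomy` (from [generate_taxonomy()]), and
#'   `truth`: the informative taxon names at genus/family/order rank plus the
#'   per-species effect multipliers.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  tax <- generate_taxonomy(cfg)
  n_sp <- nrow(tax)
  informative_genera <- with_seed(
    seed_hash(cfg$seed, "informative"),
    sort(sample(unique(tax$genus), cfg$n_informative_groups)))
  info_species <- tax$genus %in% informative_genera
  multipliers <- ifelse(info_species, exp(cfg$effect), 1)

  labels <- c(rep(1L, cfg$n_positive), rep(0L, cfg$n_samples - cfg$n_positive))
  sids <- sprintf("S%03d", seq_len(cfg$n_samples))
  values <- with_seed(seed_hash(cfg$seed, "weights"), {
    w <- matrix(stats::rgamma(cfg$n_samples * n_sp,
                              shape = cfg$base_concentration, rate = 1),
                nrow = cfg$n_samples, byrow = TRUE)
    w[labels == 1L, ] <- sweep(w[labels == 1L, , drop = FALSE], 2L,
                               multipliers, `*`)
    w / rowSums(w)
  })
  dimnames(values) <- list(sids, tax$clade)
  am <- abundance_matrix(values, labels = labels, normalized = FALSE)

  truth <- list(
    informative = list(
      genus = informative_genera,
      family = sort(unique(tax$family[info_species])),
      order = sort(unique(tax$order[info_species]))),
    multipliers = stats::setNames(multipliers, tax$clade))
  list(matrix = am, taxonomy = tax, truth = truth)
}

#' Write a synthetic dataset as MetaPhlAn-format files
#'
#' Emits `abundance.tsv` (clade strings x samples, full double precision),
#' `labels.csv` (`sample_id,label`) and `truth.json` (the ground-truth
#' manifest) into a directory, so the simulator's output exercises the same
#' input path as real merged profiles.
#'
#' @param ds A dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  am <- ds$matrix
  tsv <- file.path(dir, "abundance.tsv")
  vals <- t(am$values) # species rows x sample columns
  lines <- c(paste(c("clade_name", colnames(vals)), collapse = "\t"),
             vapply(seq_len(nrow(vals)), function(i) {
               paste(c(rownames(vals)[i],
                       formatC(vals[i, ], format = "g", digits = 17)),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, tsv)
  labels_csv <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(sample_id = sample_ids(am),
                              label = as.integer(am$labels)),
                   labels_csv, row.names = FALSE, quote = FALSE)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(ds$truth, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(abundance = tsv, labels = labels_csv, truth = truth_json))
}
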