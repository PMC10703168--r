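#' Run the full G-S-M pipeline and write its three outputs per rank
#'
#' Orchestrates the complete analysis: read and normalize the merged
#' abundance table, attach labels, and for each requested taxonomic rank run
#' grouping, scoring and cumulative modeling under Monte Carlo
#' cross-validation, then aggregate the per-iteration group rankings into
#' significance values and propagate them to species. Per rank it writes the
#' tool's three outputs — `metrics_<rank>.csv` (per-m metric means and
#' standard deviations), `groups_<rank>.csv` (aggregated groups with
#' p-values and member species), `species_<rank>.csv` (species with
#' propagated p-values) — plus `manifest.json` and `run.log`.
#'
#' All randomness derives from `cfg$seed`, and the manifest records only
#' reproducible facts (config, input digests, package version), so identical
#' invocations produce byte-identical outputs.
#'
#' @inheritParams read_abundance_dataset
#' @param ranks Character vector of grouping ranks, subset of
#'   `c("genus", "family", "order")`.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [modeling_config()].
#' @param scoring_cfg A [scoring_config()].
#' @return Invisibly, the manifest as a list (class `run_manifest`).
#' @export
run_gsm <- function(abundance_path, labels_path, ranks = "genus",
                    out_dir, cfg = modeling_config(),
                    scoring_cfg = scoring_config(),
                    read_counts_path = NULL, positive_label = NULL,
                    min_reads = 1e6) {
  stopifnot(all(ranks %in% c("genus", "family", "order")), length(ranks) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(...) writeLines(paste0(...), log_con)

  log_line("stage: input")
  am <- withCallingHandlers(
    read_abundance_dataset(abundance_path, labels_path,
                           read_counts_path = read_counts_path,
                           positive_label = positive_label,
                           min_reads = min_reads),
    message = function(m) {
      log_line("  ", trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    },
    warning = function(w) {
      log_line("  warning: ", trimws(conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  log_line("  samples: ", nrow(am$values), " (", sum(am$labels == 1L),
           " positive), species: ", ncol(am$values))

  outputs <- list()
  lineages <- parse_lineages(species_ids(am))
  for (rank in ranks) {
    log_line("stage: modeling rank=", rank)
    group_map <- group_features(lineages, rank)
    log_line("  groups: ", length(group_map))
    run <- withCallingHandlers(
      run_mccv(am, rank, cfg, scoring_cfg, group_map = group_map),
      warning = function(w) {
        log_line("  warning: ", trimws(conditionMessage(w)))
        invokeRestart("muffleWarning")
      })

    log_line("stage: aggregation rank=", rank)
    agg <- aggregate_ranks(ranked_lists(run), universe = names(group_map))
    spt <- propagate_to_species(agg, group_map)

    metrics_path <- file.path(out_dir, paste0("metrics_", rank, ".csv"))
    groups_path <- file.path(out_dir, paste0("groups_", rank, ".csv"))
    species_path <- file.path(out_dir, paste0("species_", rank, ".csv"))
    utils::write.csv(run$summary, metrics_path, row.names = FALSE)
    agg_out <- agg
    agg_out$member_species <- vapply(agg$item, function(g)
      paste(group_map[[g]], collapse = ";"), character(1))
    utils::write.csv(agg_out, groups_path, row.names = FALSE)
    utils::write.csv(spt, species_path, row.names = FALSE)
    outputs[[rank]] <- c(metrics = metrics_path, groups = groups_path,
                         species = species_path)
  }

  manifest <- list(
    tool = "microgsm",
    version = as.character(utils::packageVersion("microgsm")),
    inputs = list(
      abundance = list(path = abundance_path,
                       md5 = unname(tools::md5sum(abundance_path))),
      labels = list(path = labels_path,
                    md5 = unname(tools::md5sum(labels_path)))),
    config = list(ranks = ranks, n_iterations = cfg$n_iterations,
                  train_fraction = cfg$train_fraction, k = cfg$k,
                  n_trees = cfg$n_trees,
                  decision_threshold = cfg$decision_threshold,
                  seed = cfg$seed, scoring_n_folds = scoring_cfg$n_folds,
                  scoring_scheme = scoring_cfg$scheme),
    outputs = lapply(outputs, function(p) as.list(basename(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("stage: done")
  class(manifest) <- "run_manifest"
  invisible(manifest)
}
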