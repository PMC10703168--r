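# microgsm

Taxonomy-aware **G**rouping–**S**coring–**M**odeling (G-S-M) classification
of species-level metagenomic relative-abundance profiles, with taxonomic
biomarker discovery.

## What it does, and for whom

Shotgun-metagenomic profilers (MetaPhlAn and kin) reduce each sample to a
compositional vector of species relative abundances — fractions in [0, 1]
summing to 1 per sample. Given such profiles for a two-class cohort
(disease vs. control), `microgsm` answers two questions at once: *how well
do the profiles classify the phenotype*, and *which taxonomic groups carry
the signal*. It is aimed at microbiome researchers who want clade-level
biomarker candidates with honest resampling-based performance estimates,
rather than unstable single-species feature selections.

The method partitions the species set S by the taxon at a chosen rank
r ∈ {genus, family, order}, Grp{u} = { s ∈ S : anc_r(s) = u }, and inside
each of T stratified 80:20 Monte Carlo cross-validation iterations:

1. scores every group u by the mean accuracy of a random forest (100 trees)
   under stratified 5-fold cross-validation on the *training* samples
   restricted to Grp{u};
2. ranks groups by score and keeps the top k = 10;
3. fits cumulative models on the union of the top-m groups' species
   (m = 1..k), evaluating accuracy, sensitivity, specificity, precision, F1
   and Mann–Whitney AUC on the held-out 20%.

The T per-iteration rankings are then aggregated by the order-statistic
(robust rank aggregation) score: an item with sorted normalized ranks
r(1) ≤ … ≤ r(N) gets ρ = min_k P(Bin(N, r(k)) ≥ k) and Bonferroni p-value
min(1, ρ·U) over the U-group universe; species inherit their group's
p-value. Three outputs result per rank: the per-m metrics table, the
aggregated group table, and the species table.

A taxonomy-structured compositional simulator with known injected signal
(`generate_dataset()`) supports validation end to end.

## Worked example

Simulate a 200-sample cohort (30 genera, 3 carrying a log-fold-2 abundance
shift in cases), run the pipeline at genus rank, and compare the recovered
groups with the ground truth:

```r
library(microgsm)

ds  <- generate_dataset(synth_config(seed = 1))
run <- run_mccv(ds$matrix, rank = "genus",
                cfg = modeling_config(n_iterations = 25, k = 10, seed = 1),
                scoring_cfg = scoring_config())
run
#> <run_result> rank=genus: 25 MCCV iterations, top-10 cumulative models
#>   m=10: AUC 1.000 +/- 0.001, accuracy 0.996, 64 features (mean)

agg <- aggregate_ranks(ranked_lists(run), universe = names(run$group_map))
head(agg, 5)
#>      item          rho      p_value n_lists_present
#> 1 Genus17 1.180235e-37 3.540706e-36              25
#> 2 Genus25 3.960213e-30 1.188064e-28              25
#> 3 Genus18 8.472886e-14 2.541866e-12              25
#> 4 Genus26 8.472886e-14 2.541866e-12              25
#> 5 Genus13 1.180235e-12 3.540706e-11              25

ds$truth$informative$genus
#> [1] "Genus17" "Genus18" "Genus25"
```

The three injected genera head the aggregated list (`n_lists_present = 25`:
they entered the top-10 in every iteration), and the cumulative top-10 model
separates held-out cases from controls almost perfectly (mean AUC 0.9997
over 64 species on average). `propagate_to_species(agg, run$group_map)`
yields the species-level table.

The same analysis runs from the shell on MetaPhlAn-style files:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","microgsm.R",package="microgsm"))')
Rscript "$CLI" simulate --out demo_in --seed 1
Rscript "$CLI" run --abundance demo_in/abundance.tsv --labels demo_in/labels.csv \
    --rank genus,family,order --k 10 --iterations 25 --seed 1 --out demo_out
```

which writes `metrics_<rank>.csv`, `groups_<rank>.csv`, `species_<rank>.csv`,
`manifest.json` and `run.log` into `demo_out/`.

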