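# ligrec

Ligand–receptor interactome analysis for time-course single-cell RNA-seq
of neuro-immune tissue.

## What it does, and for whom

After an inflammatory insult, immune and stromal cells in sensory ganglia
begin signalling to neurons: ligand genes are upregulated in *sender* cell
types, their receptors are expressed in *receiver* types, downstream target
programs switch on in the receivers, an interferon-stimulated-gene-like
module flares transiently, and monocytes flood the immune compartment
within hours. `ligrec` is for computational biologists who want to run this
whole inference chain — QC and cell selection, per-cell-type differential
expression, ligand–receptor activity scoring, module scoring, permutation
testing, and composition analysis — as tested, seedable R functions rather
than a pile of notebook snippets.

The package also ships a negative-binomial single-cell simulator with
*planted* communication programs, so every stage can be validated against
known ground truth without downloading anything.

## The core statistic

For a candidate pair (sender *s*, receiver *r*, ligand *L*, receptor *R*)
at timepoint *t*, with associated target-gene set *T* and candidate pool
*U* (the union of upregulated genes):

1. background genes (all genes not in *U*) are ranked by mean normalized
   expression in *r*'s cells at *t*, cut into **20 equal-rank intervals**,
   and **100 genes are drawn from each interval**;
2. the raw enrichment score is the receiver-cell average of
   `mean(norm[T]) − mean(norm[background])`;
3. the score is computed against **5 independent background draws**, each
   replicate is **clipped at 0** (negative enrichment = non-activity), and
   the **activity score** is the mean of the clipped replicates.

Candidate ligands come from the selection rule *fold change > 3, detected
in > 10% of cells, P < 0.05* (two-sided Wilcoxon rank-sum vs the day-0
control, exact for small samples, tie-corrected normal approximation
otherwise; Benjamini–Hochberg adjustment where adjusted P is required).

## Worked example

Simulate a two-timepoint experiment with one planted
macrophage → neuron interaction (target fold 5 at 12 h), then run the
chain:

```r
library(ligrec)
library(dplyr)

g <- function(i) sprintf("gene%04d", i)
cfg <- simulation_config(
  n_cell_types = 5, cells_per_type_per_timepoint = 60, n_genes = 2500,
  timepoints = c(0, 0.5),
  planted_interactions = list(
    planted_interaction("macrophage", "neuron_1", g(1), g(2), g(10:19),
                        fold = 5, timepoints = 0.5)),
  seed = 42)
sim <- simulate_dataset(cfg)
ds  <- log_normalize(sim$dataset)

de <- bind_rows(lapply(unique(ds$cells$cell_type),
                       \(ct) suppressWarnings(de_table(ds, ct, 0.5))))
cand  <- select_lr_candidates(de)
ref   <- lr_reference(g(1), g(2), list(g(10:19)))
pairs <- build_candidate_pairs(cand, ds, ref, timepoint = 0.5)
set.seed(1)
acts  <- score_interactome(ds, pairs, ref, unique(cand$gene), 0.5)
tidy(acts)
#> # A tibble: 5 × 7
#>   sender     receiver       ligand   receptor timepoint activity_score
#>   <chr>      <chr>          <chr>    <chr>        <dbl>          <dbl>
#> 1 macrophage neuron_1       gene0001 gene0002       0.5          1.78
#> 2 macrophage schwann_cell   gene0001 gene0002       0.5          0.157
#> 3 macrophage satellite_glia gene0001 gene0002       0.5          0.149
#> 4 macrophage macrophage     gene0001 gene0002       0.5          0.120
#> 5 macrophage monocyte       gene0001 gene0002       0.5          0.108
```

The planted macrophage → neuron pair tops the table: its induced target
program stands far above an expression-matched random background in the
receiver's cells (activity ≈ 1.8), while the same ligand–receptor pair
scored against receivers whose target program was *not* induced stays near
zero. The monocyte influx planted in the same simulation is recovered by
the composition module:

```r
comp <- composition_table(ds$cells, "immune")
composition_fold_change(comp, "monocyte", 0.5)   # planted 0.035 -> 0.65
#> fraction 0.642 vs 0.0333, fold_change 19.2, 95% CI [7.28, 50.9]
```

i.e. the ≈ 18.6-fold monocyte increase the design plants (3.5% → 65% of
immune cells), estimated here from one 360-cell immune compartment per
timepoint.

## Package tour

| area | functions |
|---|---|
| simulation | `simulation_config()`, `planted_interaction()`, `simulate_dataset()`, `write_fixture()` |
| containers & IO | `expression_dataset()`, `read_dataset()`, `log_normalize()`, `read_lr_reference()`, `read_modules()`, `read_pipeline_config()` |
| QC & labels | `compute_qc()`, `filter_neuron_candidates()`, `fit_prototype_classifier()`, `assign_labels()` |
| differential expression | `wilcoxon_rank_sum()`, `bh_adjust()`, `de_table()`, `select_pseudobulk_de()`, `select_lr_candidates()` |
| interactome | `build_candidate_pairs()`, `stratified_background()`, `enrichment_score()`, `score_interaction()`, `score_interactome()`, `sankey_export()` |
| modules & tests | `filter_modules()`, `module_score()`, `permutation_test()` |
| composition | `composition_table()`, `composition_fold_change()` |
| orchestration | `run_pipeline()` (simulate → qc → de → interactome → module-score → compose, with a provenance manifest) |

Result tables are classed tibbles with `ggplot2::autoplot()` methods, and
fitted/result objects support `tidy()`/`glance()`. See the methods
vignette (`vignettes/ligrec-methods.Rmd`) for the model, its assumptions,
and every numerical choice.
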