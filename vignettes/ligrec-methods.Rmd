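---
title: "Methods: ligand-receptor interactome analysis for time-course scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor interactome analysis for time-course scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

After an inflammatory insult, immune and stromal cells in sensory tissue
(dorsal root ganglia and similar neuro-immune niches) start signalling to
neurons and to each other. Time-course single-cell RNA-seq captures this as
(i) upregulated ligand genes in "sender" cell types, (ii) receptor
expression in "receiver" types, (iii) induced downstream target programs in
the receivers, (iv) transiently induced gene modules (an
interferon-stimulated-gene-like response), and (v) drastic shifts in
immune-cell composition (a monocyte influx from a few percent to most of the
immune compartment within hours). `ligrec` implements the full inference
chain from raw counts to a ranked sender-receiver interactome, together with
a synthetic-data generator that plants all of these signals so that every
stage can be validated against known ground truth.

# The model and procedure

## Normalization

"Normalized counts" throughout are library-size-scaled log counts:
per cell, $x_{gc} = \ln(1 + 10^4\, k_{gc} / K_c)$ where $k_{gc}$ is the
count and $K_c$ the cell's total. This is the de-facto standard
normalization of the single-cell toolchains this analysis style comes from;
the marker thresholds used by the cell-selection rules (neuronal marker
$\ge 0.5$, glial marker $\le 2$) are interpreted on this layer. Cells with
zero totals get all-zero normalized values and a warning.

## Cell selection

Quality control discards cells with more than 20% mitochondrial counts
(strictly more than; a cell at exactly 20% is kept). The primary dataset
keeps cells with more than 2,000 detected genes (count > 0); a secondary
rescue pass keeps cells with at least 1,000. Putative neurons are purified
with two marker rules applied disjunctively — a cell is removed when its
normalized neuronal-marker expression falls below 0.5 *or* its
glial-marker expression exceeds 2. We read the published conjunction as two
removal criteria because a cell that lacks the neuronal marker is a
contaminant regardless of its glial expression; the reading is configurable.

Label transfer uses a prototype (nearest-centroid) classifier: per-label
centroids over the most variable genes in normalized space, prediction
scores from a softmax over negative centroid distances. This deliberately
implements only the contract the pipeline consumes — a label, a calibrated
score in $[0,1]$, and the 0.55 discard threshold — rather than any
particular discriminant-analysis machinery; identical distances give score
0.5, hence "unassigned" under the threshold.

## Differential expression

Each cell type at each post-induction timepoint is compared against the
day-0 control with a two-sided Wilcoxon rank-sum test on normalized
expression. Ties get midranks; the variance is always tie-corrected; a 0.5
continuity correction is applied; and for pooled sizes $\le 12$ the p-value
is computed exactly by enumerating all assignments of the pooled midranks
(the same enumeration doubles as the test oracle at tiny $n$). Fold change
is the ratio of group means on the $\mathrm{expm1}$-of-normalized scale
with a $10^{-9}$ pseudocount — the toolchain convention, since the source
analysis never defines it.

Two selection regimes coexist:

* **Pseudobulk DE** (collapsed neuron types): adjusted $P < 10^{-20}$,
  strictly. We use Benjamini-Hochberg by default; the published analysis
  does not state its adjustment (its toolchain defaults to Bonferroni), so
  the method is a parameter. This choice changes the pseudobulk gene list
  and is therefore surfaced prominently rather than buried.
* **Ligand candidates**: fold change $> 3$, detection in $> 10\%$ of the
  cells of the timepoint group, raw $P < 0.05$ — all strict inequalities;
  the raw p-value is used because the published criteria list it separately
  from the adjusted pseudobulk cutoff.

## The interactome activity score

This is the package's core computation. For a timepoint:

1. The **candidate pool** is the global union of upregulated genes across
   cell types (per-type pools are available as an option).
2. A **candidate pair** (sender, receiver, ligand, receptor) exists when
   the ligand is upregulated in the sender and the receptor is detected in
   more than 10% of receiver cells — the only expression threshold the
   criteria state, reused for "expressed". Self-pairs are allowed.
3. **Stratified background**: all genes outside the candidate pool are
   ranked by mean normalized expression in the receiver's cells at the
   scored timepoint (a global-mean ranking is available as an option),
   split into 20 equal-rank intervals, and 100 genes are drawn uniformly
   without replacement from each interval. Equal-rank (quantile) intervals
   are used, not equal-width expression bins, so every interval contributes
   the same number of genes. When fewer genes are available the per-interval
   draw shrinks with a warning, never below 1.
4. The **raw enrichment score** of a pair is the receiver-cell average of
   (mean normalized expression of the pair's associated target genes minus
   mean normalized expression of the 2,000 background genes). Averaging the
   per-cell contrast over cells equals the difference of the population
   means by linearity, which is how it is computed.
5. Each pair is scored against **five independent background draws**; each
   replicate is **clipped at zero** (negative enrichment means
   non-activity) and the activity score is the mean of the clipped
   replicates. Averaging five replicates reduces the background-sampling
   variance of the score; clipping makes the score a non-negative activity
   measure.

Associated target-gene sets ("gene patterns") are an input table —
regulatory-network inference is out of scope, and the simulator emits
ground-truth target sets in the same format.

## Module scores and the permutation test

Module scores use the same binned-control contrast with one background
draw, then min–max scaling to $[0,1]$ across scored cells. The degenerate
all-equal case maps to 0 ("non-activity"; 0.5 is available). Modules are
first intersected with differentially expressed genes and dropped below 10
surviving genes. Group comparisons of per-cell activities use a label
permutation test: statistic $|\bar{x}_A - \bar{x}_B|$, p-value
$(1 + \#\{\text{permuted} \ge \text{observed}\})/(N+1)$ with $N = 1000$
shuffles — the add-one estimator, which is valid and never returns zero.
The absolute difference makes the test two-sided; the published figure
legend does not state sidedness.

## Composition

Cell-type fractions are computed within a compartment (immune, neuronal,
non-neuronal, or the whole dataset), matching how immune percentages are
reported. Fold changes of fractions between timepoints carry a 95%
interval from the normal approximation on the log ratio with independent
binomial counts. No compositional transform (CLR etc.) is applied — the
reported quantity is the raw fraction ratio, e.g. the monocyte influx from
3.5% to 65% of immune cells, a ratio of ≈ 18.6.

# The synthetic-data generator

The generator emulates the structure of an eight-timepoint (days 0–63)
dissociated-ganglion atlas: ~15 cell types across neuronal, immune and
other non-neuronal compartments (monocytes always present), gene-wise
negative-binomial counts, and planted signals.

* **Count model**: gene mean $\mu_g \sim \mathrm{LogNormal}(-0.5, 1)$,
  per-cell library factor uniform on $[0.7, 1.4]$, counts
  $\mathrm{NB}(\mu = \mu_g \ell_c,\ \phi = 0.5)$ with shared dispersion
  (variance $\mu + \phi\mu^2$). This is the simplest model with realistic
  single-cell overdispersion; the spread of the mean prior is comparable to
  the gamma mean priors used by standard scRNA-seq simulators.
* **Planted effects are multiplicative** on the NB mean — ligands in
  senders and target programs in receivers at their active timepoints,
  module genes in all cells at the module's timepoints — so the planted
  fold is exactly what the downstream fold-change rule estimates. An
  interaction can set `target_fold = 1` to create a decoy: an upregulated
  ligand with a silent target program, which downstream analysis should
  score at zero activity.
* **Baseline floors**: planted-role genes get their baseline mean floored
  at 0.5 (receptors at 1.5, in the receiver type) so that fold changes are
  estimable from finite cells and receptors pass the 10% detection rule.
  Without the floor, a planted gene with a near-zero baseline would have an
  undefined empirical fold at desk-scale cell numbers.
* **Composition**: monocyte counts among immune cells are binomial draws at
  fraction 0.035 (baseline) or 0.65 (peak timepoints, default 12 h), the
  remaining immune cells multinomially split over the other immune types —
  so downstream composition estimates carry genuine binomial sampling error.
* **Mitochondrial structure**: 5% of genes are flagged `mt-`; 5% of cells
  get a 20-fold elevated mitochondrial mean, producing the >20% mito cells
  QC must remove.
* **Seeding**: one master seed; each internal stage (composition, gene
  means, library factors, counts, ...) derives a child seed by hashing its
  stage name, so outputs are bit-reproducible and adding a stage never
  perturbs another's draws.

What the generator does **not** emulate: doublets, batch/well effects,
replicate wells per timepoint (each timepoint is one pooled sample — the
published design's replicate structure is not stated), UMI-level noise,
gene-gene correlation beyond the planted programs, and realistic
transcriptome-wide expression distributions. Passing tests therefore show
that the chain recovers the signals it defines under its own noise model —
they are necessary, not sufficient, evidence about behaviour on real data.

# Numerical choices and degenerate inputs

* Strict inequalities at every published threshold (20% mito, 2,000/1,000
  genes, 0.55 score, $10^{-20}$, fold 3, 10%, 0.05) — boundary cells are
  kept or rejected exactly as the published wording implies, and the tests
  pin the boundaries.
* Wilcoxon: exact enumeration up to pooled size 12, tie-corrected normal
  approximation with continuity correction beyond; identical samples give
  $p = 1$ (zero variance is caught explicitly).
* Interactome ties are broken lexicographically by (sender, receiver,
  ligand, receptor) so ranked tables are deterministic.
* Min–max scaling with $\max = \min$ maps to the configured degenerate
  value; empty compartments, zero reference fractions, missing marker
  genes, and sub-3-cell DE groups raise named errors or logged skips.
* All pipeline outputs are written with fixed column order and 9
  significant digits, so file digests are comparable across runs.

# Problem sizes

The validation suite and the reproduction script run the chain at desk
scale, chosen so that every property is measurable with comfortable margins:
2,000–2,500 genes; 100–200 cells per type per timepoint for DE and
recovery analyses (planted folds of 5 are then estimated within ±30%);
3 planted interactions among ≥ 50 candidate pairs (12 decoy ligands ×
expressed receivers); ~2,000 immune cells per timepoint for the
composition analysis; 1,000 label shuffles and 1,000 null draws for the
permutation-test calibration.

# Known limitations

* The activity score is a difference of means against a uniform-over-ranks
  background; it is not a calibrated p-value and is comparable only within
  a run's candidate pool and timepoint.
* Null calibration of the score depends on the expression distribution of
  inactive target programs. On the generator's log-normal mean prior, a
  decoy pair whose target set is an ordinary random gene set keeps a small
  positive activity in roughly one case in five (the validation suite
  measures ~80% exact zeros); near-complete zeroing requires inactive
  target programs to sit below the average background expression, as
  inducible response genes typically do in real tissue.
* The prototype classifier is linear in normalized space; strongly
  overlapping cell types will produce scores near 0.5 and large unassigned
  fractions by design.
* Wilcoxon DE treats cells as independent replicates (no
  pseudoreplication-aware mixed models), exactly as in the published
  analysis style it reproduces.
* The binomial interval for composition fold changes ignores the
  compositional coupling between types; it is the analysis the published
  percentages support, not a compositional-data model.
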