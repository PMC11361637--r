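---
title: "Models and methods behind fatescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fatescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fatescreen analyses fate-biased retinal regeneration: how zebrafish Müller
glia (MG) dedifferentiate into progenitors (MGPCs/RPCs) and preferentially
regenerate an ablated neuron class such as retinal ganglion cells (RGCs).
The package covers the computational arms of such a study — single-cell
trajectory comparison between conditions, signed gene-regulatory-network
(GRN) construction, hypergeometric fate-specificity scoring of
transcription factors (TFs), and the statistics of a crispant
plate-reader screen — together with a simulator that generates data of the
same shape with known ground truth, so every stage is testable without
sequencing data.

```{r setup, eval = FALSE}
library(fatescreen)
```

## The synthetic-data model

`simulate_trajectory_counts()` draws, per cell, a latent trajectory
position $t \in [0,1]$ — uniform under the control condition, and
$\mathrm{Beta}(1.5, 3)$ under ablation so that ablated samples are
enriched early in the MG-activation phase, matching the direction of
condition-density differences seen in regenerating retinas. States are
assigned by fixed thresholds ($t < 1/3$ MG, $t < 2/3$ progenitor,
otherwise neuron); the thresholds are a design choice giving three
comparable compartments, since no quantitative state boundaries exist to
borrow.

Each TF belongs to one lineage module (MG, progenitor, neuron) and has a
Gaussian activity bump over $t$ with a module-anchored centre (0.15 / 0.5
/ 0.85, jittered per TF) and width drawn from $U(0.12, 0.2)$. Gaussian
bumps are simple, smooth and give unambiguous sign ground truth for
regulation. Per cell, activity is multiplied by log-normal noise
($\sigma = 0.4$); this noise *propagates* from a TF to its targets and is
what makes planted edges identifiable beyond the trajectory they share —
with noise-free activities every gene would be a deterministic function
of $t$ and no network method could distinguish a real parent from a
same-module bystander.

The planted network assigns each TF `targets_per_tf` distinct non-TF
targets. Targets are restricted to non-TF genes because a TF gene's
expression is generated from its own activity curve, so an edge into a TF
could never manifest in the counts and would only poison recovery
benchmarks. A configured fraction of edges (default 0.2) is repressive.
Target log-means are `log(baseline) + sum(sign * weight * activity)`
with weights $U(0.3, 1.0)$; baselines are drawn once per network, not per
condition arm, so matched arms differ only through the planted effects.
Counts are negative-binomial (shared size 10) with log-normal library
factors (mean 5). These fidelity constants were set once, during
generator design, to satisfy two competing realism requirements: cells
must clear the standard QC cuts (200 genes / 1000 UMIs), and the planted
structure must be recoverable by reasonable methods — a smoother,
lower-noise manifold favours trajectory recovery while propagated TF
noise favours edge recovery.

The knockout genotype zeroes `ko_tf` (by default the first MG-module TF,
an early-activation factor) and adds `ko_shift = 0.3` to the activity of
every neuron-module TF, emulating a knockout whose progenitors are biased
toward the ablated neuron fate. `expected_condition_delta()` evaluates
the noise-free mean model under both genotypes and is the ground truth
for delta-profile tests.

What the simulator does *not* model: chromatin accessibility, doublets,
ambient RNA, batch effects, or secondary bystander cell death. Passing
tests therefore demonstrate correctness of the algorithms under a clean
generative model, not robustness to every artefact of real data.

The plate simulator draws one unablated control arm and one treated arm
with Gaussian noise truncated at zero. Both arms use the SD
`cv * control_mean`: the screen this emulates was designed around a
single SD measured on wild-type ablated larvae, and the single-SD
convention makes the standardized effect exactly `|effect_fraction|/cv`.
The designed detectable effect is a 30% change in mean; the SD of the
original measurement is not public, so the implied standardized effect
(~1.41 at n = 8, alpha 0.05, power 80%) is back-calculated, and the
simulator's default `cv = 0.213` is a calibration, not a measured value.

## Preprocessing and marker tests

`qc_filter()` removes cells with fewer than 200 detected genes or fewer
than 1000 UMIs (the UMI sentence is read as "<1000", parallel to the
gene threshold), then genes detected in fewer than 3 surviving cells, in
that fixed order. `normalize_log()` is the standard
`log1p(10^4 * count / total)` shift-log. `select_hvg()` ranks genes by a
binned dispersion: the variance of normalized expression z-scored within
20 equal-frequency mean bins, ties broken by gene identifier.

`rank_sum_markers()` implements the threshold-defined marker and DEG
tests with three presets: condition DEGs (|log2FC| >= 0.2, min.pct 0.05,
raw p < 0.05), cell-type markers (log2FC >= 0.5, BH-adjusted p < 0.05)
and timepoint DEGs (log2FC >= 0.25, i.e. fold change 1.18). Fold change
is computed on pseudocounted means of `expm1(normalized)`; the min.pct
filter uses the maximum of the two groups' detection fractions. The
p-value is a two-sided Wilcoxon rank-sum: a normal approximation with tie
and continuity correction above 25 total observations, and below that an
exact tie-aware distribution computed by a subset-sum dynamic program
over doubled midranks, equivalent to enumerating all group assignments
(base R's exact path refuses ties, hence the in-package implementation).
Genes failing the significance criterion are flagged, never dropped.

## Pseudotime and condition deltas

`fit_pseudotime()` orders cells from all conditions jointly: PCA on the
top 2000 variable genes, 30 components; a minimum-spanning-tree path
through cluster centroids rooted at the MG cluster; orthogonal projection
of cells onto the piecewise-linear path; then principal-curve-style
refinement (nodes re-estimated as local cell averages along the current
ordering, lightly smoothed, cells re-projected) until assignments move by
less than 1e-3 or 50 iterations. Cells beyond the curve termini keep
their tangential overshoot so the ends do not collapse into ties. The
method is a deliberately simple single-lineage stand-in for curve-based
trajectory tools — the trajectory here has one path, so nothing branching
is needed. Two numerical choices matter: cells are internally sorted by
identifier (making the fit invariant to input column order), and the
final positions are rank-uniformized before min-max rescaling — pseudotime
is defined only up to a monotone transform, and uniform positions make
the downstream equal-width bins evenly populated.

`condition_density()` estimates a kernel density of pseudotime per
condition, renormalized to integrate to one on $[0,1]$ (the choice of a
kernel over a histogram is ours; the comparison is qualitative either
way), and reports the pointwise log-ratio between two named conditions.

`bin_and_delta()` cuts pseudotime into 50 equal-width bins, averages
normalized expression per gene, bin and condition (empty bins linearly
interpolated from their neighbours, endpoints carried), takes the
per-bin difference (condition2 − condition1), smooths it with a running
mean of span 0.1 × 50 = 5 bins, and rescales each gene by its maximum
absolute smoothed difference so the extreme bin is ±1. Whether the
published relative-expression tables were smoothed before normalization
is unknown; the span is therefore a parameter. Significance per gene
comes from a permutation test (condition labels shuffled across cells,
maximum |smoothed delta| as the statistic) — a defined, oracle-checkable
substitute for fitting per-condition smoothers along the trajectory.
Note that permutations are shared across genes within one run; p-values
are marginally exact but correlated between genes.

`cluster_profiles()` groups per-gene z-scored profiles by k-means (fixed
seed, 10 restarts, best inertia kept, labels renumbered by descending
size); the default k = 11 mirrors the number of expression patterns the
trajectory DEGs segregate into.

## GRN construction

`infer_importance()` is tree-ensemble importance scoring of the
GENIE3/GRNBoost2 family: for each gene, a random-forest regression of its
expression on all TF expressions; a TF's importance is its total
impurity (variance) reduction, normalized per target to sum to one. The
published analysis used a gradient-boosting variant; a random forest with
sqrt-of-TF-count candidate features has equivalent importance semantics
for recovery purposes, runs deterministically under a seed, and the
choice is recorded in the result metadata. Defaults: 100 trees, minimum
leaf 5.

The chain then applies, in order:

* `filter_importance_quantile()` — the 0.95 quantile of importances
  *pooled over all pairs* (the singular phrasing "the 95th quantile"
  suggests one pooled cutoff; a per-target option exists), linear
  interpolation between order statistics, retention inclusive at the
  quantile. With 100 distinct scores exactly 5 survive.
* `annotate_edge_sign()` — Pearson correlation on log-normalized
  expression over all supplied cells (which cells entered the published
  correlation is unstated; all cells is the default here). Strictly
  greater than 0.03 is positive, strictly below −0.03 negative,
  everything else — including undefined correlations from zero-variance
  genes — is discarded and counted in the run log.
* `filter_tf_expressed()` — a TF is "expressed" in the RPC/progenitor
  cluster if detected in at least 5% of its cells, reusing the marker
  tests' min.pct convention since no definition of "expressed" is given.

## TF fate specificity and lineage bias

`tf_specificity()` scores each (TF, cell type) pair by the upper-tail
hypergeometric probability $P(X \ge k)$ of the overlap $k$ between the
TF's target set ($n$ draws) and the cell type's marker set ($K$
successes) in a universe of $N$ genes. Three conventions are ours, each
configurable and recorded: the enrichment (upper) tail, a universe
defaulting to all genes surviving QC, and no multiplicity adjustment by
default (BH optional). `lineage_bias_tally()` counts significant DEGs in
each lineage's marker set split by direction, with positive log2FC
meaning higher in the knockout — the direction in which a knockout
"favours" a fate.

In the simulator's terms, every neuron-module TF is a driver of the
planted knockout bias (the knockout shift is applied module-wide), so
recovery tests ask that neuron-module TFs top the neuron-fate
specificity ranking rather than singling out one TF.

## Crispant screen statistics

`normalize_relative_yfp()` divides each well by the mean of its plate's
unablated wild-type control wells ("relative YFP"); no cross-plate
calibration is applied beyond this per-plate normalization.
`min_sample_size()` is the two-sample, two-sided normal-approximation
design formula $n = \lceil 2 (z_{1-\alpha/2} + z_{1-\beta})^2 / d^2
\rceil$ (n = 16 at d = 1, n = 8 at d = 1.41); an exact noncentral-t
refinement is available as a cross-check.

`screen_test()` compares each crispant gene's ablated wells with the
wild-type ablated reference by the two-group one-way ANOVA F-test
(identical to the two-sided pooled t-test; an all-groups omnibus F adds
nothing when each gene is compared to one reference family). The family
of per-gene p-values is adjusted by the Benjamini–Krieger–Yekutieli
two-stage sharpened step-up: stage 1 runs BH at $q' = q/(1+q)$ and
estimates $m_0 = m - r_1$; stage 2 re-runs BH at $q' \, m / m_0$ (the
original two-stage definition, also the one implemented by the common
statistics packages). The procedure returns decisions, not adjusted
p-values, so the reported adjusted p is the smallest $q$ on a grid of
resolution $10^{-4}$ at which the gene is rejected; the rejection
threshold is monotone in $q$, which makes this inversion exact at grid
resolution. Because $m_0$ adapts to the data, an adjusted p can be
*smaller* than its raw p when many hypotheses are non-null — a property
of the procedure, not a bug. `classify_hits()` applies the screen's
printed classes: significant at adjusted p ≤ 0.01, trending in
(0.01, 0.1], otherwise no effect, with direction relative to the
wild-type ablated reference mean.

Whether the "30% effect size" of the original design refers to a
fractional mean change or a standardized effect is ambiguous; it is
interpreted as a fractional mean change, which together with the
back-calculated SD reproduces the printed n = 8.

## Numerical and testing choices

Degenerate inputs are defined, not accidental: an all-zero gene
normalizes to zeros; a gene with no between-condition difference keeps a
zero delta profile and a zero normalization factor; a TF with no targets
after universe filtering is emitted with p = 1 and a flag; zero
within-group variance in the screen takes an exact fast path (p is 0 or
1); a QC pass that removes every cell warns and returns an empty matrix.
Ties are broken deterministically everywhere (gene identifiers for HVG
ranking, first-seen order for k-means relabelling).

Test problem sizes are chosen for a laptop-scale run: the default
simulated study uses 2000 cells, 300 genes and 20 TFs (the GRN benchmark
dataset); invariant checks use 10–20 replicate datasets of a few hundred
cells; the screen null calibration uses 91-gene screens replicated a few
thousand times. Uniformity of discrete p-values (permutation and
hypergeometric) is tested after the randomized probability integral
transform, which is exactly uniform precisely when the p-values are
valid; a raw KS test against continuous uniform would reject on
discreteness alone.

Known limitations: the trajectory method assumes a single lineage and
PCA-linear geometry; the permutation delta test shares permutations
across genes; GRN recovery is benchmarked against the simulator's
first-order kinetics (no combinatorial regulation); and the screen
simulator's Gaussian wells truncate at zero, which very slightly inflates
low-signal means.
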