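---
title: "Rank-standardized co-expression networks: aggregation, replicability, and expression-level confounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-standardized co-expression networks: aggregation, replicability, and expression-level confounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recoex)
```

# The model

`recoex` treats a co-expression network as a statistical object with a
fixed marginal distribution. Given a gene × sample expression matrix, all
pairwise Spearman correlations are computed, undefined correlations
(constant genes, or too few complete observations) are injected as raw
value 0, and the upper-triangle values are replaced by their ranks
divided by the number of pairs. Every network is therefore a symmetric
matrix with a uniform weight marginal on (0, 1]; two networks differ only
in *which* pairs occupy the top of the ranking. This buys three things:

* robustness — outlier samples can move a correlation a long way but its
  rank much less;
* comparability — networks from experiments of different size, depth, and
  unit live on the same scale, so element-wise averaging is meaningful;
* a tractable null — the aggregate of B independent networks is a mean of
  B iid uniforms, giving closed-form expectations for the replicability
  statistic below.

The assumptions worth stating: co-expression is taken to be monotone
(Spearman), edges are considered exchangeable within a network (no
degree correction is applied at build time — measuring degree bias is the
point of the diagnostics), and aggregation assumes constituents are
independent replicates (batch-corrected inputs violate this, which is why
the replicability statistic should not be applied across networks that
shared a correction step).

## Neighbor voting and its AUROC

Function prediction uses the connectivity-fraction score: gene *i*'s
score for a function with voter set *H* is
$\sum_{j \in H, j \ne i} w_{ij} / \sum_{j \ne i} w_{ij}$, with
zero-degree genes scored 0. Performance is the Mann–Whitney AUROC with
average ranks for ties,
$\mathrm{AUC} = (\sum_i \mathrm{Rank}_i - N_{pos}(N_{pos}+1)/2) /
(N_{pos} N_{neg})$, the probability that a random positive outscores a
random negative with ties counting one half. The implementation is
validated in the test suite against a brute-force pair-counting oracle to
1 part in 10^12^.

Cross-validation is threefold by default: each function's positives are
partitioned into random near-equal folds independently of other
functions; per fold, the held-out positives are scored by the remaining
voters and compared against all genes never annotated to the function.
Negatives are all never-annotated genes in the universe, not only genes
carrying some other annotation — the simplest reading, and the one that
keeps the negative set identical across folds. Functions with fewer
positives than folds are skipped with a warning and excluded from the
network mean rather than being scored at 0.5, which would shrink network
differences artificially.

## Aggregation and the replicability statistic

Aggregation averages rank-standardized weights element-wise over the
shared gene universe (universes are intersected; a union would leave the
mean undefined where networks are missing), then re-ranks. Summing and
averaging give identical re-ranked networks. The pre-re-ranking mean is
retained in the `rawMean` slot because the replicability statistic is the
standard deviation of exactly these values: re-ranking would restore a
uniform marginal and erase the agreement signal. Under independence the
mean of B uniform(0,1] grids has SD $\sqrt{1/(12B)}$; replicated topology
concentrates mass at both ends and widens the spread, up to $\sqrt{B}$
fold for identical networks. The null is computed by Monte-Carlo
aggregation of permuted rank grids (the same construction as
`nullNetwork()`), and its closed form is asserted in the tests within 2%.

## Confound diagnostics

The diagnostics quantify the expression-level dependence of network
topology and performance: Spearman correlation between node degree and
median expression (excluding constant genes, whose correlations were all
undefined and carry no information); Fisher-transformed z-scores
$\mathrm{atanh}(r)\sqrt{n-3}$ for cross-network comparisons; per-gene
leave-one-out AUROC against median expression; expression-matched control
sets; label-blind predictors (degree or expression as the score for every
function); and per-group OLS of per-network AUROC on mean expression with
adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-2)$.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| top-edge `fraction` | 0.01 | fraction of gene pairs | standard "top 1%" threshold for edge-set comparisons; identities (Jaccard of a network with itself = 1, full fraction = baseline) hold at any value |
| annotation size bounds | 20–1000 | genes | the usual GO-slim filter: below 20 the AUROC is too noisy, above 1000 the term is uninformative; bounds inclusive |
| `folds` | 3 | — | threefold CV leaves two-thirds of positives voting, enough for sets of ~20 |
| detection filter threshold | 0.5 | fraction of samples | keep genes non-zero in strictly more than half the samples of every group |
| median filter threshold | 16 | UMI counts | the high-expressor restriction; strict `>` by default with an `inclusive` flag |
| sample QC | 1000 detected genes, 10 samples/group | — | "fewer than" phrasing implemented strictly: a sample at exactly the threshold survives |
| `n_null_draws` | 20 | draws | Monte-Carlo SE of the null SD is reported; 20 draws put it well below the 2% closed-form check |

# The synthetic generator

`simulationConfig()` describes a batched single-cell experiment: per-gene
baseline log-means uniform over a wide range (so an expression gradient
always exists), disjoint co-expression modules driven by standard-normal
per-cell latent factors with per-module loadings, per-gene cell-type mean
shifts (compositional co-expression when types are pooled), per-gene
batch offsets, log-normal library sizes normalized to mean 1 (so CPM
renormalization changes the data measurably), and negative-binomial count
sampling (dispersion 0.3 by default; UMI data are overdispersed, and a
Poisson option exists for closed-form checks). Zeros arise from count
sampling alone by default — drop-out rates fall as the mean rises, which
is the empirically dominant mechanism — with an optional independent
drop-out probability, default off. Defaults emulate a small plate-based
experiment: 8 batches × 16 cells, two cell types in equal proportion,
2000 genes.

The bulk generator emits each sample as an expectation over many cells
(continuous values, no count noise), with sample-level latent factors,
optional logit-scale variation in cell-type proportions (compositional
co-expression between marker modules), and log-normal measurement noise
(`noise_sd`, default 0.2 — enough to keep correlations off the boundary
without drowning moderate loadings).

`module_placement = "high_expression"` assigns module genes to the top of
the baseline gradient. This matters for confound work: in a simulation
whose only shared variation is a factorizable technical factor (library
size), the connectivity-fraction score is nearly constant across genes
and the direction of expression-related effects is unstable. Real
confounded data instead couple expression level with *learnable*
structure — well-detected genes carry the co-expression programs. Placing
a broad program among high expressors reproduces, in kind, the package's
three confound signatures: positive degree–expression correlation in raw
counts that CPM reduces or flips; expression-matched control sets
performing like an expression-tilted target set; and performance eroding
when the network is restricted to high expressors (the within-stratum
gradient is compressed, so there is little left to separate members from
non-members).

What the generator does **not** emulate: read-level noise (no FASTQ, no
UMI deduplication errors), ERCC spike-in chemistry, mapping artifacts,
realistic cell-type hierarchies, gene-length effects, or correlated
module structure (modules are disjoint and independent). Passing tests on
synthetic data therefore demonstrate that the statistics behave correctly
under their stated models — calibrated nulls, recovered planted signal,
correct closed forms — not that any particular real dataset will show the
same effect sizes.

# Numerical choices

* **Ranking domain.** Each unordered pair is ranked once over the upper
  triangle and mirrored; ranking the full symmetric matrix would
  double-count ties. The diagonal is fixed at 0 and excluded from
  ranking, degree, and voting — self-edges are uninformative and would
  shift all degrees equally.
* **Undefined correlations** become raw value 0 *before* ranking, so a
  constant gene's edges land at the rank position of 0 among the signed
  correlations, not at an arbitrary post-hoc weight.
* **Zeros-as-missing** requires at least 3 complete observation pairs per
  gene pair; fewer makes the correlation undefined (hence 0).
* **Tie-breaking in `topEdges()`** is lexicographic by gene-pair id, so
  the top-1% set is deterministic across runs and platforms.
* **Aggregation rounding.** The element-wise mean is snapped to 9 decimal
  places before re-ranking. Distinct mean-rank values differ by at least
  $1/(B \cdot n_{pairs})$ — far above rounding noise at any realistic
  size — while floating-point summation order would otherwise break exact
  ties inconsistently and make aggregation depend on network order.
* **Uniformity checks** (KS against uniform) are asserted on continuous
  data; with heavily tied count data the average-rank convention
  necessarily produces atoms in the marginal.
* **Expression-matched bins** are rank-based quantiles (ties broken by
  first occurrence), robust to the heavy ties of count medians; bin edges
  come from the full universe rather than the target set so that control
  candidates exist in every bin (a flag for target-defined bins would be
  a small extension, but universe bins are the ones under which matching
  is always feasible).
* **Degenerate inputs** error loudly and early: empty gene universes,
  all-removed samples, exhausted matching bins (naming the bin),
  constant regression predictors, |r| ≥ 1 in the Fisher transform.

# Design decisions that were genuinely open

* The median-expression filter uses strict `>` (with `inclusive = TRUE`
  available): the two natural readings differ at exactly the threshold
  value, and the strict reading is the conservative one for a filter
  meant to be stringent.
* Negatives in cross-validation are all never-annotated genes. The
  alternative (genes with at least one other annotation) changes absolute
  AUROCs slightly but none of the comparisons the package is built for.
* Cross-validation folds are drawn independently per function; a jointly
  stratified design would couple functions through their shared genes
  without an obvious benefit at GO-slim-like set counts.
* The KS comparison of "connectivity distributions" accepts either the
  per-edge semantic-similarity values of each network's top edges (the
  default, matching how the distributions are visualized) or the raw
  top-edge weights; both are exposed because the choice is a modelling
  decision, not an implementation detail.
* The command-line surface is `runWorkflow()` plus the exported
  functions; the package is an analysis library, and a shell wrapper
  would add a dependency without adding capability.

# Problem sizes

The test suite exercises networks of 60–2000 genes; chance-level
calibration uses a 2000-gene null network with 10 annotation seeds, the
replicability calibrations use 150-gene networks with 20 null draws, and
the confound battery uses 900 genes × 128 cells. The acceptance script
simulates 2000 genes × 20 bulk samples across 10 seeds. These sizes give
Monte-Carlo error comfortably inside every asserted tolerance while the
full suite stays fast enough to run routinely.

# Known limitations

* Dense matrices throughout: memory is quadratic in gene count, so
  networks much beyond ~20,000 genes need a sparse or blocked rewrite.
* Batch-correction algorithms are out of scope; corrected matrices enter
  as just another input variant, and the replicability statistic is not
  meaningful across constituents that shared a correction step.
* Gene-universe harmonization is plain id intersection — no ortholog or
  probe mapping.
* The analytic null for the replicability fold assumes exchangeable,
  independent constituents; heteroscedastic constituents (very different
  sample sizes) will inflate the observed SD slightly even without
  shared topology.
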