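---
title: "Functional epigenetic module analysis with femnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional epigenetic module analysis with femnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femnet)
```

## The model

Promoter DNA methylation and gene expression are anti-correlated for many
epigenetically silenced genes: hypermethylation of the region around the
transcription start site tends to accompany loss of expression. femnet looks
for *functional epigenetic modules* (FEMs): connected subgraphs of a
protein--protein interaction (PPI) network whose genes jointly show
differential methylation and differential expression in opposite directions
between two phenotypes (here, normal tissue versus tumour).

The pipeline has four statistical layers.

**1. Gene-level statistics.** Probe-level beta values (methylated fraction,
in $[0,1]$) are collapsed to one value per gene using a fixed promoter-region
priority: the mean of TSS200 probes if any exist, else first-exon probes,
else TSS1500 probes; gene-body probes are never used, because body
methylation is only weakly (and often positively) related to expression.
Differential statistics $t^{(D)}_g$ (methylation) and $t^{(R)}_g$
(expression) are moderated t-statistics: gene-wise pooled variances are
shrunk towards a prior variance whose scale and degrees of freedom are
estimated by the method of moments on the log sample variances, exactly the
classic empirical-Bayes squeeze of the limma school (the test suite checks
agreement with `limma::eBayes` to 1e-8). Statistics are computed on beta
values directly, with no M-value transform, and P values are two-sided.
Because the two data types have different intrinsic scales, the expression
statistics are multiplied by $sd(t^{(D)})/sd(t^{(R)})$ over the common gene
set, so both contribute with equal variance.

**2. Network weighting and module search.** Each gene receives the
integrated statistic
$$t^{(I)}_g = \left[H(t^{(D)}_g)H(-t^{(R)}_g) +
H(-t^{(D)}_g)H(t^{(R)}_g)\right]\,\lvert t^{(D)}_g - t^{(R)}_g \rvert,$$
with $H$ the Heaviside step and $H(0)=0$: a gene whose two statistics share
a sign carries no anti-correlation evidence and contributes zero. Each PPI
edge is weighted $w_{gh} = (t^{(I)}_g + t^{(I)}_h)/2$, and the search runs
on the maximally connected component of the weighted graph (ties between
equal-sized components are broken towards the component containing the
lexicographically smallest gene symbol). A module's *modularity* is the mean
weight of its induced edges — not the Newman–Girvan global quantity.

Module growth is a seeded local greedy search. From each of the top-ranked
genes by $t^{(I)}$, the neighbour whose connecting edges have the largest
mean weight is considered, and accepted while that mean exceeds $\tau$ times
the current modularity. The choice of acceptance rule was genuinely open. A
strict "only additions that increase modularity" rule is the $\tau = 1$
special case (the mean induced weight rises if and only if the new edges
beat the current mean), but it is degenerate: in any region of comparable
edge weights the running mean can only fall, so the search provably stops at
the single heaviest edge and can never recover an extended hotspot. The
default $\tau = 0.5$ lets growth traverse such plateaus while still
stopping, typically within one edge-step of a planted module's boundary,
when edge weights fall to background level; recovery simulations in the test
suite (planted 15-gene modules, statistics ~ N(±3,1) against an N(0,1)
background on 500-gene graphs) give mean Jaccard overlap above 0.8 between
recovered and planted members. Growth is capped at `max_size = 100` by
default.

**3. Significance, pruning, validation.** A module's permutation P value
randomly reassigns the node statistic pairs over all network genes and
recomputes the module's modularity on its fixed member set. Since an edge
weight is the mean of its endpoints' integrated statistics, the permuted
modularity depends only on which statistics land on the member genes; the
implementation therefore samples member statistics directly, which is
algebraically identical to re-weighting the whole network (a test verifies
this) and orders of magnitude faster. P values use the tie-inclusive
convention $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$ and
never return zero. Largely overlapping modules are redundant: after sorting
by modularity, a module is dropped when its overlap coefficient
$|A \cap B| / \min(|A|,|B|)$ with a retained module exceeds 0.5. Validation
in an independent cohort re-weights the network with that cohort's
statistics and recomputes each module's modularity and permutation P on its
surviving members; a complementary check correlates discovery and
validation t-statistics over module genes.

**4. Deviation scores, coordination, subtypes.** Per-gene normal-reference
means and standard deviations (normals only; zero standard deviations are
floored at the smallest positive value observed and flagged) standardize
each sample: $Z_{gs} = (X_{gs} - \mu_g)/\sigma_g$. The scaling factor
$\alpha = \sigma_Z(D)/\sigma_Z(R)$, computed over *all* genes and scored
samples, makes the two Z scales comparable, and the FEM score of module $m$
in sample $s$ is
$$\mathrm{FEM}_s = \frac{1}{|G_m|}\sum_{g \in G_m}
\lvert Z^{(D)}_{gs} - \alpha Z^{(R)}_{gs}\rvert,$$
where $G_m$ are the module genes significant at both levels with
anti-correlated statistics. The binary deviation matrix marks gene--sample
pairs whose two-sided Gaussian P values (from $|Z|$) both fall below 0.1
*and* whose deviation directions match the gene's cohort-level
anti-correlative pattern; the relatively relaxed 0.1 threshold follows the
module-level logic — FEMs are inferred without per-gene thresholds, and the
matrix should describe patterns across as many module genes as possible.
Coordination is tested by comparing the mean Manhattan distance between the
matrix rows to a null built from independent within-row sample
permutations (each row's flag count is preserved exactly); coordinated
deviation gives *smaller* distances, so the default alternative is
lower-tail, with the mutually-exclusive upper tail exposed as an option.
Whether the published test was one- or two-tailed is not stated in words;
we commit to the lower tail as the reading consistent with the reported
coordination findings.

For integrative subtypes, the latent-variable joint clustering used on the
real cohorts is deliberately **not** reimplemented: `joint_cluster_standin`
(row-standardized stacking of the two data types + k-means with 25 restarts)
is an explicit stand-in, and `build_centroids` accepts any externally
produced partition. The package's own committed computation is the
centroid/classification layer: per data type, genes are centred to mean zero
over the training samples and averaged within clusters; new samples are
centred with *their own* set's gene means and assigned by maximal Spearman
correlation. Centring is an explicit, default-on step (`centre = FALSE` for
pre-centred input) because the two invariance contracts interact: the
classification step proper is exactly invariant to strictly monotone
per-sample transforms of its input, while the centring step absorbs
per-gene additive offsets; applying a monotone transform *before* centring
would in general change ranks, so the two properties hold for the stages
that own them.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.5 | growth acceptance: new-edge mean weight must exceed `tau` x modularity; 1 = strict increase |
| `max_size` | 100 | module growth cap |
| `n_perm` | 1000 | permutations for module and coordination tests |
| `overlap_threshold` | 0.5 | overlap coefficient above which a module is redundant |
| `sig_threshold` | 0.05 | per-gene eligibility (both P values) for deviation scoring |
| `p_threshold` | 0.1 | per-sample deviation call in the binary matrix |
| `max_missing_frac`, `k` | 0.5, 5 | probe missingness filter ("strictly more than half" dropped) and k-NN imputation |

All stochastic functions accept an explicit `seed`; `run_fem_pipeline`
derives per-stage child seeds from one master seed (default 1, recorded in
the manifest), so a run is reproducible from its manifest and inputs alone.

## The synthetic cohort generator

`generate_cohort` emulates the statistical structure the analysis assumes,
so every stage can be exercised without any external download:

* **Methylation** is logit-normal at the probe level: promoter probes around
  a baseline beta of 0.15, decoy gene-body probes around 0.7 (which the
  summarizer must ignore), per-probe offsets and per-entry noise on the
  logit scale, so beta values stay strictly inside (0, 1).
* **Expression** is Gaussian on the log2 scale (a "raw" mode with zeros
  exercises the zero-substitution/log2/quantile-normalization path).
* **Planted modules** are dense connected subgraphs (default internal
  density 0.8) attached to a connected small-world or scale-free background
  by a small number of bridge edges (default 3). Member genes are shifted by
  `delta_D` on the logit-methylation scale and `delta_R` (opposite sign) on
  the log2-expression scale; per-gene effect sizes are jittered by a fixed
  U(0.6, 1.4) factor stored with the network, because real modules are
  driven by heterogeneous effects — a flat profile would make
  correlation-based centroid classification meaningless. Passing the same
  network object to `generate_cohort` draws an independent cohort over the
  same genes and module biology, which is how validation cohorts are made.
* **Subtype gradient**: luminal-B-like samples shift by
  `lumB_multiplier` (default 2) times the luminal-A shift, reproducing the
  normal < luminal-A < luminal-B deviation ordering.
* **Coordination mode** controls which tumours deviate per gene: one shared
  sample set (`coordinated`), disjoint sets (`exclusive`), or independent
  draws.
* **Copy number** is a gene-level statistic with large effects placed
  uniformly over the network — deliberately unclustered, to contrast with
  the network-clustered methylation hotspots in the shortest-path
  comparison.

What the generator does *not* emulate: realistic 450k probe identities and
genomic coordinates, batch and purity effects, count noise in RNA-seq,
segmentation structure in copy number, or correlated background topology
between the two data types. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the assumed generative
structure, not performance on real cohorts.

## Numerical choices and degenerate inputs

* Permutation P values are tie-inclusive with a +1 pseudo-count and never
  return 0 or use strict inequalities on floating-point equality (a 1e-12
  tolerance guards comparisons).
* Zero pooled variances (moderated t) and zero normal-reference standard
  deviations are floored at the smallest positive value observed and
  flagged rather than producing infinities.
* Quantile normalization breaks ties by averaging tied-rank reference
  values; statistic scaling uses all genes present in both statistic
  vectors, not only network genes.
* Isolated seeds yield degenerate single-gene modules with p = 1 that are
  excluded downstream; a constant binary deviation matrix reports p = 1
  with a degeneracy flag; a module with no eligible genes is skipped with a
  warning rather than scored as 0.
* k-means restarts (25) with a fixed seed make the clustering stand-in
  deterministic; Spearman ties use average ranks; classification ties are
  broken towards the first cluster label and flagged.

## Simulation scales

The test suite and the acceptance script run entirely on generated data at
desk scale, chosen to keep the full suite under a minute while leaving
comfortable statistical margins: 500-gene networks with one 15-gene planted
module for hotspot recovery (50 replicates), 500 null replicates at
`n_perm = 200` for calibration of both permutation tests, 100 replicates
each for the deviation-score ordering, coordination discrimination
(10 genes x 100 samples, `n_perm = 500`) and shortest-path contrasts, and
50 replicates for centroid classification. The acceptance script uses one
300-gene cohort of 50 + 50 + 50 samples with three planted modules
(fully affected, partially coordinated, mutually exclusive) and
`n_perm = 1000`.

## Known limitations

* The greedy search is local and deterministic; it does not implement the
  simulated-annealing global spin-glass optimization, and only the
  statistic-randomization significance test is provided (a topology-aware
  permutation scheme would be a natural extension hook).
* The iCluster-style joint latent variable model, survival analyses, and
  pathway-activity scoring that surround the method on real data are out of
  scope by design.
* Gene-set enrichment is a hypergeometric overlap test over GMT sets, not a
  ranked-list enrichment score.
* With very small normal reference sets the Gaussian per-sample P values
  in the binary deviation matrix are only approximate.

## A worked example

```{r example, eval = FALSE}
library(femnet)

spec <- cohort_spec(seed = 42)       # 50+50+50 samples, 500 genes
cohort <- generate_cohort(spec)
res <- run_fem_pipeline(cohort, out_dir = "fem_run", n_perm = 1000,
                        seed = 42)
res$module_table                     # seed, size, modularity, permutation p
res$deviation$alpha                  # data-type scaling factor
res$deviation$scores                 # module x sample FEM scores
sapply(res$deviation$coordination, `[[`, "p")
```
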