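---
title: "Hybrid K-means initialization: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid K-means initialization: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kminit)
```

## The problem

Batch K-means minimizes the within-cluster sum of squared Euclidean
distances, `SSE(C) = sum_k sum_{x_i in c_k} ||x_i - mu_k||^2`, by Lloyd
sweeps: assign every point to its nearest centroid, recompute centroids
as cluster means, repeat until the assignment is stable. The objective
is non-convex; both the solution quality and the number of sweeps
depend on the starting centroids, which are classically drawn at random
from the data. `kminit` implements three deterministic or
population-based alternatives and the apparatus needed to compare them
fairly: baselines, validity indices, model selection for `k`, a
synthetic-data generator, and a reporting pipeline.

K-means' implicit model is compact, roughly spherical, convex clusters
of comparable spread. Everything downstream (the synthetic generator in
particular) is built around that assumption; none of it should be
expected to behave sensibly on manifold or density-defined structure —
that is what the DBSCAN baseline is for.

## The K-means core

`run_kmeans()` is a faithful batch implementation with three documented
policies:

* **Convergence** is "assignment vector unchanged between consecutive
  sweeps". For batch updates this is equivalent to "centroids no longer
  move", but needs no floating-point tolerance. A centroid-shift
  safeguard (`tol`, default `1e-9`) and `max_iter = 300` protect
  against numerically oscillating ties.
* **Iteration counting**: `iterations` is the number of completed
  assign-and-update sweeps; the final sweep that merely confirms
  stability is not counted. A start that is already a fixed point
  reports 1. This makes iteration counts comparable across
  initializers.
* **Empty clusters** (possible when a start is poor) are repaired by
  handing the emptied cluster the point farthest from its stale
  centroid, keeping `K` fixed. Assignment ties break towards the lowest
  cluster index, so runs are deterministic given the start.

The SSE trace across sweeps is retained on every partition; the test
suite asserts it is non-increasing on every run it touches.

## The three initializers

**MST skeleton (`mst_init`).** Prim's algorithm on the complete
Euclidean graph (deterministic; ties toward smaller vertex indices)
gives a spanning tree whose high-degree vertices sit in locally dense
regions. The *skeleton* is all vertices of degree ≥ 2, ranked by degree
(descending), total incident edge weight (ascending — tighter hubs
first), then index; if fewer than `K` qualify (tiny or path-like data),
leaves are appended under the same ranking. The first centroid is the
top-ranked hub; the rest are added by a maxi-min rule on the
degree-weighted distance `h(s_i, s_j) = (v_i + v_j) d(s_i, s_j)`:
among remaining skeleton points, pick the one whose smallest `h` to the
already chosen centroids is largest. The degree weighting biases the
spread-out selection towards dense regions, mitigating the classical
maxi-min weakness of seeding on outliers. The source literature defers
the exact skeleton criterion to an earlier reference that is not
recoverable; the ranking above is this package's own committed
rendering of "points from which the most edges pass", and published
per-dataset MST-hybrid numbers are therefore not treated as exactly
reproducible.

**Genetic search (`ga_init`).** Chromosomes are sets of `K` distinct
observation indices — centroids are restricted to observed points,
which keeps the search space finite and guarantees pairwise-distinct
starts. Fitness is `1 / (1 + SSE)` of a single nearest-centroid
assignment; the source description names only "a target function", and
this choice is positive and strictly monotone in the K-means objective.
Defaults `M = 50`, `T = 100`, `P_C = 0.8`, `P_m = 0.1`, elitism 1 are
conventional GA settings at this problem size. Selection is
roulette-wheel on fitness; crossover is single-point at centroid
boundaries; mutation swaps one centroid for a uniformly drawn data row;
offspring with duplicated centroids have the duplicate resampled.
Elitism plus best-ever tracking make the attained fitness
non-decreasing over generations. Monte-Carlo loops in the tests shrink
`M` and `T` (typically 20 and 30) purely for runtime; the
published-value wine check runs the full defaults.

**Hierarchical cut (`hier_init`).** Ward-linkage agglomeration (the
`ward.D2` form on Euclidean distances) minimizes within-cluster
variance — the same objective K-means optimizes — so its `K`-cut group
means are natural starts; `stats::hclust` supplies the tree. Complete,
average, and single linkage are accepted alternatives.

## Validity indices

Internal: mean silhouette (`s_i = (b_i - a_i)/max(a_i, b_i)`,
singletons and fully coincident configurations contribute 0), the Dunn
index (minimum between-cluster distance over maximum diameter; `Inf`
with a warning when all clusters collapse), and RPT. The
robustness–performance trade-off index has no published formula; the
definition committed here is `RPT = Si * (1 + S)` where `S` is the mean
Rand index between the input clustering and re-clusterings of `B`
bootstrap resamples (same method, same `K`), compared on the resampled
points. `RPT/Si` is bounded in `(1, 2]`, near 2 for stable separated
clusterings — a pattern consistent with the published tables (e.g.,
printed iris RPT/Si ≈ 1.84), but printed RPT values are not treated as
reproducible.

External (computed only when ground-truth labels exist): Rand and
Hubert–Arabie adjusted Rand from pair counts; Hubert's Γ as the Pearson
correlation of the two pairwise co-membership indicators; accuracy as
the optimal one-to-one cluster-to-class matching (a Hungarian
assignment on the contingency table — not per-cluster majority voting,
which can exceed the matching bound when cluster counts differ);
class-size-weighted best F1; and mutual information / variation of
information with natural-log entropies (the printed VI magnitudes are
consistent with nats, e.g. values near `ln 2`). Degenerate cases are
explicit: ARI with a zero denominator is 1 for identical partitions
else 0 (logged); Hubert's Γ on a trivial partition is an error, and the
pipeline reports `NA` there.

## Choosing k

`select_k()` scans `k = 2…15` (clipped to `n - 1` with a warning) and
takes the majority of three votes: argmax mean silhouette; the gap
statistic with uniform reference draws over the feature bounding box
(`B = 50` by default) under the one-standard-error rule; and the elbow
automated as the largest second difference of the SSE curve (the visual
criterion made deterministic). If all three disagree the median is
used and flagged. Each vote re-clusters with the same configurable
method (default: K-means, best of 10 restarts).

## Synthetic data: what it emulates, what it does not

`make_mixture()` draws `K` isotropic unit-variance Gaussian components
whose means sit on an axis-aligned unit grid scaled by `separation`,
so the nearest pair of component means is exactly `separation`
within-component standard deviations apart. Component sizes are
multinomial in the requested weights (redrawn until every component has
at least 2 members); an `outlier_frac` fraction of points is replaced
by uniform draws over 1.5 times the bounding box and relabelled by
nearest component mean, so external indices stay well defined. The
seven profiles of `dataset_profiles()` reproduce the benchmark shapes
(n from 30 to 306, d from 3 to 13, 2–7 classes); `separation` defaults
to 3, which after standardization yields visibly overlapping classes
comparable to the real tables' difficulty.

The generator matches the spherical-cluster assumption by construction.
It does not emulate correlated features, heteroscedastic classes,
heavy tails, or manifold structure — a green synthetic test therefore
establishes correctness of the machinery under the model's own
assumptions, not performance on arbitrary real data. Two measured
consequences worth knowing:

* At `separation = 8` the Gaussian tails still occasionally generate a
  point whose nearest component mean is not its generating component;
  no clusterer can "recover" that label. The perfect-recovery test
  therefore runs at `separation = 10`, where this probability is
  negligible (≈ Φ(−5) per point).
* The convergence-rate comparison is a small effect for the MST hybrid:
  across 600 benchmark-shaped mixtures at separation 2–4, random
  initialization needs on average ~8.5 sweeps, the MST hybrid ~7.8, the
  GA hybrid ~6.3, and the hierarchical hybrid ~4.2. The MST advantage
  (~0.7 sweeps against a per-dataset SD near 5) needs several hundred
  datasets to resolve, which is why the acceptance test uses 600 rather
  than the minimal 200, and why the sign test is applied to the pooled
  hybrids-versus-random comparison — the dominance claim it checks —
  rather than per hybrid.

## Standardization and data handling

All clustering is done on z-scored features using the sample
(`n − 1` denominator) standard deviation; this choice reproduces the
published SSE scale (standardized iris as one cluster has total SS
`149 × 4 = 596`, and the `K = 3` solution SSE ≈ 139, matching the
printed ≈ 140; the population denominator would inflate these).
Zero-variance columns are an error naming the column. Rows with missing
values are dropped and counted at load time. Class labels are recoded
to consecutive integers from 1 and are used only by external indices,
never by any clusterer. Cluster ids are 1-based and DBSCAN noise is
labelled 0, the conventions of R's clustering ecosystem.

## Baselines

Agglomerative clustering shares `hier_init`'s tree and returns the cut
itself. DBSCAN is the textbook algorithm; with `eps = "auto"` the
radius is the knee — maximum second difference — of the sorted
`min_pts`-nearest-neighbour distance curve, and `min_pts` defaults to
4. Published DBSCAN rows depend on unstated parameters and are not
reproduction targets; silhouette and RPT for DBSCAN are computed on
non-noise points only (logged convention). The EM Gaussian mixture is
full-covariance, initialized from random distinct rows and the pooled
covariance, best log-likelihood over restarts, with a `1e-6` ridge on
near-singular covariances (logged); its within-run log-likelihood is
asserted non-decreasing.

## Reproducibility and numerical policy

Every stochastic operation takes an explicit seed and restores the
caller's RNG state, so results are pure functions of their arguments.
Deterministic tie-breaks are documented at each site (lowest index for
assignment, smallest vertex pair for the MST, lowest seed for restart
ties). Squared distances are computed via one BLAS product with
negative values clamped at 0; equality assertions against oracles use
`1e-12` (index algebra) or `1e-9` (accumulated geometry) tolerances.

## Known limitations

* The MST skeleton criterion is this package's committed
  interpretation; published MST-hybrid rows are reproduced in kind, not
  number.
* RPT is a package-defined index standing in for an unpublished one.
* Absolute published iteration counts depend on an unstated restart
  protocol and are compared only as orderings.
* The GA operates on observation indices; it cannot propose centroids
  off the data, which is the right search space for initialization but
  not for direct SSE minimization.
* Published rows for the three gene-expression datasets depend on an
  external feature-selection step and are out of scope; synthetic
  profiles stand in for their shapes only.
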