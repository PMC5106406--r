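---
title: "Methods: projected clustering and subspace-cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projected clustering and subspace-cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subspacer)
```

## Why subspace clustering

With tens of dimensions and well under a thousand records, distances
computed over the full dimension set concentrate: every record is roughly
equally far from every other, and full-space clustering or classification
extracts little. The working assumption of this package is that meaningful
groups exist, but each group is defined only within its own subset of
dimensions — one patient group may agree on a handful of laboratory values,
another on a different handful, and the remaining dimensions are noise *for
that group*. A subspace cluster is therefore a pair (member set, dimension
set), and the analysis object is a whole collection of such pairs, usually
pooled from many algorithm runs.

## Preprocessing

Three steps, in a fixed order, each auditable via `preprocess_report()`:

1. **Complete-case filtering** (`drop_incomplete_records()`): any record
   with a missing value in any dimension is removed. Imputation is
   deliberately out of scope — in small cohorts an imputed value can invent
   exactly the within-subspace agreement the method is searching for.
2. **Nominal encoding** (`encode_nominal()`): a binary dimension maps its
   two levels to 0 and 1 (declared level order, first level to 0); a
   k-level dimension maps to integer codes 0..k-1. Integer coding keeps one
   column per dimension so the table shape is preserved; it does impose an
   artificial order on unordered levels, which is acceptable for the
   k = 3 case it is meant for and should be reconsidered for larger k.
3. **Min-max normalization** (`normalize_minmax()`): each dimension is
   rescaled by `(v - min) / (max - min)` to [0, 1] using its own observed
   extremes, so all dimensions carry equal weight in segmental distances.
   A constant dimension would divide by zero; it is mapped to 0 with a
   warning (and recorded) rather than failing, so a degenerate column
   cannot abort a pipeline. The transform is idempotent, which the tests
   assert.

Class labels are held outside the value table throughout: they are never
encoded, normalized, or visible to the clustering; they exist only for
splitting and evaluation.

## The PROCLUS implementation

`proclus(ds, C, D)` follows the classic three-phase medoid scheme.

*Initialization.* A uniform sample of `min(n, A * C)` records (default
`sample_factor A = 30`) is thinned by greedy farthest-first selection —
under the full-space Manhattan segmental distance — to a pool of
`min(sample, B * C)` candidate medoids (default `greedy_factor B = 3`).
Farthest-first guarantees the pool spreads across all planted groups with
high probability; the factors are conventional safety multipliers, exposed
in the interface.

*Iteration.* From the current `C` medoids: (1) each medoid's **locality**
is the set of records strictly within its full-space distance to the
nearest other medoid (if that leaves at most one record, the
`ceiling(n/C)` nearest records are used instead, preventing degenerate
statistics); (2) the per-dimension mean absolute deviation `X[i, j]` of the
locality from its medoid is standardized within each medoid,
`Z[i, j] = (X[i, j] - mean_j) / sd_j`, and the `C * D` globally smallest
Z-values are taken greedily subject to two dimensions minimum per medoid —
if a medoid's deviations have zero spread, its dimensions rank by raw
deviation instead; (3) every record joins the medoid minimizing the
segmental distance under that medoid's dimension set; (4) the configuration
is scored by the cluster-size-weighted mean segmental distance of members
to their cluster centroid. The best configuration is kept; its "bad"
medoids — the smallest cluster, plus any cluster under
`min_deviation * n / C` members (default 0.1) — are swapped for unused pool
candidates, and the loop stops after `max_iterations` (default 30)
consecutive non-improving swaps. Because only the best configuration is
ever mutated, the kept objective is non-increasing by construction.

*Refinement.* Dimension sets are recomputed once from the actual clusters
(not localities), records are reassigned once, and, when
`handle_outliers = TRUE`, a record whose distance to its nearest medoid
exceeds that medoid's *sphere of influence* (its smallest distance to
another medoid under its own dimension set) becomes an outlier rather than
a forced member.

Every source of randomness — sampling, pool seeding, swap choices — runs
under one integer seed recorded in the result's provenance, and all ties
(equal distances, equal Z-scores) break to the lowest index, so a run is
bit-reproducible. The tests assert identical member and dimension sets for
repeated runs with the same seed.

`run_sweep()` enumerates the (C, D, seed) grid in product order and
`pool_results()` concatenates all clusters, because redundancy across
parameter settings is itself informative: a structure that recurs across
many settings is more credible than one seen once.

## Comparing clusters

All three set measures are implemented as **dissimilarities**:
`jaccard = 1 - |A∩B|/|A∪B|`, `dice = 1 - 2|A∩B|/(|A|+|B|)`,
`overlap = 1 - |A∩B|/min(|A|,|B|)`, on either the member or the dimension
sets. Presenting the Jaccard index in its `1 - ratio` form makes it a
distance (it satisfies the metric axioms, which the tests verify by brute
force on random triples), so embedding and seriation apply directly; the
other two are kept on the same orientation for consistency. The empty-set
conventions `d(∅, ∅) = 0` and `d(∅, X) = 1` close the 0/0 corner so a
pairwise matrix is always total.

`mds_embed()` defaults to classical (Torgerson) scaling: double-center the
squared dissimilarities, take the top two eigenpairs, scale by the square
roots of the (non-negative-clamped) eigenvalues. It is deterministic and
exact on Euclidean-realizable matrices; a canonical orientation (axes by
eigenvalue order, each axis's sign fixed so its first non-zero coordinate
is positive) removes the reflection ambiguity so repeated runs are
identical. The SMACOF alternative (seeded random start, Guttman-transform
majorization) is available for matrices far from Euclidean; Kruskal
stress-1 is reported for both. Heatmap seriation uses average-linkage
hierarchical clustering leaf order — a standard, deterministic choice that
places zero-distance pairs adjacent.

Filters are a flat clause list under a single AND or OR, mirroring a filter
panel rather than a query language; sequential application of several specs
composes more complex logic. The keep-mask is returned alongside the
filtered collection so a display can grey out rather than drop.

## Evaluation

`entropy_score()` is Shannon entropy of the within-cluster label
proportions normalized by `log K`, with `K` the number of distinct labels
in the *full* dataset — normalization makes 1 mean "as mixed as possible"
regardless of K, and using the dataset-wide K keeps scores comparable when
a cluster happens to miss a class entirely. `compactness()` measures spread
within the cluster's *own* subspace, which is the only space in which the
cluster claims its members are similar. `match_to_ground_truth()` matches
found to planted clusters greedily by pairwise member F1 (ties to lowest
index) and averages over `max(n_found, n_true)` slots so both spurious and
missed clusters are penalized; subspace agreement is the mean Jaccard
similarity of the matched dimension sets.

## The class-split / refinement workflow

`run_workflow()` executes: split by label, sweep and pool per class,
evaluate; then optionally detect dominant dimensions, remove them, and
re-sweep. The dominance rule — a dimension occurring in at least a fraction
τ (default 0.5) of *every* class's pooled clusters — formalizes what is
otherwise an expert's reading of per-class occurrence charts: a dimension
frequent in one class only is class-specific signal, while cross-class
ubiquity marks global structure that crowds out local patterns. The rule is
monotone in τ (tested), and `manual_dims` lets an expert inject a
hand-chosen list instead, preserving the human-in-the-loop path. The
removed dimensions are asserted absent from every post-refinement subspace
on every run.

Two further conventions: when labels are absent the split step is skipped
with a log note and the whole dataset is processed as one subset; and a
conceptual "single cluster per class" run is provided as
`single_cluster_dims()` — the D lowest-variance dimensions of the subset —
because the medoid-based algorithm needs at least two medoids to define a
locality radius, so C = 1 is emulated rather than run.

The sweep's D range matters for refinement: dominant dimensions only
surface in runs whose dimension budget exceeds the class-specific subspace
size (small-D runs fill their few slots with the tightest class-specific
dimensions first). The workflow default therefore spans D values both below
and above the expected subspace size, as a broad sweep would in practice.

## What the generator emulates — and what it does not

`generate_dataset()` plants Gaussian clusters on a uniform background:
members of cluster k are `Normal(mean_profile, sigma_in)` (clipped to
[0, 1]) on that cluster's subspace and Uniform(0, 1) elsewhere. This is the
minimal structure satisfying the algorithm's low-variance-per-dimension
criterion. Default mean profiles alternate 0.15/0.85 with a per-cluster
rotation, so with the default `sigma_in = 0.05` planted clusters are
well separated (subspace-mean gaps of at least ten standard deviations) on
their disjoint subspaces.

**Dominant dimensions** are a contaminated normal: every record is
`Normal(global_mean, sigma)` except a small fraction
(`global_outlier_rate`, default 0.05) drawn from the background. The
contamination is essential, not cosmetic: per-dimension min-max
normalization rescales by the observed range, so a *pure* concentrated
Gaussian would be stretched back to ordinary variance and lose exactly the
dominance it is meant to model. A few full-range records anchor the range
so the bulk stays concentrated after normalization — which is also the
realistic clinical pattern: on a dominant marker most patients agree while
a few extremes span the scale.

Optional extras exercise the rest of the pipeline: nominal yes/no columns
with cluster-specific rates (so encoding does real work), fully-background
noise records with coin-flip labels (stressing entropy and outlier
handling), and missing values injected uniformly *after* the ground truth
is fixed.

What the generator does **not** emulate: realistic clinical marginals,
correlations between dimensions, overlapping subspaces, non-Gaussian
within-cluster shapes, or label noise beyond the noise records. Passing the
recovery tests therefore shows the machinery is correct on its stated
model, not that any particular clinical dataset will yield clean subspace
clusters.

## Numerical choices and conventions

- Record ids and dimension names are the public identifiers everywhere;
  the import dialect's 0-based positional indices are translated on read.
- Ties break to the lowest index in every ranking (medoid assignment,
  Z-scores, greedy matching), making runs reproducible.
- Aggregation-table "barcodes" use 20 equal-width bins over [0, 1];
  histograms use the declared level codes. Cell counts must sum to the
  cluster size and global counts to the record count (asserted over random
  collections).
- Table-lens quartiles use linear-interpolation quantiles (R type 7), with
  Tukey's 1.5 IQR rule for outliers.
- Glyph spikes: angle `2π(index-1)/n_dims` by dataset column order, color
  index `(index-1) mod 10` into a fixed 10-color palette, and
  `inverse_spread` length `1 - sd_cluster/sd_global` clipped to [0.2, 1]
  (0.2 when the global spread is zero). The importance measure is this
  package's convention — spike length has no canonical definition — and is
  flagged in the sidecar so downstream consumers can tell.
- Figures always carry machine-readable CSV sidecars; nothing downstream
  (including the tests) parses a rendered image.

## Problem sizes used by the test suite

The suite's study conditions are chosen to finish in minutes on one CPU
while leaving clear margins: the recovery benchmark plants 3 clusters of
100 records in disjoint 5-dimension subspaces of a 25-dimension background
(`sigma_in = 0.05`) and asks `proclus(C = 3, D = 5)` for median member F1
of at least 0.9 and median subspace Jaccard similarity of at least 0.6 over
10 seeds; the sweep-structure check runs the full 7 x 12 grid (C 2-8,
D 3-14) on 100 records; the workflow benchmark uses 160 records in two
classes (70/90) with one planted 4-dimension subspace each plus a
6-dimension dominant block, swept with C in {2, 3} and D in {6, 8, 10, 12},
asking for at least 5 of 6 dominant dimensions at τ = 0.5 and a median
post-refinement best-match subspace Jaccard of at least 0.5 over 10
generated cohorts. Property checks (set-measure oracles, filter oracles,
metric axioms, count conservation) run on hundreds to a thousand random
instances under fixed seeds.

## Known limitations

- PROCLUS inherits its family's biases: it prefers large clusters, needs C
  and D up front, and its outlier rule depends on medoid geometry. Pooled
  sweeps mitigate but do not remove the parameter sensitivity.
- Integer coding of k > 2 nominal levels imposes an order; one-hot
  encoding would change the dimension universe and is not provided.
- The dominance rule treats all pooled runs equally; weighting by run
  quality (or restricting to a D range) is left to the caller via the
  sweep configuration.
- Combined member-plus-dimension dissimilarities are an extension point:
  the measure registry is one function, but only the three set measures
  ship.
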