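---
title: "Degree rank-order disruption and consensus modularity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree rank-order disruption and consensus modularity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdconn)
```

This vignette is the package's account of its own methods: the models and
estimators it implements, the conventions it fixes where the field's
informal descriptions leave choices open, what the synthetic-data generator
does and does not emulate, and the problem sizes at which the test suite
validates each claim.

## 1. From time series to binary graphs

A subject is an `N x T` matrix of node time series. The analysis pipeline
is deliberately minimal: Pearson correlation over time for all node pairs,
then **thresholding by absolute correlation to a fixed link density**. For
density `d`, exactly `M = floor(d * N(N-1)/2)` node pairs with the largest
`|r|` become edges of an undirected, unweighted simple graph. Fixing the
edge *count* rather than the correlation cut makes graphs comparable across
subjects — the threshold itself becomes subject-dependent and is recorded
as metadata.

Conventions fixed here (the quantity is standard, the details often are
not):

* **floor, not round**, for `M`: the realized density never exceeds the
  nominal one, and the count is deterministic.
* **Ties at the cut** are broken by lexicographic node-pair order. Ties are
  measure-zero for real-valued correlations but occur in degenerate and
  test inputs; a deterministic rule makes every construction bit-identical
  on rerun.
* **Absolute value**: strong negative correlations form edges. Negating
  any subset of node series leaves the graph unchanged (tested).
* **Connectivity is reported, never enforced.** Sparse graphs can
  disconnect; the component structure is metadata, and disconnected node
  pairs simply contribute zero to global efficiency.
* Zero-variance node series make correlations undefined; the constructor
  refuses them by name rather than silently dropping nodes, because node
  order is the cohort-wide frame of reference for every later stage.

Density sweeps reuse one ranking, so edge sets are nested across densities
(10–50% in steps of 10% by default); nestedness and the exact edge count
are asserted as properties over random instances.

## 2. Graph metrics and random-graph normalization

Per graph the package computes mean Watts–Strogatz local clustering (nodes
of degree < 2 contribute 0), global efficiency (mean inverse shortest-path
length, zero for disconnected pairs), modularity

$$Q(\gamma) = \frac{1}{2M}\sum_{ij}\Big[A_{ij} - \gamma\,\frac{k_i k_j}{2M}\Big]\,\delta(c_i, c_j),$$

and small-worldness, the ratio
`(C_G / C_rand) / (E_rand / E_G)` with the conventional small-world call at
ratio > 2. The random reference is the mean over `n_real` null graphs
(default 25). Two null models are available: **Erdős–Rényi** G(N, M)
(the default) and **degree-preserving** Maslov–Sneppen rewiring. Both are
exposed because descriptions of small-world normalization in the
literature alternate between them; the choice is a parameter, never
implicit. Clustering, efficiency, and Q are validated against brute-force
oracles (exhaustive triangle counts, Floyd–Warshall distances, the direct
double sum) to 1e−12 on dozens of random graphs with N ≤ 15.

## 3. The disruption index k_D

Let `r` be the **reference degree map** — the element-wise mean nodal
degree of a designated reference cohort, all graphs at one common density —
and `d` a subject's degree profile at that density. k_D is the OLS slope of
`d − r` on `r` over all N nodes, with intercept `b` and fit correlation
`r_fit` reported alongside. The regression is unweighted and includes every
node, zero-degree nodes included; no significance test is attached to an
individual slope (group-level inference is a separate, explicit step).

Interpretation is anchored by exact limits, all of which are tested
analytically:

* a cohort regressed on its own map gives k_D = 0 exactly;
* `d = α r` gives k_D = α − 1 (a uniform gain is a positive slope, not
  disruption of order);
* a full random permutation of degrees gives E[k_D] = −1.

**Variants.** `kd_after_deletion` (k_D′) drops designated nodes from the
regression — degrees are *not* recomputed on a pruned graph, so the
variant isolates whether the index is driven by those nodes rather than
measuring a different network. `kd_random_subset` (k_D″) refits on random
node subsets (defaults: 10% of nodes, 5000 subsets); for a genuinely global
disruption, subset medians track the full-network value, and that agreement
is itself an acceptance property. `kd_noise_curve` mixes white Gaussian
noise into the series at levels 0.2–1.0 in steps of 0.2, rebuilds the graph
at each level, and reports k_D per level with the noise-free baseline
prepended.

**Group k_D** is the slope of the *group mean* degree profile against the
reference — not the mean of per-subject slopes — because the group-level
quantity of interest is the scatter of mean degree differences. Per-subject
slopes remain available by mapping `kd_index` over the cohort. At the
problem sizes used here (N ≈ 90) individual-subject slopes are noisy
(inter-subject sd ≈ 0.3–0.4 under the default generator) while group
slopes are stable; the validated claims are therefore stated at the group
level, and individual k_D should be interpreted at these scales only
relative to its cohort spread. At the node counts of imaging studies
(thousands of nodes) the per-subject estimate tightens substantially.

## 4. Consensus modularity, NMI, allegiance

Community detection uses multi-level Louvain maximization of Q(γ) (the
optimizer is `igraph::cluster_louvain`; sweep order is randomized by an
explicit seed, and labels are canonicalized to first-appearance order).
Because correlation networks exhibit modularity degeneracy, a **consensus**
over 100 repetitions is the unit of analysis: the co-assignment matrix
(fraction of repetitions placing a node pair in one module) is thresholded
at 0.9, and the final modules are the connected components of the kept-pair
graph. Components are the minimal closure of the pairwise "same module
above threshold" relation; singleton modules are allowed. With one
repetition the consensus reduces to the single run (tested), and quality is
asserted non-decreasing across the optimizer's aggregation levels.

Partition similarity is normalized mutual information,
`NMI = 2 I(P1;P2) / (H(P1) + H(P2))`, from the label co-occurrence
confusion matrix. Entropy-zero corners are defined explicitly: two
single-module partitions are identical (NMI 1); single- versus multi-module
is 0.

**Module allegiance** asks, node by node, whether a subject keeps its
baseline module membership. Because independently detected partitions carry
arbitrary labels, "same membership" needs a label correspondence; the
package uses optimal one-to-one maximum-overlap matching (an assignment
problem on the confusion matrix, solved by a Hungarian-algorithm
implementation validated against exhaustive enumeration). The matching is
deterministic, symmetric in module count, and reduces to the identity when
the partitions agree, so a partition against any relabeling of itself
scores all-ones. Unmatched subject modules (when the subject has more
modules than the baseline) map to "none" and score 0. Group allegiance maps
are element-wise means; ROI profiles report, per subject, the fraction of
ROI nodes whose matched label lands in each baseline module (rows sum to at
most 1).

**Parameter selection.** The two-parameter sweep (densities 10–50%,
γ = 1–2 in steps of 0.25) scores each cell by the mean NMI of its consensus
partition with its 4-neighborhood in parameter space and selects the
stability peak, ties resolved toward the lowest density, then the lowest γ.
The pipeline default operating point is 10% density and γ = 1.5. Selection
here is purely similarity-based; judging whether named functional systems
appear in the selected partition is a human call outside this package's
scope.

## 5. The synthetic generator: what it emulates, what it does not

`modular_cov_spec` defines a block correlation matrix: `r_within` inside
modules, `r_between` across, unit diagonal. Under the constraints
(`0 < r_within < 1`, `0 ≤ r_between < r_within`) this matrix is always
positive semi-definite, and the constructor additionally verifies PSD by
eigendecomposition. Subjects are zero-mean multivariate Gaussian draws;
per-subject heterogeneity is symmetric jitter on the latent correlation
matrix (sd `subject_noise_sd`), projected back to the nearest valid
correlation matrix by eigenvalue clipping — membership of nodes in modules
never varies across subjects. The inter-subject variability model of real
resting-state cohorts is unknown; correlation-level jitter is this
package's choice, made once and documented here.

The default study conditions used across the examples, tests, and the
acceptance script: 90 nodes in 6 modules of unequal sizes
(25, 20, 15, 12, 10, 8), `r_within = 0.6`, `r_between = 0.05`, T = 300
timepoints, `subject_noise_sd = 0.03`, cohorts of 20, graphs at 10%
density. Unequal module sizes matter: at a fixed edge budget, nodes in
larger modules have more strong partners and become hubs, giving the
degree heterogeneity the disruption regression needs (a constant reference
map makes the slope undefined, and the code refuses it).

**Planted disruption** comes in two constructions, with different roles:

* `plant_disruption` (degree-mix): `d' = (1 − λ) d + λ π(d)` for a uniform
  random permutation π. Since E[cov(π(d), d)] ≈ 0, the expected recovered
  slope is −λ exactly, giving a closed-form ground truth for parameter
  recovery (verified by Monte-Carlo at λ ∈ {0, 0.25, 0.5, 0.75, 1} and
  recovered within ±0.05 at N = 1000).
* `rewire_disruption` (edge-rewire): a fraction λ of edges, sampled with
  probability proportional to summed endpoint degrees, is detached and
  reattached uniformly among non-edges, conserving N, M, and simplicity.
  This acts at the graph level, so the full path time series → graph → k_D
  can be exercised; its k_D response is strictly decreasing in λ but not
  calibrated to equal −λ (hub-preferential removal is more damaging per
  edge: λ = 0.3 yields group k_D ≈ −0.46 under the default conditions).

`add_white_noise` mixes z-scored signal with unit-variance white Gaussian
noise as `(1 − p)·z(signal) + p·z(noise)`, re-z-scored, so `p` is the noise
fraction and correlation magnitudes stay comparable across levels; `p = 0`
reproduces the input correlations and `p = 1` destroys all inter-node
structure.

What the generator does **not** emulate: hemodynamics and autocorrelated
BOLD spectra (draws are temporally white), spatial geometry and
parcellation structure, scanner artifacts, motion, and physiological
confounds, and any empirical inter-subject variability law. Passing
recovery tests on these cohorts demonstrates that the estimators recover
what they claim under the stated statistical model — not that real
recordings satisfy that model.

## 6. Cohort pipeline and inference conventions

`run_cohort` orchestrates the full analysis from a manifest (TSV:
`subject_id`, `group`, `file`, optional numeric covariates): graphs per
subject, reference map and consensus baseline from the designated reference
group (the baseline partition is computed on the reference group's mean
correlation matrix), per-subject k_D, NMI versus baseline, allegiance maps,
optional metric sweeps, group summaries, covariate correlations of k_D
(patients only), and per-node group contrasts. Group inference is
deliberately simple and assumption-light at this scale: per-node
**permutation tests** on group-label shuffles (two-sided, p floored at
`1/(n_perm+1)`) with **Benjamini–Hochberg** FDR across nodes. Covariate
relationships are Pearson correlations with the t-transform p-value.
Spatially aware inference (cluster enhancement, family-wise error over
voxel neighborhoods) belongs to imaging toolchains upstream of this
package and is intentionally absent.

All randomness flows from one top-level seed through a documented mixing
function (`derive_seed`), so per-subject and per-repetition streams are
independent yet individually reproducible; reports embed the seed and
config. Cohorts with differing node counts are rejected, not masked: node
identity across subjects is an upstream contract.

## 7. Numerical choices and degenerate inputs

* Correlation matrices are symmetrized (`(R + Rᵀ)/2`) and the diagonal
  pinned to 1 before thresholding; a ridge of 1e−10 stabilizes the
  Cholesky factor of jittered covariances.
* `kd_fit` errors on a constant reference (undefined slope) and returns
  `r_fit = 0` for a constant response (the self-reference case).
* Deletion variants require at least 2 surviving nodes and report
  `n_nodes_used`; subset variants require at least 3 nodes per subset.
* NMI entropy-zero corners as in section 4; allegiance with unmatched
  modules as in section 4.
* The assignment solver minimizes over potentials in O(n³); scores are
  negated overlaps, and rectangular matrices are handled by transposition
  with unmatched rows reported as NA.
* Consensus co-assignment keeps pairs strictly above the threshold
  (`> 0.9`), matching the "likelihood above 0.9" reading; with all
  repetitions identical the matrix is exactly 0/1 and the choice of strict
  versus weak inequality is immaterial.

## 8. Validation scale and limitations

The test suite validates: exact analytic limits of k_D; degree-mix
recovery at N = 1000 over 100 subjects per magnitude (±0.05); the
end-to-end rewire dose response at N = 90 with 20 subjects per arm;
metric-oracle agreement at N ≤ 15; consensus recovery of 4-block planted
partitions (N = 100, 100 repetitions, 50 runs); subset-k_D agreement at
N = 500; noise robustness at N = 90 (cohort-mean k_D within ±0.15 of zero
up to 40% noise, collapse below −0.5 at 100%); and FDR calibration of the
nodal contrast over 50 null replicates. These sizes were chosen so the
whole suite runs in minutes on a laptop while keeping Monte-Carlo error
well inside each asserted band.

Known limitations: binarized graphs only (no weighted metrics, by design);
no betweenness/rich-club/path-length metrics; temporally white generator
(see section 5); individual-subject k_D is noisy at double-digit node
counts (section 3); and the consensus-threshold closure can, for unstable
graphs, produce one giant module when co-assignment rarely exceeds the
threshold — raising `n_reps` or lowering `threshold` is the standard
remedy, and the co-assignment matrix is returned so such cases are
visible.
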