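---
title: "Mapper-based local-model ensembles as risk-minimizing workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapper-based local-model ensembles as risk-minimizing workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlmapper)
```

## 1. The morphism abstraction

`mlmapper` treats every stage of a supervised-learning pipeline as the
same kind of object: a *machine learning morphism* — a parametric map
`F(x; p)` between an input and an output space, bundled with an empirical
risk function `R̄(p; X, Y)` and a parameter prior. Fitting is always risk
minimization over training realizations:

```
p* = argmin_p R̄(p; X, Y)
```

All risks in the package are empirical (in-memory realizations); no
expected-risk integrals or convergence machinery are implemented. The
prior is metadata interpreted by solvers that understand it: a
uniform-box prior supplies grid-search bounds, a point-mass prior pins a
parameter, and the default improper prior `P(p) = 1` imposes nothing.

Three algebraic operations make morphisms compositional:

* **Composition** `F2(F1(x; p1); p2)`. *Sequential* fitting fits the
  inner morphism first and the outer morphism on transformed data — this
  is what the full workflow uses, mirroring the practice of optimizing
  each stage independently. *Joint* fitting minimizes the outer risk over
  the product of the declared parameter grids. Grid search is this
  package's choice for the joint mode: no solver is canonical for the
  general non-convex joint problem, and the flagship workflow never needs
  one because its stages are fitted sequentially.
* **Direct sum**: for two morphisms with a shared output space and a
  closed operation `⊕`, the sum acts as `F1(x1) ⊕ F2(x2)` with risk
  `a·R̄1 + b·R̄2`. Because the risk decomposes, fitting the sum *is*
  fitting the members independently; the tests verify the equality to
  1e-8 on orthogonal least-squares designs, where the full normal
  equations provably split into per-column problems.
* **Collections** support evaluation and model selection; `select_best`
  breaks ties toward the lowest (1-based) index.

Concrete morphisms shipped: one-hot encoding, standardization
`(x − c) diag(s)^{-1}` with the Gaussian-model KL divergence to `N(0, I)`
as its risk (closed-form optimum: column means and sample standard
deviations), PCA with orthonormal loadings, least-squares regression,
binary classifiers, resamplers, and the decision threshold.

## 2. The Mapper partition

Mapper approximates the Reeb graph of the data under a *filtration*
`A : X → R`: cover the range of `A` with `k` intervals of uniform length
`a_I = range / (k − (k−1)o)` overlapping by `o · a_I`, cluster each
interval preimage, and connect clusters sharing samples.

Numerical conventions, chosen once and tested:

* **Closed intervals.** The textbook recipe says open intervals, but open
  boundaries drop the extreme points; every practical implementation uses
  closed membership, and so does this one. The first and last endpoints
  are pinned to the exact min/max so the pre-pruning cover is total.
* **Filtration** defaults to the first principal component of the
  standardized encoded matrix, with the sign fixed so the
  largest-magnitude loading is positive (reproducibility without a seed).
  Coordinate filtrations and arbitrary functions are accepted.
* **Clustering** defaults to k-medoids under the Gower metric, because
  k-means is incompatible with a non-Euclidean dissimilarity; a
  Euclidean k-means mode on the encoded matrix is provided for literal
  conformance with the "k-means with b clusters" recipe. Medoid seeding
  is deterministic (farthest-point from the lowest index), so graphs are
  reproducible without randomness.
* **`b` is an upper bound, not an exact count.** After the k-medoids
  partition, clusters whose minimum cross-distance lies within the
  preimage's within-cluster nearest-neighbor resolution are merged. This
  implements "at most `b` clusters": forcing exactly `b` clusters would
  cut connected point clouds in half — on a circle under a height
  filtration it provably severs the apex and the graph can never contain
  a cycle, contradicting the Reeb graph it is meant to approximate. With
  the merge rule the geometry suite recovers a cycle from a noisy circle,
  two components from separated blobs, and a path from uniform 1-D data.
* **Pruning before edges.** Nodes with fewer than `min_node_size`
  (default 40) members are dropped *before* edge construction, so edges
  never reference removed nodes. The ordering is unspecified in the
  source recipe; this choice keeps the graph self-consistent.
* **New points** are assigned by filtration value to their covering
  intervals (out-of-range values clamp to the nearest interval), then to
  the nearest retained node per interval under the training-frozen
  distance, keeping at most two nodes. If no containing interval has a
  retained node, the globally nearest node is used.

The Mapper morphism's declared risk is the exact graph edit distance
(node insert/delete/substitute, edge insert/delete; unit costs, free
substitution of unlabeled nodes), computed by exhaustive assignment
search for graphs of at most 8 nodes. In practice no "true" Reeb graph is
available for tabular cohorts, so — as in the source protocol — the
Mapper parameters are actually selected by downstream cross-validated
AUC, and GED is exposed as a graph-comparison utility.

## 3. The ensemble workflow

`fit_workflow` implements `ML3 ∘ ML2 ∘ ML1 ∘ ML0`:

1. one-hot encode (full indicator blocks, no reference level dropped —
   downstream models are regularized or tree-based, so collinearity is
   tolerable; unseen levels at prediction time encode to zero blocks with
   a warning);
2. grid-search the Mapper parameters (defaults `k` in 5–20, `o` in
   0.2–0.6, `b` in 5–30), scoring each grid point by the unweighted mean
   of its node models' cross-validated hold-out AUCs, first maximum wins
   (`k` varies fastest);
3. per retained node, tune and fit a classifier pipeline on that node's
   members only: optional PCA (fitted once per node), optional resampler
   applied to *training folds only* — validation folds are never
   resampled, a property the test suite asserts with a spy sampler —
   and a classifier chosen by stratified 10-fold CV maximizing AUC
   (folds shrink with a message when a node is small; single-class nodes
   get a constant-prior predictor);
4. fit the decision threshold on the *pooled* CV hold-out scores of the
   winning configuration (pooling across nodes rather than per-node: the
   ensemble emits one probability stream, so one threshold; a sample
   assigned to two nodes contributes two pooled scores).

Prediction assigns each point to at most two nodes, computes convex
weights (`closest`, `equal`, `inverse_distance` with ε = 1e-9,
`auc_proportional` as `AUC_i/(AUC_i + AUC_j)`; the fifth option of
training the weights inside CV is an explicit unimplemented stub), and
returns the weighted node probability — a convex combination, hence
bounded by the node outputs. Thresholding is boundary-inclusive:
probability exactly at `T` predicts 1.

With Mapper disabled the workflow collapses to one global pipeline, and a
degenerate configuration (`k = 1, o = 0, b = 1, min_node_size = 1`)
reproduces the global pipeline's predictions exactly — a correctness
anchor in the acceptance suite.

### Classifier implementations

The runtime environment provides no standalone SVM/tree packages, so the
wrappers are compact native implementations: logistic regression via
`stats::glm` (ridge via glmnet when a λ grid is supplied), a soft-margin
linear SVM solved as a dual QP (`quadprog`) with margins calibrated
through a logistic link (the ensemble needs probabilities in [0, 1]), a
bagged-CART random forest (Gini splits, `mtry = √m`), and AdaBoost over
decision stumps with `plogis(2F)` probabilities. They are intentionally
modest; the morphism contract, not the classifier internals, is the
package's subject.

### Resamplers

SMOTE interpolates uniformly between a minority point and one of its k
nearest minority neighbors, in the encoded Euclidean space (plain
interpolation; categorical-aware variants are out of scope because
resampling happens after encoding). The ROSE-style sampler is a generic
class-balanced smoothed bootstrap with per-feature Silverman bandwidths
scaled by `h_scale`; `h_scale = 0` degenerates to a plain balanced
bootstrap. It is not a bug-compatible clone of any particular package.

## 4. What the synthetic cohort emulates

`generate_mixed_imbalanced` produces the regime the workflow targets,
with defaults fixed once to mirror a readmission-style cohort:

* `n = 776`, `minority_frac = 0.173` (the 134-of-776 anchor);
* mixed features: 6 numeric, 3 categorical (3/2/4 levels);
* two latent groups. The *structural* half of the numeric features is
  shifted by ±3 noise-SD units per group along a common direction
  (`group_sep = 6` between centers), and categorical level probabilities
  are group-dependent. This deliberately places the groups along the
  leading principal direction, so the PC1 filtration separates them —
  the mechanism the ensemble hypothesizes, made literal;
* the *effect* half of the numeric features carries logistic coefficients
  of magnitude ≈ 1 whose signs flip between groups (`effect_flip =
  (+1, −1)`), so a global model sees cancelling effects;
* the intercept is calibrated by bisection (tolerance 1e-4 in
  probability) so the mean model probability equals the target
  prevalence — chosen over rejection sampling for determinism and speed.
  An option draws an exact number of positives (weighted sampling without
  replacement) for arithmetic checks that need exactly 134 events.

What it does **not** emulate: real covariate distributions (the clinical
tables describing the private cohort are descriptive only), missing data,
measurement error, temporal drift, or label noise. A green benefit test
therefore establishes that the pipeline exploits planted sign-flipped
group structure — not that it improves any particular clinical dataset.

The auxiliary generators are a noisy circle (Mapper geometry) and
orthogonal regression designs via QR (the direct-sum decomposition
fixture), both pure functions of their seed.

## 5. Evaluation protocol

`holdout_splits` draws stratified 80/20 splits with the test size exactly
`floor(0.2 n)` apportioned across classes by largest remainder — an
n = 776 cohort always splits 621/155, and stratification is used because
unstratified splits of a 17% minority occasionally starve a test fold.
AUC is the Mann-Whitney rank statistic with midranks for ties (checked
against all-pairs concordance on hundreds of random fixtures); standard
deviations use the n−1 denominator; a single run reports sd 0 with a
warning. `compare_workflows` reuses one set of split indices across all
configurations (paired comparison — lower-variance contrasts; whether
the original protocol shared splits across rows is unstated, this is the
package's choice).

## 6. Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| `k` (intervals) | grid 5–20 | more intervals = finer, smaller nodes |
| `o` (overlap) | grid 0.2–0.6 | more overlap = more shared samples, denser graphs; unit fraction of interval length |
| `b` (clusters/preimage) | grid 5–30 | upper bound; gap-merge keeps connected clouds whole |
| `min_node_size` | 40 | prunes outlier nodes; lower it for small cohorts or every cluster may vanish |
| `cv_folds` | 10 | shrinks automatically inside small nodes |
| `weights$scheme` | equal | over at most 2 nodes; `auc_proportional` needs node CV AUCs |
| threshold criterion | Youden J | scanned over observed score midpoints, ties to the smallest T |

## 7. Known limitations

* Exact GED is exponential; graphs beyond 8 nodes require the greedy
  `approx = TRUE` upper bound.
* Joint composition fitting is grid-search only.
* Binary outcomes only; no multi-class or survival endpoints.
* The full default Mapper grid (480 points, each with per-node CV) is
  expensive; tests and examples use fixed parameters or small grids, and
  the stochastic acceptance check fixes `(k, o, b) = (4, 0.4, 2)`.
* Inverse-distance weighting is defined for the 1–2 node assignments the
  workflow produces, not for arbitrary node sets.
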