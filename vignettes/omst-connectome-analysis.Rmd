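---
title: "Methods: OMST-filtered connectome analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OMST-filtered connectome analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(omstnet)
```

This vignette documents the models and procedures implemented in
`omstnet`, the parameters that matter, the design choices made where the
methodology was genuinely open, and what the synthetic-data tests do and
do not establish about real data.

## The analysis model

The pipeline treats a subject's resting-state recording as a set of
regional time courses and asks whether graph-theoretical summaries of the
implied functional network covary with a standardized general-intelligence
score *g* across subjects.

**Connectivity.** Edge weights are pairwise partial correlations: each
node series is residualized on the nuisance (white-matter/ventricle-like)
confound series plus an intercept, and entry (i, j) is the Pearson
correlation of the residualized series. Controls are the confounds only,
not the remaining nodes — full-order partialing over hundreds of nodes
would demand more volumes than nodes and is not what the wording
"controlling confound time courses" describes. Negative correlations are
then replaced by zero and the surviving weights are Fisher z-transformed
(variance stabilization). The order clip-then-z follows the order in
which the steps are described for this analysis; both the order and the
per-session standardization applied before concatenating sessions are
config-exposed because the original convention is not stated. Perfect
correlations are capped at 1 − 10⁻⁷ before artanh so all edge weights
stay finite, which downstream spanning-tree filtering requires.

**OMST pruning.** Thresholding by orthogonal minimum spanning trees
removes spurious weak edges without an arbitrary cutoff while
guaranteeing a connected result. With distances d = 1/w (strong edges are
short), Kruskal's algorithm extracts an MST; its n − 1 edges are zeroed
out and the next MST is extracted from the remainder, so successive trees
are edge-disjoint ("orthogonal"). After each round m the aggregate union
U_m is scored by *Global Cost Efficiency*

GCE(m) = E(U_m) / E(full graph) − cost(m),

where cost(m) is the ratio of selected to total edge weight. The
aggregate maximizing GCE is returned. Two details are open in the source
methodology and were decided here: efficiency is normalized by the full
graph's efficiency (otherwise "efficiency minus cost" subtracts
quantities on different scales), and the search returns the global argmax
over all rounds (up to `max_trees`, default 50) rather than the first
local maximum, which makes the procedure deterministic. Kruskal ties are
broken by (distance, smaller node index, larger node index).

**Graph metrics.** Shortest paths run on d = 1/w via Dijkstra from every
source (compiled; for the dense, modest-size graphs involved a linear
minimum selection outperforms a heap). Global efficiency is the mean
nodal efficiency, E_i = Σ_{j≠i}(d_ij)⁻¹/(n−1). The weighted clustering
coefficient uses the geometric-mean (Onnela-style) triangle intensity on
weights normalized by the global maximum — the simplest reading of
"normalized to be between 0 and 1" — with C_i = 2t_i/(k_i(k_i−1)) and
C_i = 0 where a node has fewer than two neighbors. Small-world propensity
compares observed clustering and characteristic path length with a
ring-lattice null (observed weights, sorted descending, assigned to node
pairs by increasing ring distance) and with random nulls (same edge
count, uniform placement, permuted weights; disconnected draws rejected,
cap 100 attempts; statistics averaged over `n_null`, default 10). Both
Δ_C and Δ_L are clamped to [0, 1] and φ = 1 − √((Δ_C² + Δ_L²)/2). How the
original implementation handled disconnected nulls or how many null
realizations it used is not stated; these defaults are documented
choices, config-exposed and seeded.

**Association battery.** *g* and the global metrics are winsorized at
mean ± 3 IQR (linear-interpolation quantiles). Partial correlations
control the fixed covariate set age, sex, age×sex, age², age²×sex,
handedness, total brain volume, head motion; age is mean-centered before
powers and interactions are formed to limit collinearity, and the
design's condition number is attached for inspection. The two-sided test
uses t = r√(df/(1−r²)) with df = n − 2 − (number of controls); the
methodology is silent on the df convention, so the control count is
subtracted and documented. Holm's correction is applied across the global
metrics tested within one data set (the per-row structure of the
published association tables); correcting across the whole correlation
matrix, as the convenience function used originally does, is exposed as
an alternative by passing a different metric set. Nodal metrics enter the
elastic net standardized and residualized but unwinsorized, matching the
described procedure.

**Elastic net and cross-sample prediction.** `elastic_net_select()`
drives `glmnet::cv.glmnet` — the same engine the original analysis
used — with α = 0.5, 100 log-spaced penalties from
λ_max = max|Xᵀy|/(nα) down to 10⁻⁴λ_max, and seeded 10-fold assignment.
The penalty is chosen by the CV-MSE minimizer by default
(`lambda_rule = "min"`); the one-standard-error rule is available. The
two rules trade off differently: under pure-noise data the minimizer
occasionally admits a handful of spurious nodes (its cross-validation
curve is flat and noisy near the top of the path), while the
one-standard-error rule keeps the null support near-empty but often
returns an empty model on weak diffuse signals. The tests assert null
sparsity under the conservative rule and sensitivity under the default.
Reported effect sizes are the coefficients at the selected penalty, not
refitted OLS betas. Cross-sample prediction regresses residualized *g*
on the residualized selected metrics in the target sample (controls
removed first, as in selection; fitting controls jointly is available
via `include_controls = TRUE`) and reports R² with the overall F-test,
thresholded at 0.05/m with m = 16 for the published 4 × 4 grid
(source × target including self-prediction, per that grid's caption).

**Reliability.** ICC(3,1) is the two-way mixed-effects consistency form
(BMS − EMS)/(BMS + (k−1)·EMS) computed from the subjects × sessions
ANOVA decomposition. Split-half reliability splits every subject's
volumes into odd and even subsets, repeats the entire
connectivity → OMST → metrics pipeline on each half, correlates the
half-derived metrics across subjects, and applies Spearman–Brown,
SB = 2r/(1 + r).

## The synthetic cohort generator

The generator exists so that every downstream stage can be tested against
known truth; its defaults are the study conditions of the test suite.

A **ground truth network** is a weighted stochastic block model:
`n_modules` communities with within-module weights centered at 0.5 and
between-module weights at 0.2 (correlation scale, Gaussian jitter
SD 0.05), plus long-range rewiring (probability 0.05) that swaps
within-module weights with between-module pairs, giving the graph a
small-world flavour. If the block structure leaves components
disconnected (between weight 0), single bridge edges are added. The
default node count of 376 mirrors a whole-brain parcellation with 360
cortical and 16 subcortical areas; tests and examples use 12–40 nodes so
that whole cohorts run in seconds.

A **cohort** draws g ~ N(0, 1) and a latent driver
d = true_r · g + √(1 − true_r²) · ε, so cor(g, d) = true_r in
expectation. The driver modulates each subject's copy of the ground
truth:

* *Efficiency targets* scale the relevant weights by (1 + 0.2·d). On
  inverse-weight distances, global efficiency is exactly linear in a
  uniform scale while the max-normalized clustering coefficient is
  exactly invariant to it, so the effect stays confined by construction.
* *Clustering targets* blend the relevant weights toward the graph
  maximum, w′ = w + s(max − w), which compresses weight ratios and raises
  the geometric-mean triangle intensity. Two corrections confine and
  linearize the effect. First, the blended matrix is rescaled on the
  Fisher-z scale by γ = E₀ᵖ/Eᵖ, pinning the OMST-pruned efficiency at the
  ground-truth value: a uniform z-rescale is exactly invisible both to
  the OMST selection (GCE is scale-free) and to max-normalized
  clustering, while pruned efficiency scales linearly, so the correction
  is exact on noise-free networks. Without it the blend leaks into
  pruned efficiency through the selection feedback (naive variants
  showed spurious pruned-efficiency correlations of 0.15–0.5 with the
  driver). Second, the driver is reparametrized through the inverse of
  the noise-free composed clustering response (evaluated on a grid of
  driver values per cohort), so the planted response is linear and
  Pearson recovery is not attenuated by curvature. A uniform log-normal
  amplitude factor (SD 0.03), also invisible to clustering, restores
  natural driver-independent variation in pruned efficiency.

Per-subject measurement noise is a multiplicative log-normal jitter on
every edge (SD 0.005 by default). With these conditions the mean
recovered g–clustering correlation across replicate cohorts deviates
from the planted value by less than 0.05 for true_r ∈ {0, 0.2, 0.4}, the
contract the property tests assert.

**Demographics** are conveniences, not estimates of any real sample: age
truncated-normal around 28 (18–75), balanced sex, ~85% right-handers with
LQ clustered near 100, total brain volume ~N(1.2·10⁶, 10⁵), and a head
motion covariate that is negatively correlated with g (−0.2 by default),
emulating the motion–cognition association reported in large samples,
with motion scaling the white noise added to simulated series.

**BOLD-like series** are zero-mean multivariate Gaussian draws whose
correlation target is the subject network with unit diagonal, repaired to
the nearest positive-definite correlation matrix (Higham iteration via
`Matrix::nearPD`, tolerance 10⁻⁸). Confounds are AR(1) signals
(autoregression 0.3) added to every node with loadings U(0.1, 0.3) and
returned as the nuisance regressors, which makes confound control
testable: controlled and uncontrolled matrices must differ. No
hemodynamic response, spatial structure, temporal autocorrelation of the
node signals themselves, scanner drift or multi-site effects are
simulated — so passing tests demonstrate the correctness of the
statistical machinery under the stated generative model, not robustness
to the full physics of fMRI.

## Numerical choices and degenerate inputs

* All randomness flows from one integer master seed through a documented
  splitting scheme (stream k is (seed + k·10007) mod 2³¹−1); identical
  configurations reproduce reports bit for bit.
* Matrices are validated for symmetry within 10⁻¹², zero diagonal and
  nonnegativity at every module boundary; TSV round trips are exact to
  10⁻¹² and asymmetries above 10⁻⁸ are rejected at read time.
* All-zero matrices yield zero clustering without error; disconnected
  inputs to path-based operations raise typed errors naming the
  condition; constant node series and rank-deficient covariate designs
  are rejected with the offending columns named.
* The elastic net standardizes residualized columns; zero-variance
  columns become all-zero predictors rather than NaN.
* Winsorization with zero IQR returns the input unchanged.

## Problem sizes in the test suite

The suite validates oracle equivalence (Floyd–Warshall, brute-force
clustering, exhaustive spanning-tree enumeration, igraph cross-checks) on
graphs of up to 15 nodes; the OMST contract on 50 random 40-node
matrices; statistical calibration with 2000 null replicates at n = 300
and elastic-net sensitivity over 20 seeds at n = 500, p = 100; and
end-to-end recovery on two-cohort studies of 300 subjects with 40-node
networks over 10 replicate seeds. These sizes keep the full suite within
a coffee break on one CPU while leaving every statistical check
well-powered.

## Known limitations

* OMST's GCE curve can have near-tied adjacent rounds; tiny estimation
  noise then flips the selected round and produces discrete jumps in
  pruned-network metrics. This is inherent to argmax selection and
  mirrors the moderate test–retest reliability the filtering approach
  shows in practice; it is why split-half convergence is demonstrated on
  panels of a dozen subjects rather than a handful.
* The clustering-effect calibration is exact on noise-free networks;
  edge jitter re-introduces a small interaction term, which is why the
  recovery contract is stated as a tolerance (±0.05 on the mean) rather
  than an identity.
* Partial correlations control measured confound series only; unmodeled
  confounds propagate into edge weights exactly as they would in a real
  analysis.
* The generator's demographic distributions are conveniences; nothing in
  the package estimates the joint covariate distribution of any real
  sample.
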