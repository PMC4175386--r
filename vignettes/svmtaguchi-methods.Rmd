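---
title: "Methods: SVM-RFE ranking, Taguchi tuning and multiclass SVM evaluation"
author: "svmtaguchi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SVM-RFE ranking, Taguchi tuning and multiclass SVM evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmtaguchi)
```

This vignette documents the models and procedures the package
implements, the choices made where the methodology leaves room, and
what the synthetic test fixtures do and do not demonstrate.

## The binary soft-margin SVM

The elementary learner is the two-class soft-margin SVM. Given training
pairs $(x_i, y_i)$ with $y_i \in \{-1,+1\}$, the primal problem
minimises $\tfrac12\|w\|^2 + C\sum_i \xi_i$ subject to
$y_i(w \cdot x_i + b) \ge 1 - \xi_i$, $\xi_i \ge 0$; the package works
with its kernelised dual

$$\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j
  y_i y_j K(x_i, x_j), \qquad 0 \le \alpha_i \le C,\quad
  \sum_i \alpha_i y_i = 0,$$

and the decision function $f(x) = \sum_i y_i \alpha_i K(x, x_i) + b$.
Four kernels are provided (`kernel_spec()`): linear, polynomial
$(\gamma x\cdot y + r)^m$, RBF $\exp(-\gamma\|x-y\|^2)$ and sigmoid
$\tanh(\gamma x \cdot y + r)$.

Numerical choices:

* **RBF parameterisation.** The RBF kernel is parameterised directly by
  $\gamma$ rather than a bandwidth $\sigma$ (the two are related by
  $\gamma = 1/2\sigma^2$). Tuning grids with values like
  $\gamma \in [2.4, 12]$ only make sense under the direct-$\gamma$
  convention, which is also libsvm's.
* **Solver.** The dual quadratic program is solved by libsvm through
  `e1071::svm`; correctness is defined by the constraint/objective
  contract, not by the algorithm, and the test suite asserts dual
  feasibility (box and equality constraints) on every trained machine
  and cross-checks the dual objective against an independent solver
  (`kernlab`). The support coefficients, vectors, labels and bias are
  extracted into a plain `binary_svm` object; decision values and
  feature weights are then computed by the package itself. libsvm
  orients its stored coefficients by whichever class appears first in
  the training data, so training normalises the sign so that a positive
  decision value always means class $+1$.
* **Hard margin.** Effectively hard-margin machines are obtained as
  soft margin with $C = 10^6$ rather than a separate code path; the
  blob separability certificate uses exactly this.
* **Polynomial/sigmoid defaults** $r = 0$, $m = 3$ exist for
  completeness; the tuned workflow only exercises the RBF kernel.
* **Default solver tolerance** is $10^{-6}$ — tight, because the
  datasets this package targets are small (hundreds of instances) and a
  sharp dual optimum makes the RFE weight criterion reproducible.

## Multiclass decomposition

`train_multiclass()` supports one-against-all (K machines, prediction
by maximal decision value), one-against-one (all $K(K-1)/2$ pairs,
majority vote) and the decision DAG (same machines, $K-1$ sequential
(first, last) eliminations over a candidate list kept in ascending
class-code order). Tie-breaking is deliberate and deterministic:

* OAA: exact ties go to the lowest class code.
* OAO: tied vote counts are broken by the larger sum of absolute
  decision values over the tied classes' contests, then by the lowest
  code. A pairwise decision value of exactly zero votes for the
  lower-coded class of the pair.
* DAG: a zero decision value keeps the lower-coded class, consistent
  with the other rules.

OAO is the package default: on datasets of this size (well under a
thousand test instances) its error rate is typically the lowest of the
three, and the pairwise machines train on small subsets. The DAG shares
the OAO machines, so its only advantage here is the $K-1$ evaluation
count, which the tests assert.

## SVM-RFE

`svm_rfe()` implements backward elimination with the squared-weight
criterion $c_i = w_i^2$, where $w = \sum_k \alpha_k y_k x_k$ is the
linear decision-function weight vector. Design choices:

* **Linear kernel always.** The expansion above is only the gradient of
  the decision function for the linear kernel, so the ranking machines
  are linear even when the final tuned classifier is RBF. Ranking
  happens once, before parameter tuning — the workflow is rank, then
  tune, then evaluate.
* **Multiclass aggregation.** The binary criterion generalises to K
  classes as the elementwise sum of $w_i^2$ over all OAO machines (the
  standard multiclass-RFE extension); tests verify the aggregate equals
  a brute-force recomputation.
* **One feature per iteration**, no chunked elimination; iteration
  count therefore equals the feature count and the audit trail records
  the criterion vector of every iteration.
* **Ties** (equal criteria, e.g. two all-zero columns) remove the
  lowest-index feature, for determinism.
* **Internal penalty** defaults to $C = 1$; since tuning follows
  ranking, the ranking must not depend on the tuned values. The choice
  is configurable (`rfe_C` in the pipeline config).

An all-zero feature has exactly zero weight in every machine, so it is
eliminated first and its removal provably leaves all subsequent
decision values unchanged — both are asserted in tests.

## Taguchi parameter design

`taguchi_tune()` explores $3 \times 3$ candidate levels of
$(C, \gamma)$ with the nine-run L9(3²) array. With only two three-level
factors the orthogonal array coincides with the full factorial, and the
design is generated directly in A-major run order
$(1,1),(1,2),\dots,(3,3)$ rather than by slicing a four-column L9
table; this keeps run indices aligned with the conventional report
layout.

Each run collects $n$ repeated accuracy observations $y_1..y_n$
(fractions in $(0,1]$) and is summarised by the larger-the-better
signal-to-noise ratio

$$SN_{LTB} = -10\,\log_{10}\!\Big[\frac1n \sum_{i=1}^n
  \frac{1}{y_i^2}\Big] \quad \text{(dB)},$$

which is strictly increasing in every observation (property-tested),
equals $20\log_{10} y$ for constant observations, and penalises
variance across repeats — the reason it is preferred over the plain
mean. Main-effects analysis averages the nine SN values by factor
level; because the design is balanced, the mean of the three level
means equals the grand mean (asserted exactly). The optimum is the
maximal-SN level of each factor, ties to the lowest level index,
decoded through the `factor_levels` configuration.

Repeat observations come from re-randomised stratified CV fold splits
with recorded seeds (`base_seed + repeat - 1`), so the $r$-th repeat of
every run shares its folds and runs differ only in $(C, \gamma)$. The
methodology's wider two-stage search (a coarse grid first, then
narrowed three-level ranges) is intentionally left to the user via the
config: no automatic narrowing rule is imposed.

Comparisons against the bundled reference tables are made at
$|\Delta| \le 1.5\times10^{-4}$: $5\times10^{-5}$ for the 4-d.p.
printed precision of the target plus $10^{-4}$ slack for the rounding
of the printed observations the value is recomputed from.

## Cross-validation

`stratified_kfold()` partitions instances class by class: each class's
indices are shuffled and dealt round-robin from a random starting fold,
so per-class fold counts never differ by more than one and classes
smaller than $k$ appear in exactly their-count folds. $k$ defaults to
10, the conventional choice for datasets of a few hundred instances;
accuracy is instance-weighted (micro) accuracy, and `cross_validate()`
returns the mean over folds (for equal-sized folds this equals pooled
accuracy, which a test verifies). A training split that loses a class
entirely is a hard error naming the fold, rather than a silent skip —
the caller should lower $k$. The run log reports dispersion both over
repeats and over folds, since "± sd" conventions differ between the
two.

## Synthetic fixtures: what they emulate and what they do not

The generators (`synth_multiclass()`, `synth_dermatology_like()`,
`synth_zoo_like()`, `synth_blobs()`, `synth_planted()`) emulate the
*shape* of small UCI benchmarks: exact class counts — including the
severe imbalance of a 4-instance class against a 41-instance one, which
stresses stratified CV — ordinal 0–3 codes obtained by thresholding a
latent Gaussian at $(-1, 0, 1)$, boolean codes by thresholding at 0,
and a planted-informative structure in which selected features carry
class-dependent means whose between-class standard deviation equals
`effect_size` noise-sd units while the rest are pure noise.

They deliberately do **not** reproduce real attribute distributions,
inter-feature correlation (features are independent given the class),
or label noise. Passing tests therefore demonstrate that the
implementation's mechanics are correct under controlled conditions —
ranking recovers planted signal, separable data is classified
perfectly, SN arithmetic matches reference tables — not that any
particular accuracy level will be attained on real clinical data.
Fixture sizes are kept modest (200-instance, 10-feature RFE recovery
over 20 seeds; 45-instance blobs for strategy checks; 358-instance
Dermatology-shaped tables for the worked example) so the full suite
runs in well under a minute.

The blob generator certifies pairwise linear separability by fitting a
near-hard-margin linear machine ($C=10^6$) to every class pair and
requiring zero training errors — a sufficient certificate; on failure
it regenerates with 1.5× the separation, at most five times.

## Data handling choices

* Missing values are handled by listwise deletion only; no imputation.
  The 358-of-366 retention behaviour on Dermatology-style input is the
  reference case.
* Attribute coding defaults to the identity (both emulated schemas are
  already numeric); `encode_features()` exists for generality and
  rejects unmapped observed values loudly.
* No feature standardisation is applied by default. An optional min-max
  rescale (`rescale_unit()`, `rescale: true` in the config) is provided
  because RBF distances depend on raw units, but it is off by default
  to keep the reference behaviour.
* Class codes are 1-based externally; binarisation to $\pm1$ happens at
  training time (lower code of a pair maps to $+1$).
* Non-ordinal columns (such as an age attribute among 0–3 severity
  codes) can be excluded with `exclude_columns`; the package never
  drops a column silently.

## Known limitations

* The RFE criterion is margin-based and linear; strongly correlated
  informative features can share weight and be eliminated earlier than
  univariate screening would suggest. No correlation-bias correction or
  stability selection is attempted.
* The Taguchi main-effects model is additive in the two factors; a
  strong $C\times\gamma$ interaction can make the selected combination
  differ from the full-grid argmax (the tests use additive surfaces,
  where the two provably coincide).
* Exact reproduction of a published feature ranking on the real UCI
  files depends on unstated choices (internal penalty, scaling,
  aggregation); the `replicate-uci` helper therefore reports top-k set
  overlap rather than asserting exact order.
* No probability calibration, no error-correcting output codes, and no
  performance engineering (shrinking, caching) beyond what libsvm
  provides.
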