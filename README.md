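# svmtaguchi

Feature ranking, parameter tuning and multiclass classification with
support vector machines, for small tabular datasets of the kind found
in clinical and biological benchmarks (ordinal symptom severities,
boolean trait tables) where the class variable has more than two
levels and only a subset of the recorded attributes carries signal.

The package implements a three-stage workflow:

1. **SVM-RFE feature ranking.** A linear soft-margin SVM has decision
   function *f(x) = w·x + b* with *w = Σᵢ αᵢ yᵢ xᵢ*. Recursive feature
   elimination retrains the machine on the surviving features, scores
   feature *i* by *cᵢ = wᵢ²*, removes the single feature with the
   smallest criterion, and repeats until none remain — producing a
   complete importance ranking. For K > 2 classes the criterion is the
   elementwise sum of *wᵢ²* over all pairwise (one-against-one) binary
   machines.

2. **Taguchi parameter design for (C, γ).** Instead of a full grid
   search, the soft-margin penalty C and the RBF kernel parameter γ
   (with *K(x, y) = exp(−γ‖x−y‖²)*) are assigned three candidate levels
   each and explored through the nine runs of an L9(3²) orthogonal
   array (here, the full 3×3 factorial). Each run is scored by repeated
   stratified cross-validation and summarised by the larger-the-better
   signal-to-noise ratio

   *SN = −10·log₁₀[(1/n) Σᵢ 1/yᵢ²]*  (dB),

   which rewards both high and consistent accuracy. Main-effects
   analysis (the mean SN of each factor level) selects the winning
   level of each factor.

3. **Multiclass SVM classification.** One-against-all (argmax of
   decision values), one-against-one (majority vote over K(K−1)/2
   pairwise machines; the default) and the decision directed acyclic
   graph (K−1 sequential pairwise eliminations), all built on binary
   soft-margin kernel SVMs, evaluated by stratified repeated k-fold
   cross-validation.

Data enters as delimited text in the UCI `.data` dialect (`"?"` for
missing fields); preprocessing is listwise deletion of incomplete
instances plus optional attribute recoding. Deterministic synthetic
generators emulate the Dermatology-style (6 classes, 0–3 ordinal
severities) and Zoo-style (7 classes, boolean traits) schemas for
testing without any download.

## Worked example

```r
library(svmtaguchi)

# 358 instances, 6 classes (counts 111/71/60/48/48/20), 33 ordinal features
d <- synth_dermatology_like(seed = 1)

# Stage 1: rank all features
ranking <- svm_rfe(d$table, d$labels)

# Stage 2: tune (C, gamma) on the L9 design, 3 repeats of 5-fold CV
ex <- taguchi_tune(d$table, d$labels,
                   levels_A = factor_levels("A(C)", c(10, 50, 100)),
                   levels_B = factor_levels("B(gamma)", c(0.01, 0.05, 0.2)),
                   k = 5, n_repeats = 3, base_seed = 1)
print(ex)
#> Main effects (mean SN per level):
#>   A: -3.4413  -3.4413  -3.4413  diff=0.0000  best level=1
#>   B: -0.0975  -0.0561  -10.1704  diff=10.1143  best level=2
#>   optimum: C=10, gamma=0.05 (A1B2)

# Stage 3: fit and evaluate the tuned classifier
fit <- msvm(d$table, d$labels, C = ex$optimum$C, gamma = ex$optimum$gamma)
obs <- repeated_cv(d$table, d$labels,
                   svm_config(kernel_spec("rbf", gamma = ex$optimum$gamma),
                              C = ex$optimum$C),
                   "OAO", k = 5, n_repeats = 5, base_seed = 1)
sprintf("CV accuracy %.4f +/- %.4f (SN %.4f dB)",
        mean(obs), sd(obs), sn_ltb(obs))
#> "CV accuracy 0.9939 +/- 0.0012 (SN -0.0529 dB)"
```

On this synthetic table the penalty C is inert (the classes are
separable at every level, so all three A-level SN means coincide and
the tie resolves to level 1) while γ dominates: the level-3 value 0.2
over-localises the RBF kernel and collapses accuracy to the majority
class, which the SN main effect flags with a 10 dB range. The tuned
classifier reaches 99.4% repeated-CV accuracy.

The same stages run from a shell via the bundled CLI
(`inst/scripts/svmtaguchi-cli.R`) with subcommands `rank`, `tune`,
`evaluate`, `pipeline` and `replicate-uci` over a YAML/JSON config; see
`?read_pipeline_config`.

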