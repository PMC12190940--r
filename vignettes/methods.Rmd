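---
title: "Methods: explainable fuzzy classification of preeclampsia risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable fuzzy classification of preeclampsia risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzmoefs)
```

## The modelling problem

Preeclampsia is a hypertensive pregnancy syndrome with onset after 20
gestational weeks; screening cohorts are strongly imbalanced (here 502
controls against 72 cases) and the clinical cost of a false negative far
exceeds that of a false positive. The package therefore builds a fuzzy
rule-based classifier whose reduced rule set a clinician can read, whose
inference abstains when no rule covers a patient, and whose tuning
emphasises sensitivity.

Five third-trimester variables common to heterogeneous public cohorts are
used: mean arterial pressure (MAP, mmHg), body mass index (BMI, kg/m²),
maternal age (years), parity (prior births) and gestational age (GA,
weeks). MAP and BMI are recomputed from raw readings where necessary
(`mean_arterial_pressure()`, `body_mass_index()`), so multi-source tables
are comparable before merging on the common variables.

## Strong triangular partitions

A variable's partition is defined entirely by its ordered peak vector
(*anchors*): set *i* peaks at anchor *i* with support ending at the
neighbouring peaks. Consequences that the code relies on:

* memberships sum to one everywhere between the outer anchors (tested at
  1000 random points per partition, tolerance 1e-9);
* the four-parameter trapezoid translation `(p1 = p2 = b_i,
  left_width = b_i − b_{i−1}, right_width = b_{i+1} − b_i)` is exactly
  membership-preserving, which `to_trapezoid()` reproduces against the
  published MAP table;
* boundary sets are *shouldered* (membership 1 beyond the outer peaks), so
  clinical inputs outside the training range still receive full coverage.
  This matches the zero widths the published trapezoid table assigns to
  its boundary sets.

Two constructors are provided. `uniform_strong_partition()` spaces anchors
evenly — the initial setting of the reference pipeline.
`supervised_fuzzy_discretization()` inserts anchors greedily where they
most increase the fuzzy information gain of the whole partition. An
interval-local two-set formulation was tried first and discarded: its gain
was maximized by re-inserting near-duplicate anchors at an already-chosen
class boundary, producing degenerate partitions. The whole-partition
marginal-gain form keeps the same stopping controls (`min_gain`,
`min_impurity` in bits, and the `threshold + 2` set cap) without that
artifact, and gain ties break deterministically toward the leftmost
candidate midpoint.

## Fuzzy decision tree

The tree maximizes fuzzy information gain — parent fuzzy entropy minus the
cardinality-weighted child entropies, where cardinalities are soft counts
`|G| = Σ_i μ_G(x_i)`. Leaves always store the fuzzy class *distribution*;
crisp labels would discard exactly the uncertainty the output layer needs.

**Choice of t-norm.** The conjunction combining parent and set
memberships defaults to *product* for tree induction. Under a strong
partition the product t-norm conserves fuzzy mass exactly
(`Σ_j w·μ_j = w`), so child weights are a true decomposition of the
parent. The minimum t-norm violates this: a record with parent degree 0.3
and set degrees (0.5, 0.5) contributes 0.6 of child mass, inflating child
cardinalities wherever memberships overlap. Empirically that bias steers
splits toward near-crisp features (parity) and starves the rule base
(~19 rules instead of ~145 on the default synthetic cohort). Minimum
remains available by configuration and is the default for *rule
activation* in the inference engine, where no conservation argument
applies and minimum is the conventional conjunction.

Stopping rules (defaults = the reference study's selected configuration):
depth cap β = 15; minimum node fuzzy cardinality λ = 4 — compared against
the soft count, since nodes hold partial memberships; minimum split gain
0.001 with an absolute floor ε = 1e-6 (the configurable threshold and the
floor are exposed separately because the two cutoffs are described
independently; the effective threshold is their maximum); purity stop
`max_prop = 1`. Gain ties break by feature declaration order, then
partition-set order, so builds are deterministic. Child memberships below
1e-12 are dropped from the child's index — a pure sparsity cutoff far
below every tolerance used.

In the crisp limit (indicator memberships) the whole construction
coincides with a textbook multiway ID3 tree, which the test suite checks
against an independent oracle implementation on ≤200-row fixtures.

## Rule weights and inference

The rule weight has no published formula; the default is the rule's
confidence (the maximum of its class distribution), with `RW ≡ 1`
available. Inference is additive — class score `k` is
`Σ_m activation_m · RW_m · dist_m[k]` — rather than winner-takes-all,
so partial evidence from several rules accumulates. Decisions:

* all activations zero → **ABSTAIN** (the conservative clinical choice;
  missing feature values zero the activations of rules that test them);
* an exact class-score tie → **ABSTAIN**, never a silent pick;
* otherwise the argmax class, and a crisp risk score from defuzzification.

The output universe is a PE-risk score on [0, 1] with class output sets
defaulting to triangles peaking at 0 (No-PE) and 1 (PE) whose supports
cover the interval; the published illustration shows, but does not
parameterize, these sets, so the simplest full-coverage pair was fixed.
Class scores are normalized to proportions before clipping so the curve
heights stay in [0, 1]. Aggregation is fuzzy OR (max) by default with
bounded sum available; defuzzification is trapezoidal-quadrature centroid
or the smallest grid point splitting the area in half (bisector), on a
≥1001-point grid (verified against a 10^5-point oracle to 1e-3). The
decision threshold on the crisp score is 0.5; on the published six-rule
set the crisp decision and the score argmax agree whenever the normalized
score margin exceeds 0.05.

## Multi-objective rule reduction

The reduction stage selects rule *subsets*, encoded as inclusion masks —
the only reading consistent with Pareto fronts over whole rule bases (the
single-rule-per-chromosome encoding cited as background is not used). The
optimizer is NSGA-II-style: non-dominated sorting with crowding distances,
binary tournament selection, uniform crossover (rate 0.9), per-bit flip
mutation (rate 1/M), repair of empty masks, elitist environmental
selection. Defaults: population 64, 50 generations, seed 123 (the
reference study's fixed seed).

The initial population spans a *density gradient* of masks (inclusion
probabilities 0.05–0.95 plus the full mask). With uniform Bernoulli(0.5)
initialization the final front covered only a narrow high-complexity band;
the gradient makes the compact end of the front reachable within the
default budget, mirroring the published reduction of ~80 rules to single
digits.

The performance objective defaults to the mean of sensitivity and
specificity ("balanced"), the fitness the method describes; with a 7:1
class imbalance a plain-accuracy objective collapses onto the majority
class. Accuracy remains available, and `evaluate_solution()` itself
defaults to accuracy for neutral post-hoc evaluation. Abstentions count as
errors inside the objective. From the front, *first* is the
highest-performance solution, *last* the lowest-TRL one, and *median* the
middle of the performance-sorted front.

## Imputation

Missing cells are completed by EM for probabilistic PCA, `Y = mu + W Z + E`
with isotropic noise, treating missing entries as latent. The E-step
computes exact joint posterior moments per missingness pattern; the M-step
is an exact per-feature regression on the expected sufficient statistics,
so the *observed-data log-likelihood* is provably non-decreasing — that is
the quantity tracked and tested (the expected complete-data objective is
not monotone in general). With shrinkage enabled, an
automatic-relevance-determination prior on the columns of W turns the
M-step into a MAP update (Bayesian PCA-style), letting surplus components
decay; monotonicity is then not guaranteed and the test runs with
shrinkage off. Defaults: components = features − 1, shrinkage on,
seed-fixed initialization from feature means plus small Gaussian noise,
noise variance floored at 1e-10 so noiseless low-rank inputs converge to
exact completion. Imputed values are posterior means, clipped to the
declared clinical domains; observed cells are never touched. Imputation is
intended per source cohort before merging, matching the reference
pipeline's per-dataset treatment; single posterior-mean completion only —
no multiple imputation.

## Synthetic cohorts: what they are and are not

`pe_cohort_spec()` encodes the published class-conditional marginals of
the combined 574-record cohort (e.g. No-PE MAP 86.21 ± 18.70 mmHg vs PE
MAP 113.18 ± 11.48 mmHg) with the published per-class ranges as truncation
bounds; draws are independent truncated normals per feature (inverse-CDF,
so seed-deterministic), parity rounded to a positive integer, missingness
injected MCAR. Only marginals are published, so **no covariance is
modelled** and inter-source heterogeneity is absent. A green end-to-end
test therefore establishes that the pipeline recovers structure of this
stated world — it does not reproduce the real-data headline metrics, which
depend on the downloadable merged cohort. The generator's sampling target
is the *truncated*-normal mean (the closed form is the test oracle);
truncation shifts some stated means by a few percent, most visibly PE age.

## Degenerate inputs and numerical conventions

* `0 log 0 ≡ 0` in every entropy; zero-cardinality nodes have entropy 0
  (with a warning).
* Constant features discretize to a degenerate two-set partition with a
  warning; single-class labels insert no anchors.
* Zero-area defuzzification is undefined and propagates as abstention.
* Metric denominators of zero yield `NA`, never NaN; the error rate
  offers both the predicted-cases and all-cases denominators because the
  published validation table mixes the two conventions.
* Abstentions folded into errors (`count_as_error`) are reassigned to the
  FN/FP cell matching their true class and not tallied separately,
  keeping the all-cases denominator free of double counting.

## Known limitations

* The reference pipeline's pre-clustering partition initialization
  ("long-distance" centroid selection) has no published formula and is
  not implemented; uniform and supervised constructors are the two
  options.
* Rule-weight learning and membership-function tuning during evolution
  (shift/delete/split moves) are out of scope; the GA reduces rules only.
* Duplicate patients across source cohorts are kept; the merge has no
  deduplication rule to apply.
* The external-validation and SHAP-comparison analyses of the reference
  study require data and tooling outside this package.
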