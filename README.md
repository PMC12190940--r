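# fuzzmoefs

Explainable fuzzy rule-based classification of clinical risk, with
third-trimester preeclampsia (PE) screening as the running example.

Clinical prediction models for obstetric care need more than accuracy: a
clinician has to see *why* a patient was flagged. `fuzzmoefs` builds
classifiers whose entire decision logic is a handful of linguistic IF–THEN
rules over routine prenatal variables — mean arterial pressure (MAP), body
mass index (BMI), maternal age, parity and gestational age (GA) — such as

```
If MAP is H and GA is L, then p is 1[0.03 0.97]
```

and whose inference can abstain rather than guess when no rule covers a
patient.

## The method

1. **Fuzzification.** Each variable *X_f* gets a *strong triangular
   partition* `P_f = {A_f,1, …, A_f,T}`: overlapping triangles
   `(a, b, c)` whose peaks coincide with their neighbours' support
   boundaries, so membership degrees sum to one everywhere. Partitions are
   built uniformly over the observed range or by supervised gain-driven
   discretization; boundary sets are shouldered so any real input is
   covered.
2. **Rule induction.** A fuzzy decision tree splits on the feature whose
   partition maximizes the *fuzzy information gain*
   `FGain = FEnt(G) − Σ_j (|G_j| / |G|) FEnt(G_j)`, where `|G| = Σ_i μ_G(x_i)`
   is the fuzzy cardinality (soft count) of the node and `FEnt` is Shannon
   entropy of the normalized per-class cardinalities. Every root-to-leaf
   path becomes one rule; leaves keep full class *distributions*, never
   crisp labels.
3. **Multi-objective reduction.** An NSGA-II-style genetic algorithm over
   rule-inclusion masks maximizes classification performance (accuracy, or
   the mean of sensitivity and specificity) while minimizing the *total
   rule length* (TRL, the number of antecedent conditions). The Pareto
   front offers a *first* (most accurate), *median* (balanced) and *last*
   (most compact) rule base.
4. **Inference.** Mamdani-style additive inference: each rule contributes
   `activation × weight × distribution` to the class scores; the class
   output sets on the PE-risk universe [0, 1] are clipped and aggregated,
   and centroid or bisector defuzzification yields a crisp risk score
   compared against a 0.5 threshold. Zero activation (or an exact tie)
   means **ABSTAIN**.
5. **Preprocessing.** Missing values are completed by
   expectation–maximization probabilistic PCA (`Y = WZ + E`) with optional
   Bayesian (automatic-relevance) shrinkage; merged multi-source cohorts
   are restricted to their common variables, with MAP and BMI recomputed
   as `MAP = SYS/3 + 2·DIA/3` and `BMI = weight/height²`.

A synthetic-cohort generator reproduces the published class-conditional
summary statistics of a 574-patient multi-ethnic cohort (502 No-PE / 72
PE), so the whole pipeline is testable without patient data.

## Worked example

```r
library(fuzzmoefs)

co <- generate_cohort(seed = 123)                  # 574 synthetic records
sp <- split_and_validate(co, seed = 123)           # stratified 75/25
fc <- fit_fuzzy_classifier(subset_cohort(co, sp$train_idx), n_sets = 4,
                           ga = ga_config(seed = 123))
fc
#> <fuzzy_classifier> 145 initial rules -> 9 selected (median solution), front size 31
#> <rule_base> 9 rules over 5 features; TRL = 31
#>    Rule 1: If MAP is VL, then p is 0[1 0]
#>    ...
#>    Rule 9: If MAP is H and GA is L, then p is 1[0.03 0.97]

te <- subset_cohort(co, sp$test_idx)
metrics(confusion(predict_cohort(fc$rulebase, te), te$outcome))
#> <metric_report> accuracy 0.85 | precision 0.44 | recall 0.82 | F1 0.57 | error 0.15 | coverage 0.98

s <- c(MAP = 118, BMI = 27, age = 24, parity = 1, GA = 38)
r <- classify(fc$rulebase, s)
r
#> <inference_result> decision = 1; scores [No-PE 0.134, PE 0.854]; crisp = 0.650
cat(explain(fc$rulebase, s, r), sep = "\n")
#> Rule 3: If MAP is M and GA is L and age is L and BMI is M, then p is 1[0.197 0.803]  [activation 0.403, ...]
#> ...
```

The 145-rule tree is reduced to 9 rules; held-out recall is 0.82 with the
majority of errors being false positives — the trade-off a screening tool
wants. The crisp score 0.65 > 0.50 flags the high-MAP, early-GA, young
patient as at risk, and the explanation names the rules that fired.

The GA-reduction, evaluation (confusion/ROC/grid search) and imputation
stages are also scriptable from a shell via
`Rscript inst/scripts/fuzzmoefs.R <synth|impute|reduce|evaluate|explain> ...`.

## Acceptance script

`scripts/acceptance.R` rebuilds the package's reference quantities from
scratch — it constructs the published MAP strong partition, translates it
to the four-parameter trapezoid format, and reports the resulting width
parameters, after exercising the full synthetic pipeline as a smoke check:

```sh
Rscript scripts/acceptance.R --seed 123 --out results/acceptance.json
```

## Scope notes

The headline figures of the reference study (91% accuracy, AUC 0.89,
recall 0.88, the 82-to-6 rule reduction) were measured on a merged *real*
dataset assembled from four public repositories; they are not reproducible
from summary statistics and are not asserted anywhere in the test suite.
`scripts/real_data.R` documents how to attempt that analysis once the
public files are downloaded.
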