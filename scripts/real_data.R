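#!/usr/bin/env Rscript
# OPTIONAL integration path (requires network + manual downloads).
#
# The headline results of the reference study (accuracy ~0.91, AUC ~0.89,
# recall ~0.88, and the 82 -> 6 rule reduction) were obtained on a merged
# real dataset assembled from four public cohorts. Those numbers are NOT
# reproducible from summary statistics alone, so nothing in the package's
# tests asserts them. This script documents how to attempt the analysis
# once the source files have been downloaded next to it:
#
#   1. Cambridge Baby Growth Study blood-pressure table
#      https://www.repository.cam.ac.uk/items/2e890286-663c-4f38-af71-cb972ce455b9
#   2. Mendeley: cardiovascular function under hypertensive pregnancy
#      https://data.mendeley.com/datasets/d72zr4xggx/1
#   3. Mendeley: renal biomarkers in preeclampsia
#      https://data.mendeley.com/datasets/ffpx6t6ky4/1
#   4. Fuzzy-knowledge-graph preeclampsia cohort
#      https://github.com/FKGHUST/Preeclampsia
#
# Each file must be reshaped to a CSV with columns among
# MAP (or SYS/DIA), BMI (or weight/height), age, parity, GA and outcome
# (0/1 or No-PE/PE). mean_arterial_pressure() and body_mass_index()
# recompute the derived variables where only raw readings are provided.

suppressPackageStartupMessages(library(fuzzmoefs))

files <- commandArgs(trailingOnly = TRUE)
if (length(files) == 0L) {
  message("usage: Rscript scripts/real_data.R cohort1.csv [cohort2.csv ...]")
  message("See the header comments for the download and reshaping steps.")
  quit(status = 0)
}

cohorts <- lapply(files, function(f) {
  co <- load_cohort(f)
  miss <- attr(co, "load_report")
  if (any(miss$n_missing > 0)) {
    m <- fit_latent_model(co, seed = 123)
    co <- impute(m, co)
  }
  co
})
merged <- merge_cohorts(cohorts)
print(merged)

sp <- split_and_validate(merged, train_frac = 0.75, n_folds = 4, seed = 123)
fc <- fit_fuzzy_classifier(subset_cohort(merged, sp$train_idx), n_sets = 4,
                           ga = ga_config(seed = 123))
print(fc)
te <- subset_cohort(merged, sp$test_idx)
cm <- confusion(predict_cohort(fc$rulebase, te), te$outcome)
print(cm)
print(metrics(cm))
sc <- risk_scores(fc$rulebase, te)
ok <- !is.na(sc)
print(roc_auc(sc[ok], te$outcome[ok], n_folds = 4, seed = 123))
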