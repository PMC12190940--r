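#' Build a confusion matrix with abstention handling
#'
#' Positive class is PE (label 1). Abstained predictions (\code{NA} or
#' \code{"ABSTAIN"}) are either excluded from the 2x2 counts but tallied
#' (default) or folded into the errors (an abstained case counts as FN when
#' truly positive, FP when truly negative).
#'
#' @param predictions Vector of 0/1 labels with \code{NA} (or
#'   \code{"ABSTAIN"}) for abstentions.
#' @param truths Vector of 0/1 labels.
#' @param abstain_policy \code{"exclude"} or \code{"count_as_error"}.
#' @return A \code{confusion_matrix} with fields \code{tp, fn, fp, tn,
#'   abstained}.
#' @export
confusion <- function(predictions, truths,
                      abstain_policy = c("exclude", "count_as_error")) {
  abstain_policy <- match.arg(abstain_policy)
  stopifnot(length(predictions) == length(truths))
  predictions[predictions %in% "ABSTAIN"] <- NA
  predictions <- suppressWarnings(as.integer(predictions))
  truths <- as.integer(truths)
  if (anyNA(truths) || !all(truths %in% c(0L, 1L)))
    stop("confusion: truths must be 0/1")
  if (!all(stats::na.omit(predictions) %in% c(0L, 1L)))
    stop("confusion: predictions must be 0/1 or abstain")
  abst <- is.na(predictions)
  if (abstain_policy == "count_as_error") {
    # folded into the 2x2 (FN if truly positive, FP if truly negative),
    # so they are not tallied separately as well
    predictions[abst] <- 1L - truths[abst]
    abst <- rep(FALSE, length(abst))
    n_abst <- 0L
  } else n_abst <- sum(abst)
  p <- predictions[!abst]; t <- truths[!abst]
  confusion_matrix(tp = sum(p == 1L & t == 1L), fn = sum(p == 0L & t == 1L),
                   fp = sum(p == 1L & t == 0L), tn = sum(p == 0L & t == 0L),
                   abstained = n_abst)
}

#' Confusion matrix object
#'
#' @param tp,fn,fp,tn Non-negative 2x2 counts (positive = PE).
#' @param abstained Count of unpredicted cases, outside the 2x2.
#' @return A \code{confusion_matrix}.
#' @export
confusion_matrix <- function(tp, fn, fp, tn, abstained = 0L) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn, abstained = abstained)
  if (any(v < 0)) stop("confusion_matrix: counts must be >= 0")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d FP=%d TN=%d (abstained %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$abstained))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall (sensitivity), F1, error rate, TPR and FPR.
#' Accuracy/precision/recall/F1 are computed over the predicted cases; the
#' error denominator is selectable (\code{"predicted"} = the 2x2 total,
#' \code{"all"} = predicted plus abstained) because external reports mix
#' both conventions. Degenerate denominators yield \code{NA}, never NaN.
#'
#' @param cm A \code{confusion_matrix}.
#' @param error_denominator \code{"predicted"} or \code{"all"}.
#' @return A \code{metric_report} list with \code{accuracy, precision,
#'   recall, f1, error, tpr, fpr, coverage}.
#' @export
metrics <- function(cm, error_denominator = c("predicted", "all")) {
  error_denominator <- match.arg(error_denominator)
  stopifnot(inherits(cm, "confusion_matrix"))
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  predicted <- cm$tp + cm$fn + cm$fp + cm$tn
  precision <- sdiv(cm$tp, cm$tp + cm$fp)
  recall <- sdiv(cm$tp, cm$tp + cm$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  den <- if (error_denominator == "all") predicted + cm$abstained else
    predicted
  structure(list(
    accuracy = sdiv(cm$tp + cm$tn, predicted),
    precision = precision, recall = recall, f1 = f1,
    error = sdiv(cm$fp + cm$fn, den),
    tpr = recall, fpr = sdiv(cm$fp, cm$fp + cm$tn),
    coverage = sdiv(predicted, predicted + cm$abstained)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf(paste("<metric_report> accuracy %s | precision %s | recall %s",
                    "| F1 %s | error %s | coverage %s\n"),
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall),
              fmt(x$f1), fmt(x$error), fmt(x$coverage)))
  invisible(x)
}

#' Normalized true/false difference rates
#'
#' The configuration-selection coordinates \code{(TP - FP)/(TP + FP)} and
#' \code{(TN - FN)/(TN + FN)}, both in \code{[-1, 1]}; a perfect classifier
#' sits at the (1, 1) corner.
#'
#' @param cm A \code{confusion_matrix}.
#' @return Named vector \code{c(tp_fp_rate, tn_fn_rate)}; \code{NA} on a
#'   zero denominator.
#' @export
normalized_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  c(tp_fp_rate = if (cm$tp + cm$fp > 0)
      (cm$tp - cm$fp) / (cm$tp + cm$fp) else NA_real_,
    tn_fn_rate = if (cm$tn + cm$fn > 0)
      (cm$tn - cm$fn) / (cm$tn + cm$fn) else NA_real_)
}

# stratified assignment of 1..n into k groups preserving class ratios
.stratified_groups <- function(strata, k) {
  g <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    g[idx] <- rep_len(seq_len(k), length(idx))
  }
  g
}

#' Stratified train/test split with cross-validation folds
#'
#' Produces a stratified holdout split preserving the class ratio within
#' one record per stratum, plus stratified cross-validation folds over the
#' training records. When imputed-record flags are supplied, stratification
#' is on class x flag, so imputed values are equally represented in all
#' partitions.
#'
#' @param x A \code{cohort} with both classes present.
#' @param train_frac Training fraction (default 0.75).
#' @param n_folds Number of CV folds over the training set (default 4).
#' @param seed RNG seed (default 123).
#' @param imputed_flags Optional logical vector marking records that
#'   contain imputed cells.
#' @return List with \code{train_idx}, \code{test_idx} and \code{fold}
#'   (fold id per training record, aligned with \code{train_idx}).
#' @export
split_and_validate <- function(x, train_frac = 0.75, n_folds = 4,
                               seed = 123, imputed_flags = NULL) {
  stopifnot(inherits(x, "cohort"))
  y <- x$outcome
  if (length(unique(y)) < 2L)
    stop("split_and_validate: both classes must be present")
  if (any(table(y) < n_folds))
    stop("split_and_validate: a class has fewer records than folds")
  strata <- if (is.null(imputed_flags)) as.character(y) else
    paste(y, as.integer(imputed_flags))
  set.seed(seed)
  test_idx <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_test <- round(length(idx) * (1 - train_frac))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  fold <- .stratified_groups(strata[train_idx], n_folds)
  list(train_idx = train_idx, test_idx = test_idx, fold = fold)
}

#' Subset a cohort by record index
#' @param x A \code{cohort}.
#' @param idx Integer record indices.
#' @return The sub-cohort.
#' @export
subset_cohort <- function(x, idx) {
  cohort(x$data[idx, , drop = FALSE], x$outcome[idx], x$provenance[idx],
         x$schema)
}

#' ROC area under the curve with stratified folds
#'
#' Builds each fold's ROC by sweeping the decision threshold over the
#' unique scores (TPR vs FPR) and integrates by trapezoid. Folds are
#' stratified on the labels; single-class folds are skipped with a warning.
#'
#' @param scores Real-valued per-sample risk scores (higher = more PE).
#' @param truths 0/1 labels.
#' @param n_folds Number of folds (default 4).
#' @param seed RNG seed for fold assignment.
#' @return List with \code{auc_per_fold} and \code{auc_mean}.
#' @export
roc_auc <- function(scores, truths, n_folds = 4, seed = 123) {
  stopifnot(length(scores) == length(truths))
  truths <- as.integer(truths)
  set.seed(seed)
  fold <- .stratified_groups(as.character(truths), n_folds)
  auc1 <- function(s, y) {
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    tpr <- vapply(thr, function(t) mean(s[y == 1L] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(s[y == 0L] >= t), numeric(1))
    sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  }
  aucs <- vapply(seq_len(n_folds), function(k) {
    y <- truths[fold == k]
    if (length(unique(y)) < 2L) {
      warning("roc_auc: single-class fold skipped")
      return(NA_real_)
    }
    auc1(scores[fold == k], y)
  }, numeric(1))
  list(auc_per_fold = aucs, auc_mean = mean(aucs, na.rm = TRUE))
}

#' Grid specification
#'
#' Per-parameter value lists for the configuration search. The default
#' lists reproduce the published tuning grid (3 x 6 x 6 x 6 x 4 x 1 x 4 x 1
#' = 10,368 combinations).
#'
#' @param max_depth,discr_minImpurity,discr_minGain,minGain,minNumExamples
#'   Value vectors.
#' @param max_prop,discr_threshold,mf Value vectors.
#' @param repeats Training repeats per configuration.
#' @param seed Base RNG seed.
#' @return A \code{grid_spec}.
#' @export
grid_spec <- function(max_depth = c(5, 10, 15),
                      discr_minImpurity = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1),
                      discr_minGain = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1),
                      minGain = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1),
                      minNumExamples = c(1, 2, 3, 4),
                      max_prop = 1.0,
                      discr_threshold = c(0, 1, 2, 3),
                      mf = 5,
                      repeats = 1, seed = 123) {
  structure(list(params = list(max_depth = max_depth,
                               discr_minImpurity = discr_minImpurity,
                               discr_minGain = discr_minGain,
                               minGain = minGain,
                               minNumExamples = minNumExamples,
                               max_prop = max_prop,
                               discr_threshold = discr_threshold,
                               mf = mf),
                 repeats = repeats, seed = seed),
            class = "grid_spec")
}

#' Number of configurations in a grid
#' @param grid A \code{grid_spec}.
#' @return Integer product of the per-parameter list lengths.
#' @export
grid_cardinality <- function(grid) {
  prod(vapply(grid$params, length, integer(1)))
}

#' Enumerate or run a configuration grid search
#'
#' With \code{train = FALSE} (default) the full Cartesian grid is
#' enumerated as metadata only. With \code{train = TRUE} each configuration
#' x repeat trains the whole pipeline (supervised discretization, fuzzy
#' tree, GA reduction) on a stratified split of \code{x}, records confusion
#' matrices for the unreduced tree and for the first/median/last Pareto
#' selections on the test set, and applies the five shortlist filters:
#' (1) the median solution's minority-class recall must exceed the
#' unreduced tree's; (2) the initial rule count must reach
#' \code{min_rules}; (3) the last solution's normalized TP-FP and TN-FN
#' rates must both exceed the configured thresholds; (4) configurations
#' containing a parameter value seen fewer than \code{min_count} times
#' among the survivors of filters 1-3 are dropped; (5) the last solution's
#' minority-class recall must exceed a logistic-regression baseline's.
#'
#' @param grid A \code{grid_spec}.
#' @param x Optional training \code{cohort} (required when
#'   \code{train = TRUE}).
#' @param train Run the pipeline per configuration.
#' @param ga Shared \code{ga_config} for the reduction stage.
#' @param rate_thresholds Length-2 numeric thresholds for filter 3
#'   (default both 0).
#' @param min_rules Filter 2 threshold (default 100).
#' @param min_count Filter 4 histogram minimum (default 1 = no-op).
#' @return With \code{train = FALSE}, the enumerated configuration data
#'   frame (attribute \code{"cardinality"}). With \code{train = TRUE}, a
#'   list with \code{results} (per run) and \code{shortlist} (surviving
#'   configuration rows, with a \code{passed} filter matrix attribute).
#' @export
grid_search <- function(grid, x = NULL, train = FALSE,
                        ga = ga_config(population_size = 16, generations = 10),
                        rate_thresholds = c(0, 0), min_rules = 100,
                        min_count = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  configs <- expand.grid(grid$params, KEEP.OUT.ATTRS = FALSE)
  attr(configs, "cardinality") <- nrow(configs)
  if (!train) return(configs)
  stopifnot(inherits(x, "cohort"))
  runs <- list()
  for (ci in seq_len(nrow(configs))) {
    cfg <- configs[ci, ]
    for (rep_i in seq_len(grid$repeats)) {
      seed_i <- grid$seed + (ci - 1L) * grid$repeats + rep_i - 1L
      sp <- split_and_validate(x, seed = seed_i)
      tr <- subset_cohort(x, sp$train_idx)
      te <- subset_cohort(x, sp$test_idx)
      partitions <- lapply(feature_names(tr), function(f)
        supervised_fuzzy_discretization(
          tr$data[[f]], tr$outcome,
          min_impurity = cfg$discr_minImpurity,
          min_gain = cfg$discr_minGain,
          threshold = cfg$discr_threshold, feature = f))
      names(partitions) <- feature_names(tr)
      tree <- build_fuzzy_tree(tr, partitions, tree_config(
        max_depth = cfg$max_depth, min_num_examples = cfg$minNumExamples,
        min_gain = cfg$minGain, max_prop = cfg$max_prop))
      rb <- extract_rules(tree)
      ga_i <- ga; ga_i$seed <- seed_i
      front <- evolve(rb, tr, ga_i)
      eval_rb <- function(rbx) {
        pred <- predict_cohort(rbx, te)
        confusion(pred, te$outcome)
      }
      cms <- list(tree = eval_rb(rb),
                  first = eval_rb(select_solution(front, "first")),
                  median = eval_rb(select_solution(front, "median")),
                  last = eval_rb(select_solution(front, "last")))
      runs[[length(runs) + 1L]] <- list(config = ci, repeat_i = rep_i,
                                        n_rules = length(rb),
                                        confusions = cms,
                                        test_idx = sp$test_idx)
    }
  }
  # logistic-regression baseline minority recall on each run's split
  base_recall <- vapply(runs, function(r) {
    sp_test <- r$test_idx
    tr <- subset_cohort(x, setdiff(seq_len(n_records(x)), sp_test))
    te <- subset_cohort(x, sp_test)
    fit <- stats::glm(y ~ ., family = stats::binomial(),
                      data = cbind(tr$data, y = tr$outcome))
    pred <- as.integer(stats::predict(fit, te$data,
                                      type = "response") > 0.5)
    cm <- confusion(pred, te$outcome)
    m <- metrics(cm)$recall
    if (is.na(m)) 0 else m
  }, numeric(1))
  rec <- function(cm) { r <- metrics(cm)$recall; if (is.na(r)) 0 else r }
  f1 <- vapply(runs, function(r)
    rec(r$confusions$median) > rec(r$confusions$tree), logical(1))
  f2 <- vapply(runs, function(r) r$n_rules >= min_rules, logical(1))
  f3 <- vapply(runs, function(r) {
    nr <- normalized_rates(r$confusions$last)
    !anyNA(nr) && nr[1] > rate_thresholds[1] && nr[2] > rate_thresholds[2]
  }, logical(1))
  surv123 <- which(f1 & f2 & f3)
  cfg_surv <- configs[vapply(runs[surv123], `[[`, integer(1), "config"), ,
                      drop = FALSE]
  f4 <- rep(FALSE, length(runs))
  if (length(surv123) > 0) {
    dense <- rep(TRUE, length(surv123))
    for (p in names(grid$params)) {
      tab <- table(cfg_surv[[p]])
      dense <- dense & tab[as.character(cfg_surv[[p]])] >= min_count
    }
    f4[surv123[dense]] <- TRUE
  }
  f5 <- vapply(seq_along(runs), function(i)
    rec(runs[[i]]$confusions$last) > base_recall[i], logical(1))
  passed <- cbind(median_beats_tree = f1, enough_rules = f2,
                  rate_region = f3, dense_params = f4,
                  last_beats_baseline = f5)
  keep <- which(rowSums(passed) == 5L)
  shortlist <- configs[vapply(runs[keep], `[[`, integer(1), "config"), ,
                       drop = FALSE]
  attr(shortlist, "passed") <- passed
  list(results = runs, shortlist = shortlist)
}
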