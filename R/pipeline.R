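#' Batch-classify a cohort
#'
#' Vectorized additive Mamdani inference over all records. Abstentions
#' (no fired rule, or an exact class-score tie) are returned as \code{NA}.
#'
#' @param rulebase A \code{rule_base}.
#' @param x A \code{cohort} (missing feature values zero the activations of
#'   rules that test them).
#' @param tnorm t-norm for rule activation.
#' @return Integer vector of 0/1 predictions with \code{NA} for
#'   abstentions.
#' @export
predict_cohort <- function(rulebase, x, tnorm = "minimum") {
  stopifnot(inherits(rulebase, "rule_base"), inherits(x, "cohort"))
  if (length(rulebase$rules) == 0L) stop("predict_cohort: empty rule base")
  A <- .activation_matrix(rulebase, x$data, tnorm)
  w <- vapply(rulebase$rules, `[[`, numeric(1), "weight")
  D <- t(vapply(rulebase$rules, `[[`, numeric(2), "class_distribution"))
  .masked_predict(A, w * D, rep(TRUE, length(rulebase$rules)))
}

#' Continuous PE-risk scores for a cohort
#'
#' The PE share of the aggregated class scores, in \code{[0, 1]};
#' \code{NA} where no rule fires. Useful as the score input for ROC/AUC.
#'
#' @param rulebase A \code{rule_base}.
#' @param x A \code{cohort}.
#' @param tnorm t-norm for rule activation.
#' @return Numeric vector of scores.
#' @export
risk_scores <- function(rulebase, x, tnorm = "minimum") {
  A <- .activation_matrix(rulebase, x$data, tnorm)
  w <- vapply(rulebase$rules, `[[`, numeric(1), "weight")
  D <- t(vapply(rulebase$rules, `[[`, numeric(2), "class_distribution"))
  S <- A %*% (w * D)
  tot <- rowSums(S)
  ifelse(tot > 0, S[, 2] / tot, NA_real_)
}

#' Fit the full explainable fuzzy classifier
#'
#' Convenience wrapper over the whole pipeline: build per-feature strong
#' partitions (uniform over the observed training range, or supervised
#' gain-driven discretization), induce the fuzzy decision tree, extract the
#' initial rule base, and reduce it with the multi-objective GA. The
#' returned model carries the Pareto front and the selected solution.
#'
#' @param x Training \code{cohort} without missing values.
#' @param n_sets Number of membership functions per variable for uniform
#'   partitioning (default 4, the configuration selected in the reference
#'   study).
#' @param partition_method \code{"uniform"} or \code{"supervised"}.
#' @param tree A \code{tree_config}.
#' @param ga A \code{ga_config}.
#' @param select Pareto selection: \code{"median"} (default),
#'   \code{"first"} or \code{"last"}.
#' @return A \code{fuzzy_classifier} list: \code{partitions}, \code{tree},
#'   \code{full_rules}, \code{front}, \code{rulebase} (the selection).
#' @export
fit_fuzzy_classifier <- function(x, n_sets = 4,
                                 partition_method = c("uniform", "supervised"),
                                 tree = tree_config(), ga = ga_config(),
                                 select = c("median", "first", "last")) {
  partition_method <- match.arg(partition_method)
  select <- match.arg(select)
  stopifnot(inherits(x, "cohort"))
  partitions <- lapply(feature_names(x), function(f) {
    v <- x$data[[f]]
    if (partition_method == "uniform") {
      rng <- range(v)
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      strong_partition(f, seq(rng[1], rng[2], length.out = n_sets))
    } else {
      supervised_fuzzy_discretization(v, x$outcome, feature = f,
                                      threshold = n_sets - 2L)
    }
  })
  names(partitions) <- feature_names(x)
  fdt <- build_fuzzy_tree(x, partitions, tree)
  full_rules <- extract_rules(fdt)
  front <- evolve(full_rules, x, ga, tnorm = tree$tnorm)
  structure(list(partitions = partitions, tree = fdt,
                 full_rules = full_rules, front = front,
                 rulebase = select_solution(front, select),
                 selection = select),
            class = "fuzzy_classifier")
}

#' @export
print.fuzzy_classifier <- function(x, ...) {
  cat(sprintf(paste("<fuzzy_classifier> %d initial rules -> %d selected",
                    "(%s solution), front size %d\n"),
              length(x$full_rules), length(x$rulebase), x$selection,
              nrow(x$front)))
  print(x$rulebase)
  invisible(x)
}

#' @export
predict.fuzzy_classifier <- function(object, newdata, ...) {
  predict_cohort(object$rulebase, newdata)
}
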