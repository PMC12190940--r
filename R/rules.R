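#' Fuzzy classification rule
#'
#' An IF-THEN rule whose antecedent is a conjunction of (feature,
#' linguistic term) conditions and whose consequent is a class-probability
#' vector ordered \code{[No-PE, PE]} (class 0, class 1), plus a rule weight
#' in \code{[0, 1]}.
#'
#' @param antecedents Data frame with columns \code{feature}, \code{term};
#'   features must be distinct. Zero rows = matches everything.
#' @param class_distribution Length-2 non-negative vector summing to 1.
#' @param weight Rule weight in \code{[0, 1]}.
#' @param support Optional fuzzy cardinality backing the rule.
#' @return A \code{fuzzy_rule}.
#' @export
fuzzy_rule <- function(antecedents, class_distribution, weight = 1,
                       support = NA_real_) {
  antecedents <- as.data.frame(antecedents)
  if (nrow(antecedents) > 0 && anyDuplicated(antecedents$feature))
    stop("fuzzy_rule: antecedent features must be distinct")
  class_distribution <- as.numeric(class_distribution)
  if (length(class_distribution) != 2L || any(class_distribution < 0) ||
      abs(sum(class_distribution) - 1) > 1e-9)
    stop("fuzzy_rule: distribution must be length 2 and sum to 1")
  if (weight < 0 || weight > 1) stop("fuzzy_rule: weight must be in [0, 1]")
  structure(list(antecedents = antecedents,
                 class_distribution = class_distribution,
                 weight = weight,
                 predicted_class = which.max(class_distribution) - 1L,
                 support = support),
            class = "fuzzy_rule")
}

#' Rule base
#'
#' An ordered list of fuzzy rules together with the per-feature strong
#' partitions their linguistic terms refer to.
#'
#' @param rules List of \code{fuzzy_rule}.
#' @param partitions Named list of \code{strong_partition}.
#' @param class_labels Ordered class names (class 0 first).
#' @return A \code{rule_base}.
#' @export
rule_base <- function(rules, partitions, class_labels = c("No-PE", "PE")) {
  stopifnot(is.list(rules), length(rules) >= 0)
  for (r in rules) {
    stopifnot(inherits(r, "fuzzy_rule"))
    if (nrow(r$antecedents) > 0) {
      for (i in seq_len(nrow(r$antecedents))) {
        f <- r$antecedents$feature[i]; tm <- r$antecedents$term[i]
        if (!f %in% names(partitions))
          stop(sprintf("rule_base: no partition for feature '%s'", f))
        if (!tm %in% partitions[[f]]$labels)
          stop(sprintf("rule_base: term '%s' not in partition of '%s'", tm, f))
      }
    }
  }
  structure(list(rules = rules, partitions = partitions,
                 class_labels = class_labels),
            class = "rule_base")
}

#' @export
length.rule_base <- function(x) length(x$rules)

#' Render a rule in linguistic form
#'
#' @param rule A \code{fuzzy_rule}.
#' @param index Optional rule number for the prefix.
#' @return A string such as
#'   \code{"Rule 4: If MAP is H, then p is 1[0.480 0.520]"}.
#' @export
format_rule <- function(rule, index = NULL) {
  ante <- if (nrow(rule$antecedents) == 0) "TRUE" else
    paste(sprintf("%s is %s", rule$antecedents$feature,
                  rule$antecedents$term), collapse = " and ")
  sprintf("%sIf %s, then p is %d[%s]",
          if (is.null(index)) "" else sprintf("Rule %d: ", index),
          ante, rule$predicted_class,
          paste(format(round(rule$class_distribution, 3), trim = TRUE),
                collapse = " "))
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("<rule_base> %d rules over %d features; TRL = %d\n",
              length(x$rules), length(x$partitions), total_rule_length(x)))
  for (i in seq_along(x$rules)) cat("  ", format_rule(x$rules[[i]], i), "\n")
  invisible(x)
}

#' Activation degree of a rule for one sample
#'
#' The t-norm over the antecedent memberships; an empty antecedent
#' activates at degree 1. A missing feature value either zeroes the
#' activation (default, the conservative clinical choice) or raises an
#' error.
#'
#' @param rule A \code{fuzzy_rule}.
#' @param sample Named numeric vector of feature values.
#' @param partitions Named list of \code{strong_partition}.
#' @param tnorm \code{"minimum"} or \code{"product"}.
#' @param missing_policy \code{"zero"} or \code{"error"}.
#' @return Degree in \code{[0, 1]}.
#' @export
rule_activation <- function(rule, sample, partitions,
                            tnorm = c("minimum", "product"),
                            missing_policy = c("zero", "error")) {
  tnorm <- match.arg(tnorm)
  missing_policy <- match.arg(missing_policy)
  if (nrow(rule$antecedents) == 0L) return(1)
  degs <- vapply(seq_len(nrow(rule$antecedents)), function(i) {
    f <- rule$antecedents$feature[i]
    v <- if (f %in% names(sample)) sample[[f]] else NULL
    if (is.null(v) || is.na(v)) {
      if (missing_policy == "error")
        stop(sprintf("rule_activation: missing value for feature '%s'", f))
      return(0)
    }
    membership(partitions[[f]]$sets[[rule$antecedents$term[i]]], v)
  }, numeric(1))
  if (tnorm == "minimum") min(degs) else prod(degs)
}

# N x M activation matrix for a whole cohort / matrix of samples
.activation_matrix <- function(rulebase, X, tnorm = "minimum") {
  X <- as.matrix(X)
  n <- nrow(X)
  feats <- unique(unlist(lapply(rulebase$rules,
                                function(r) r$antecedents$feature)))
  mdeg <- lapply(feats, function(f)
    partition_membership(rulebase$partitions[[f]], X[, f]))
  names(mdeg) <- feats
  A <- matrix(1, n, length(rulebase$rules))
  for (m in seq_along(rulebase$rules)) {
    ante <- rulebase$rules[[m]]$antecedents
    for (i in seq_len(nrow(ante))) {
      d <- mdeg[[ante$feature[i]]][, ante$term[i]]
      d[is.na(d)] <- 0
      A[, m] <- if (tnorm == "minimum") pmin(A[, m], d) else A[, m] * d
    }
  }
  A
}

#' Classify a sample with Mamdani-style additive inference
#'
#' Each rule contributes \code{activation * weight * distribution} to the
#' per-class scores; the decision is the argmax class. If no rule activates
#' the classifier abstains, and exact score ties also abstain (a class is
#' never picked silently in a clinical setting). A crisp risk score in
#' \code{[0, 1]} is produced by aggregating the class output sets and
#' defuzzifying.
#'
#' @param rulebase A \code{rule_base}.
#' @param sample Named numeric vector (or single-row data frame) of feature
#'   values.
#' @param tnorm \code{"minimum"} or \code{"product"}.
#' @param defuzz \code{"centroid"}, \code{"bisector"} or \code{"none"}.
#' @return An \code{inference_result} with \code{activations},
#'   \code{class_scores}, \code{decision} (0, 1 or \code{"ABSTAIN"}),
#'   \code{crisp_score} and a per-rule \code{trace}.
#' @export
classify <- function(rulebase, sample, tnorm = c("minimum", "product"),
                     defuzz = c("centroid", "bisector", "none")) {
  tnorm <- match.arg(tnorm)
  defuzz <- match.arg(defuzz)
  if (length(rulebase$rules) == 0L) stop("classify: empty rule base")
  if (is.data.frame(sample)) sample <- unlist(sample[1, , drop = TRUE])
  act <- vapply(rulebase$rules, rule_activation, numeric(1),
                sample = sample, partitions = rulebase$partitions,
                tnorm = tnorm)
  w <- vapply(rulebase$rules, `[[`, numeric(1), "weight")
  D <- t(vapply(rulebase$rules, `[[`, numeric(2), "class_distribution"))
  scores <- as.numeric(crossprod(act * w, D))
  names(scores) <- rulebase$class_labels
  decision <- if (all(act == 0)) "ABSTAIN" else
    if (abs(scores[1] - scores[2]) < 1e-12) "ABSTAIN" else
      as.character(which.max(scores) - 1L)
  res <- structure(list(activations = act, class_scores = scores,
                        decision = decision, crisp_score = NA_real_,
                        trace = data.frame(
                          rule = seq_along(act), activation = act,
                          weight = w, contribution_0 = act * w * D[, 1],
                          contribution_1 = act * w * D[, 2])),
                   class = "inference_result")
  if (defuzz != "none" && decision != "ABSTAIN") {
    agg <- aggregate_output(res)
    res$crisp_score <- defuzzify(agg$x, agg$mu, method = defuzz)
  }
  res
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> decision = %s; scores [%s]; crisp = %s\n",
              x$decision,
              paste(sprintf("%s %.3f", names(x$class_scores),
                            x$class_scores), collapse = ", "),
              if (is.na(x$crisp_score)) "NA" else
                sprintf("%.3f", x$crisp_score)))
  invisible(x)
}

#' Aggregate class outputs into a fuzzy risk curve
#'
#' The output universe is a PE-risk score on \code{[0, 1]}; the class
#' output sets default to triangles peaking at 0 (No-PE) and 1 (PE) whose
#' supports cover the whole interval. Each set is clipped at its class's
#' aggregated strength (class scores normalized to proportions) and the
#' clipped curves are combined with max (fuzzy OR, default) or bounded sum.
#'
#' @param result An \code{inference_result}.
#' @param n_grid Grid resolution, \code{>= 1001}.
#' @param aggregator \code{"max"} or \code{"sum"} (bounded).
#' @param output_sets Optional list of two \code{fuzzy_set} on \code{[0,1]}.
#' @return List with grid \code{x} and membership curve \code{mu}.
#' @export
aggregate_output <- function(result, n_grid = 1001,
                             aggregator = c("max", "sum"),
                             output_sets = NULL) {
  aggregator <- match.arg(aggregator)
  stopifnot(n_grid >= 1001)
  if (is.null(output_sets))
    output_sets <- list(fuzzy_set("No-PE", 0, 0, 1),
                        fuzzy_set("PE", 0, 1, 1))
  x <- seq(0, 1, length.out = n_grid)
  s <- result$class_scores
  tot <- sum(s)
  strength <- if (tot > 0) s / tot else c(0, 0)
  curves <- vapply(1:2, function(k)
    pmin(strength[k], membership(output_sets[[k]], x)),
    numeric(n_grid))
  mu <- if (aggregator == "max") pmax(curves[, 1], curves[, 2]) else
    pmin(1, curves[, 1] + curves[, 2])
  list(x = x, mu = mu)
}

#' Defuzzify a sampled membership curve
#'
#' Centroid: centre of gravity \code{int x mu / int mu} by trapezoidal
#' quadrature. Bisector: the smallest grid point splitting the area into
#' two equal halves. A zero-area curve has no defined crisp value and
#' returns \code{NA} (propagates as abstention).
#'
#' @param x Grid points (increasing).
#' @param mu Membership values on the grid.
#' @param method \code{"centroid"} or \code{"bisector"}.
#' @return Crisp value in \code{[min(x), max(x)]}, or \code{NA}.
#' @export
defuzzify <- function(x, mu, method = c("centroid", "bisector")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(mu), length(x) >= 2)
  dx <- diff(x)
  seg_area <- dx * (mu[-length(mu)] + mu[-1]) / 2
  area <- sum(seg_area)
  if (area <= 0) return(NA_real_)
  if (method == "centroid") {
    xm <- x * mu
    num <- sum(dx * (xm[-length(xm)] + xm[-1]) / 2)
    return(num / area)
  }
  cum <- cumsum(seg_area)
  i <- which(cum >= area / 2)[1]
  x[i + 1L]
}

#' Explain a classification in natural language
#'
#' Lists the fired rules in decreasing activation order with their
#' linguistic antecedents and class contributions, then states the crisp
#' risk score and the 0.5 decision threshold. Abstentions are reported as
#' "no rule activated".
#'
#' @param rulebase A \code{rule_base}.
#' @param sample The classified sample.
#' @param result The \code{inference_result} from \code{classify()}.
#' @return Character vector of explanation lines (also printed invisibly
#'   friendly via \code{cat}).
#' @export
explain <- function(rulebase, sample, result) {
  stopifnot(inherits(result, "inference_result"))
  if (result$decision == "ABSTAIN" && all(result$activations == 0)) {
    return(paste("No rule activated for this input;",
                 "the classifier abstains from a decision."))
  }
  fired <- which(result$activations > 0)
  fired <- fired[order(result$activations[fired], decreasing = TRUE)]
  lines <- sprintf(
    "%s  [activation %.3f, contributes %s %.3f / %s %.3f]",
    vapply(fired, function(m) format_rule(rulebase$rules[[m]], m),
           character(1)),
    result$activations[fired],
    rulebase$class_labels[1], result$trace$contribution_0[fired],
    rulebase$class_labels[2], result$trace$contribution_1[fired])
  tail_line <- if (result$decision == "ABSTAIN")
    "Class scores tie exactly; the classifier abstains." else
      sprintf(paste("Crisp PE-risk score %.2f against decision threshold",
                    "0.50 => class %s (%s)."),
              result$crisp_score, result$decision,
              rulebase$class_labels[as.integer(result$decision) + 1L])
  c(lines, tail_line)
}

#' Write a rule base to JSON
#' @param rulebase A \code{rule_base}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_rule_base <- function(rulebase, path) {
  obj <- list(
    class_labels = rulebase$class_labels,
    partitions = lapply(rulebase$partitions, function(p)
      list(feature = p$feature, labels = p$labels, anchors = p$anchors)),
    rules = lapply(rulebase$rules, function(r)
      list(features = r$antecedents$feature, terms = r$antecedents$term,
           distribution = r$class_distribution, weight = r$weight,
           support = r$support)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rule base from JSON
#' @param path JSON file written by \code{write_rule_base}.
#' @return A \code{rule_base}.
#' @export
read_rule_base <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  partitions <- lapply(obj$partitions, function(p)
    strong_partition(p$feature, unlist(p$anchors), unlist(p$labels)))
  rules <- lapply(obj$rules, function(r)
    fuzzy_rule(data.frame(feature = unlist(r$features) %||% character(),
                          term = unlist(r$terms) %||% character(),
                          stringsAsFactors = FALSE),
               unlist(r$distribution), weight = r$weight,
               support = r$support %||% NA_real_))
  rule_base(rules, partitions, class_labels = unlist(obj$class_labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
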