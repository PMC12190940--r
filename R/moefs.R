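#' Total rule length
#'
#' The interpretability objective: the sum of antecedent condition counts
#' over the included rules. An empty-antecedent rule contributes 0.
#'
#' @param rulebase A \code{rule_base}.
#' @param mask Optional logical inclusion vector (default: all rules).
#' @return Integer TRL.
#' @export
total_rule_length <- function(rulebase, mask = NULL) {
  lens <- vapply(rulebase$rules, function(r) nrow(r$antecedents), integer(1))
  if (is.null(mask)) mask <- rep(TRUE, length(lens))
  sum(lens[mask])
}

# batch prediction of a masked rule base from precomputed pieces:
# A = N x M activations, WD = M x 2 weight * distribution
.masked_predict <- function(A, WD, mask) {
  S <- A[, mask, drop = FALSE] %*% WD[mask, , drop = FALSE]
  fired <- rowSums(A[, mask, drop = FALSE]) > 0
  pred <- ifelse(!fired | abs(S[, 1] - S[, 2]) < 1e-12, NA_integer_,
                 as.integer(S[, 2] > S[, 1]))
  pred
}

.performance <- function(pred, y, metric) {
  # abstentions (NA) count as errors
  if (metric == "accuracy") {
    mean(!is.na(pred) & pred == y)
  } else {
    sens <- if (sum(y == 1L)) mean(!is.na(pred[y == 1L]) &
                                     pred[y == 1L] == 1L) else NA_real_
    spec <- if (sum(y == 0L)) mean(!is.na(pred[y == 0L]) &
                                     pred[y == 0L] == 0L) else NA_real_
    mean(c(sens, spec), na.rm = TRUE)
  }
}

#' Evaluate a rule-subset solution
#'
#' Performance is the classification rate of the masked rule base on the
#' cohort (abstentions count as errors): plain accuracy, or the mean of
#' sensitivity and specificity for \code{metric = "balanced"}. Complexity
#' is the total rule length of the included rules.
#'
#' @param mask Logical inclusion vector over the rules.
#' @param rulebase A \code{rule_base}.
#' @param x A labelled \code{cohort}.
#' @param metric \code{"accuracy"} (default) or \code{"balanced"}.
#' @param tnorm t-norm for rule activation.
#' @return List with \code{performance}, \code{trl} and \code{feasible}.
#' @export
evaluate_solution <- function(mask, rulebase, x,
                              metric = c("accuracy", "balanced"),
                              tnorm = "minimum") {
  metric <- match.arg(metric)
  mask <- as.logical(mask)
  if (!any(mask))
    return(list(performance = 0, trl = 0L, feasible = FALSE))
  A <- .activation_matrix(rulebase, x$data, tnorm)
  w <- vapply(rulebase$rules, `[[`, numeric(1), "weight")
  D <- t(vapply(rulebase$rules, `[[`, numeric(2), "class_distribution"))
  pred <- .masked_predict(A, w * D, mask)
  list(performance = .performance(pred, x$outcome, metric),
       trl = total_rule_length(rulebase, mask), feasible = TRUE)
}

#' Non-dominated sorting with crowding distances
#'
#' Objectives: maximize performance, minimize TRL. Front 0 is the
#' non-dominated set; subsequent fronts are peeled recursively. Crowding
#' distances are computed within each front on the two-objective space.
#'
#' @param performance Numeric vector.
#' @param trl Numeric vector (same length).
#' @return List with \code{fronts} (list of index vectors), \code{rank}
#'   (0-based front index per solution) and \code{crowding}.
#' @export
nondominated_sort <- function(performance, trl) {
  n <- length(performance)
  stopifnot(length(trl) == n, n >= 1)
  dominates <- function(i, j)
    (performance[i] >= performance[j] && trl[i] <= trl[j]) &&
    (performance[i] > performance[j] || trl[i] < trl[j])
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    if (dominates(i, j)) dominated_by[[i]] <- c(dominated_by[[i]], j)
    else if (dominates(j, i)) dom_count[i] <- dom_count[i] + 1L
  }
  rank <- rep(NA_integer_, n)
  fronts <- list()
  current <- which(dom_count == 0L)
  level <- 0L
  while (length(current) > 0L) {
    rank[current] <- level
    fronts[[level + 1L]] <- current
    nxt <- integer(0)
    for (i in current) for (j in dominated_by[[i]]) {
      dom_count[j] <- dom_count[j] - 1L
      if (dom_count[j] == 0L) nxt <- c(nxt, j)
    }
    current <- sort(unique(nxt))
    level <- level + 1L
  }
  crowding <- numeric(n)
  for (fr in fronts) {
    if (length(fr) <= 2L) { crowding[fr] <- Inf; next }
    cd <- numeric(length(fr))
    for (obj in list(performance[fr], trl[fr])) {
      o <- order(obj)
      rng <- max(obj) - min(obj)
      cd[o[1]] <- cd[o[length(o)]] <- Inf
      if (rng > 0)
        for (i in 2:(length(o) - 1L))
          cd[o[i]] <- cd[o[i]] + (obj[o[i + 1L]] - obj[o[i - 1L]]) / rng
    }
    crowding[fr] <- cd
  }
  list(fronts = fronts, rank = rank, crowding = crowding)
}

#' Genetic algorithm configuration
#'
#' @param population_size Population size, \code{>= 4}.
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Operator probabilities in
#'   \code{[0, 1]}; mutation defaults to \code{1/M} per bit.
#' @param seed RNG seed (the study fixed 123).
#' @param performance_metric \code{"balanced"} (mean sensitivity /
#'   specificity, the fitness the method describes) or \code{"accuracy"}.
#' @return A \code{ga_config}.
#' @export
ga_config <- function(population_size = 64, generations = 50,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      seed = 123,
                      performance_metric = c("balanced", "accuracy")) {
  performance_metric <- match.arg(performance_metric)
  stopifnot(population_size >= 4, generations >= 0,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, seed = as.integer(seed),
                 performance_metric = performance_metric),
            class = "ga_config")
}

#' Reduce a rule base with a multi-objective genetic algorithm
#'
#' NSGA-II-style subset selection over rule-inclusion masks: binary
#' tournament on (front rank, crowding), uniform crossover, per-bit flip
#' mutation with repair of empty masks, and elitist environmental selection
#' retaining the best fronts. Rule activations are precomputed once, so
#' each mask evaluation is a small matrix product. Deterministic for a
#' given seed.
#'
#' @param rulebase The full \code{rule_base} extracted from the tree.
#' @param x Training \code{cohort}.
#' @param config A \code{ga_config}.
#' @param tnorm t-norm for rule activation.
#' @return A \code{pareto_front}: data frame of the final non-dominated set
#'   (columns \code{performance}, \code{trl}, \code{n_rules}) sorted by
#'   descending performance, with the masks in attribute \code{"masks"} and
#'   the rule base in \code{"rulebase"}.
#' @export
evolve <- function(rulebase, x, config = ga_config(), tnorm = "minimum") {
  stopifnot(inherits(rulebase, "rule_base"), inherits(x, "cohort"))
  M <- length(rulebase$rules)
  if (M == 0L) stop("evolve: empty rule base")
  set.seed(config$seed)
  pmut <- if (is.null(config$mutation_rate)) 1 / M else config$mutation_rate
  A <- .activation_matrix(rulebase, x$data, tnorm)
  w <- vapply(rulebase$rules, `[[`, numeric(1), "weight")
  D <- t(vapply(rulebase$rules, `[[`, numeric(2), "class_distribution"))
  WD <- w * D
  lens <- vapply(rulebase$rules, function(r) nrow(r$antecedents), integer(1))
  y <- x$outcome
  eval_mask <- function(mask) {
    pred <- .masked_predict(A, WD, mask)
    c(perf = .performance(pred, y, config$performance_metric),
      trl = sum(lens[mask]))
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(M, 1L)] <- TRUE
    mask
  }
  # initial population: full mask plus random masks on a density gradient,
  # so the TRL axis of the front is covered from the start
  dens <- seq(0.05, 0.95, length.out = config$population_size - 1L)
  pop <- c(list(rep(TRUE, M)),
           lapply(dens, function(p) repair(stats::runif(M) < p)))
  obj <- t(vapply(pop, eval_mask, numeric(2)))
  for (gen in seq_len(config$generations)) {
    ns <- nondominated_sort(obj[, "perf"], obj[, "trl"])
    tournament <- function() {
      ij <- sample.int(length(pop), 2L)
      i <- ij[1]; j <- ij[2]
      if (ns$rank[i] < ns$rank[j]) i
      else if (ns$rank[j] < ns$rank[i]) j
      else if (ns$crowding[i] >= ns$crowding[j]) i else j
    }
    offspring <- vector("list", config$population_size)
    for (o in seq(1, config$population_size, by = 2)) {
      p1 <- pop[[tournament()]]; p2 <- pop[[tournament()]]
      if (stats::runif(1) < config$crossover_rate) {
        swap <- stats::runif(M) < 0.5
        c1 <- ifelse(swap, p2, p1); c2 <- ifelse(swap, p1, p2)
      } else { c1 <- p1; c2 <- p2 }
      flip1 <- stats::runif(M) < pmut
      flip2 <- stats::runif(M) < pmut
      offspring[[o]] <- repair(xor(c1, flip1))
      if (o + 1L <= config$population_size)
        offspring[[o + 1L]] <- repair(xor(c2, flip2))
    }
    obj_off <- t(vapply(offspring, eval_mask, numeric(2)))
    all_pop <- c(pop, offspring)
    all_obj <- rbind(obj, obj_off)
    ns2 <- nondominated_sort(all_obj[, "perf"], all_obj[, "trl"])
    keep <- integer(0)
    for (fr in ns2$fronts) {
      if (length(keep) + length(fr) <= config$population_size) {
        keep <- c(keep, fr)
      } else {
        room <- config$population_size - length(keep)
        keep <- c(keep, fr[order(ns2$crowding[fr],
                                 decreasing = TRUE)][seq_len(room)])
        break
      }
    }
    pop <- all_pop[keep]
    obj <- all_obj[keep, , drop = FALSE]
  }
  ns <- nondominated_sort(obj[, "perf"], obj[, "trl"])
  fr0 <- ns$fronts[[1]]
  # deduplicate identical objective pairs, keep first occurrence
  o <- fr0[order(-obj[fr0, "perf"], obj[fr0, "trl"])]
  dup <- duplicated(obj[o, , drop = FALSE])
  o <- o[!dup]
  front <- data.frame(performance = obj[o, "perf"], trl = obj[o, "trl"],
                      n_rules = vapply(pop[o], sum, integer(1)))
  rownames(front) <- NULL
  structure(front, masks = pop[o], rulebase = rulebase,
            class = c("pareto_front", "data.frame"))
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d non-dominated solution(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Select a solution from a Pareto front
#'
#' \code{"first"} is the highest-performance solution, \code{"last"} the
#' lowest-TRL (most interpretable) one, and \code{"median"} the middle
#' element of the front sorted by descending performance.
#'
#' @param front A \code{pareto_front} from \code{evolve()}.
#' @param which \code{"first"}, \code{"median"} or \code{"last"}.
#' @return The reduced \code{rule_base}; the chosen mask and objectives are
#'   attached as attributes \code{"mask"}, \code{"performance"},
#'   \code{"trl"}.
#' @export
select_solution <- function(front, which = c("first", "median", "last")) {
  which <- match.arg(which)
  if (nrow(front) == 0L) stop("select_solution: empty front")
  i <- switch(which,
              first = 1L,
              median = as.integer(floor((nrow(front) + 1) / 2)),
              last = which.min(front$trl))
  mask <- attr(front, "masks")[[i]]
  rb <- attr(front, "rulebase")
  out <- rule_base(rb$rules[mask], rb$partitions, rb$class_labels)
  attr(out, "mask") <- mask
  attr(out, "performance") <- front$performance[i]
  attr(out, "trl") <- front$trl[i]
  out
}
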