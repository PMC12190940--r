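#' Fuzzy cardinality
#'
#' The "soft count" of a fuzzy set of records: the sum of membership
#' degrees. With crisp 0/1 indicators it reduces to an ordinary count.
#'
#' @param memberships Numeric degrees in \code{[0, 1]}.
#' @return Scalar sum of degrees.
#' @export
fuzzy_cardinality <- function(memberships) {
  if (length(memberships) && (any(memberships < 0) || any(memberships > 1)))
    stop("fuzzy_cardinality: degrees must lie in [0, 1]")
  sum(memberships)
}

#' Per-class fuzzy cardinalities
#'
#' @param memberships Node membership degree per record.
#' @param y Integer class labels (0/1) aligned with \code{memberships}.
#' @return Named numeric vector \code{c("0" = ., "1" = .)}.
#' @export
class_cardinalities <- function(memberships, y) {
  y <- as.integer(y)
  c("0" = sum(memberships[y == 0L]), "1" = sum(memberships[y == 1L]))
}

#' Combine parent and candidate-set memberships with a t-norm
#'
#' Child membership of each record is the t-norm of its membership in the
#' parent node and in the candidate fuzzy set. For categorical branches the
#' set degree is the 0/1 match indicator, so the minimum/product both reduce
#' to passing the parent degree through on matching records.
#'
#' @param parent_degrees,set_degrees Equal-length degree vectors.
#' @param tnorm \code{"minimum"} or \code{"product"}.
#' @return Degree vector of the child node.
#' @export
child_membership <- function(parent_degrees, set_degrees,
                             tnorm = c("minimum", "product")) {
  tnorm <- match.arg(tnorm)
  stopifnot(length(parent_degrees) == length(set_degrees))
  if (tnorm == "minimum") pmin(parent_degrees, set_degrees)
  else parent_degrees * set_degrees
}

#' Fuzzy entropy in bits
#'
#' Shannon entropy of the normalized per-class fuzzy cardinalities, with
#' the convention \code{0 log 0 = 0}. A zero total is defined as 0 bits
#' (with a warning), matching the "empty node is pure" reading.
#'
#' @param class_cardinalities Non-negative per-class fuzzy counts.
#' @return Entropy in bits.
#' @export
fuzzy_entropy <- function(class_cardinalities) {
  if (any(class_cardinalities < 0))
    stop("fuzzy_entropy: cardinalities must be >= 0")
  tot <- sum(class_cardinalities)
  if (tot <= 0) {
    warning("fuzzy_entropy: zero total cardinality, entropy defined as 0")
    return(0)
  }
  p <- class_cardinalities / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Fuzzy information gain of a candidate split
#'
#' Parent fuzzy entropy minus the cardinality-weighted mean of the child
#' entropies, where each child's weight is its fuzzy cardinality divided by
#' the parent's. In the crisp limit this equals classical information gain.
#'
#' @param parent_degrees Node membership per record.
#' @param child_degrees Records-by-children matrix of child memberships
#'   (already combined with the parent via the t-norm).
#' @param y Integer class labels (0/1).
#' @return Gain in bits.
#' @export
fuzzy_gain <- function(parent_degrees, child_degrees, y) {
  child_degrees <- as.matrix(child_degrees)
  parent_card <- sum(parent_degrees)
  if (parent_card <= 0) stop("fuzzy_gain: parent has zero cardinality")
  parent_ent <- fuzzy_entropy(class_cardinalities(parent_degrees, y))
  wch <- 0
  for (j in seq_len(ncol(child_degrees))) {
    cardj <- class_cardinalities(child_degrees[, j], y)
    totj <- sum(cardj)
    if (totj > 0) wch <- wch + (totj / parent_card) * fuzzy_entropy(cardj)
  }
  parent_ent - wch
}

#' Fuzzy tree configuration
#'
#' Defaults follow the selected configuration of the reference study:
#' depth cap 15, minimum node fuzzy cardinality 4, minimum split gain
#' 0.001 with an absolute floor of 1e-6, and no purity early-stop
#' (\code{max_prop = 1}).
#'
#' @param max_depth Maximum tree depth (\code{beta}), \code{>= 1}.
#' @param min_num_examples Minimum node fuzzy cardinality (\code{lambda})
#'   to attempt a split; compared against the soft count, not row count.
#' @param min_gain Minimum fuzzy information gain to split.
#' @param gain_epsilon Absolute gain floor (the effective threshold is
#'   \code{max(min_gain, gain_epsilon)}).
#' @param max_prop Stop splitting once the majority-class proportion
#'   reaches this value, in \code{(0, 1]}.
#' @param tnorm Conjunction operator for tree induction: \code{"product"}
#'   (default; conserves fuzzy mass across a strong-partition split, so
#'   child cardinalities sum exactly to the parent's) or \code{"minimum"}
#'   (can inflate the joint child mass where set memberships exceed the
#'   parent degree, biasing splits toward near-crisp features).
#' @return A \code{tree_config}.
#' @export
tree_config <- function(max_depth = 15, min_num_examples = 4,
                        min_gain = 0.001, gain_epsilon = 1e-6,
                        max_prop = 1.0, tnorm = c("product", "minimum")) {
  tnorm <- match.arg(tnorm)
  stopifnot(max_depth >= 1, min_num_examples > 0, gain_epsilon > 0,
            max_prop > 0, max_prop <= 1)
  structure(list(max_depth = max_depth,
                 min_num_examples = min_num_examples,
                 min_gain = min_gain, gain_epsilon = gain_epsilon,
                 max_prop = max_prop, tnorm = tnorm),
            class = "tree_config")
}

# membership < this is treated as zero when indexing child records
.sparsity_cutoff <- 1e-12

#' Build a fuzzy decision tree
#'
#' Recursive multiway construction over fuzzified features: at each internal
#' node the feature whose full partition yields the highest fuzzy
#' information gain is selected (a feature is used at most once per path),
#' and one child is created per linguistic term with membership given by the
#' t-norm of the parent and set degrees. A node becomes a leaf when a single
#' class remains, its fuzzy cardinality drops below \code{min_num_examples},
#' the depth cap is reached, the best gain falls below the effective
#' threshold, or the majority-class proportion reaches \code{max_prop}.
#' Leaves store fuzzy class distributions, never crisp labels.
#'
#' @param x A \code{cohort} without missing values.
#' @param partitions Named list of \code{strong_partition}, one per feature.
#' @param config A \code{tree_config}.
#' @return A \code{fuzzy_tree} (root \code{fuzzy_tree_node}).
#' @export
build_fuzzy_tree <- function(x, partitions, config = tree_config()) {
  stopifnot(inherits(x, "cohort"), inherits(config, "tree_config"))
  if (n_records(x) == 0L) stop("build_fuzzy_tree: empty cohort")
  feats <- feature_names(x)
  if (!all(feats %in% names(partitions)))
    stop("build_fuzzy_tree: every feature needs a partition")
  X <- as.matrix(x$data)
  if (anyNA(X)) stop("build_fuzzy_tree: cohort has missing values (impute first)")
  y <- x$outcome
  # precompute set memberships once per feature
  mdeg <- lapply(feats, function(f) partition_membership(partitions[[f]], X[, f]))
  names(mdeg) <- feats
  gain_floor <- max(config$min_gain, config$gain_epsilon)

  make_leaf <- function(idx, w, depth) {
    card <- class_cardinalities(w, y[idx])
    tot <- sum(card)
    dist <- if (tot > 0) card / tot else c("0" = 0.5, "1" = 0.5)
    structure(list(kind = "leaf", depth = depth, cardinality = tot,
                   class_cardinalities = card, class_distribution = dist),
              class = "fuzzy_tree_node")
  }

  grow <- function(idx, w, depth, unused) {
    card <- class_cardinalities(w, y[idx])
    tot <- sum(card)
    if (tot <= 0 || min(card) == 0 ||                     # single class
        tot < config$min_num_examples ||                  # lambda
        depth >= config$max_depth ||                      # beta
        max(card) / tot >= config$max_prop - 1e-12 ||     # purity stop
        length(unused) == 0L)
      return(make_leaf(idx, w, depth))
    gains <- vapply(unused, function(f) {
      ch <- child_membership(matrix(w, length(idx), ncol(mdeg[[f]])),
                             mdeg[[f]][idx, , drop = FALSE], config$tnorm)
      fuzzy_gain(w, ch, y[idx])
    }, numeric(1))
    best <- unused[which.max(gains)]   # declaration-order tie break
    if (gains[which.max(gains)] < gain_floor)
      return(make_leaf(idx, w, depth))
    part <- partitions[[best]]
    children <- lapply(seq_along(part$sets), function(j) {
      wj <- child_membership(w, mdeg[[best]][idx, j], config$tnorm)
      keep <- wj > .sparsity_cutoff
      grow(idx[keep], wj[keep], depth + 1L, setdiff(unused, best))
    })
    structure(list(kind = "internal", depth = depth, cardinality = tot,
                   split_feature = best, child_terms = part$labels,
                   children = children,
                   class_cardinalities = card),
              class = "fuzzy_tree_node")
  }

  root <- grow(seq_len(nrow(X)), rep(1, nrow(X)), 0L, feats)
  structure(list(root = root, partitions = partitions[feats],
                 config = config, class_labels = c("No-PE", "PE")),
            class = "fuzzy_tree")
}

#' @export
print.fuzzy_tree <- function(x, ...) {
  count <- function(node) {
    if (node$kind == "leaf") c(leaves = 1L, nodes = 1L)
    else c(leaves = 0L, nodes = 1L) +
      Reduce(`+`, lapply(node$children, count))
  }
  ct <- count(x$root)
  cat(sprintf("<fuzzy_tree> %d nodes, %d leaves, t-norm = %s\n",
              ct["nodes"], ct["leaves"], x$config$tnorm))
  invisible(x)
}

#' Extract the rule base from a fuzzy tree
#'
#' One rule per leaf: the antecedent is the ordered conjunction of
#' (feature, linguistic term) pairs along the root-to-leaf path and the
#' consequent is the leaf's fuzzy class distribution. The leaf cardinality
#' is kept as the weight basis; the rule weight is either the rule
#' confidence (maximum of the distribution, default) or 1.
#'
#' @param tree A \code{fuzzy_tree}.
#' @param rule_weight \code{"confidence"} or \code{"one"}.
#' @return A \code{rule_base}.
#' @export
extract_rules <- function(tree, rule_weight = c("confidence", "one")) {
  rule_weight <- match.arg(rule_weight)
  stopifnot(inherits(tree, "fuzzy_tree"))
  rules <- list()
  walk <- function(node, ante) {
    if (node$kind == "leaf") {
      dist <- as.numeric(node$class_distribution)
      rules[[length(rules) + 1L]] <<- fuzzy_rule(
        antecedents = ante,
        class_distribution = dist,
        weight = if (rule_weight == "confidence") max(dist) else 1,
        support = node$cardinality)
      return(invisible())
    }
    for (j in seq_along(node$children))
      walk(node$children[[j]],
           rbind(ante, data.frame(feature = node$split_feature,
                                  term = node$child_terms[j],
                                  stringsAsFactors = FALSE)))
  }
  walk(tree$root, data.frame(feature = character(), term = character(),
                             stringsAsFactors = FALSE))
  rule_base(rules, tree$partitions, class_labels = tree$class_labels)
}
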