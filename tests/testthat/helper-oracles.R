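# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately implemented from first principles,
# separate from the package's own code paths.

# classical Shannon entropy (bits) of a label vector
crisp_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# classical information gain of a categorical split
crisp_info_gain <- function(groups, y) {
  n <- length(y)
  crisp_entropy(y) -
    sum(vapply(unique(groups), function(g) {
      idx <- groups == g
      sum(idx) / n * crisp_entropy(y[idx])
    }, numeric(1)))
}

# textbook multiway ID3 with the same stopping rules as the fuzzy tree:
# single class, node size < min_n, depth cap, best gain < eps.
# Features are small-integer bin codes; a feature is used once per path.
# Tie-breaks mirror the package: feature declaration order.
id3_build <- function(X, y, max_depth = 15, min_n = 1, eps = 1e-6,
                      depth = 0, unused = colnames(X)) {
  dist <- c(sum(y == 0), sum(y == 1)) / length(y)
  leaf <- list(kind = "leaf", dist = dist)
  if (length(unique(y)) == 1L || length(y) < min_n ||
      depth >= max_depth || length(unused) == 0L)
    return(leaf)
  gains <- vapply(unused, function(f) crisp_info_gain(X[, f], y),
                  numeric(1))
  if (max(gains) < eps) return(leaf)
  best <- unused[which.max(gains)]
  vals <- sort(unique(X[, best]))
  kids <- lapply(vals, function(v) {
    idx <- X[, best] == v
    if (!any(idx)) return(list(kind = "leaf", dist = dist))
    id3_build(X[idx, , drop = FALSE], y[idx], max_depth, min_n, eps,
              depth + 1, setdiff(unused, best))
  })
  names(kids) <- as.character(vals)
  list(kind = "internal", feature = best, children = kids)
}

id3_predict_dist <- function(node, x) {
  while (node$kind == "internal") {
    v <- as.character(x[[node$feature]])
    if (!v %in% names(node$children)) return(node$children[[1]]$dist)
    node <- node$children[[v]]
  }
  node$dist
}

id3_count_leaves <- function(node) {
  if (node$kind == "leaf") return(1L)
  sum(vapply(node$children, id3_count_leaves, integer(1)))
}

# brute-force Pareto front: maximize perf, minimize trl
brute_force_front <- function(perf, trl) {
  n <- length(perf)
  which(vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && perf[j] >= perf[i] && trl[j] <= trl[i] &&
        (perf[j] > perf[i] || trl[j] < trl[i])
    }, logical(1)))
  }, logical(1)))
}

# the published trapezoid-table partitions for the three active variables
table9_partitions <- function() {
  list(MAP = strong_partition("MAP", c(61.67, 88.51, 101.09, 133.33)),
       BMI = strong_partition("BMI", c(17.31, 21.23, 30.27, 43.40)),
       age = strong_partition("age", c(18.0, 26.4, 31.42, 45.2)))
}

# the published six-rule reduced set (distributions normalized to sum 1)
six_rules_fixture <- function() {
  mk <- function(feats, terms, dist) {
    fuzzy_rule(data.frame(feature = feats, term = terms,
                          stringsAsFactors = FALSE),
               dist / sum(dist))
  }
  rule_base(list(
    mk(c("MAP", "BMI"), c("VL", "H"), c(0.836, 0.164)),
    mk(c("MAP", "BMI"), c("L", "L"), c(1, 0)),
    mk("MAP", "L", c(9.993e-01, 7.198e-04)),
    mk("MAP", "H", c(0.480, 0.520)),
    mk(c("MAP", "BMI", "age"), c("H", "VL", "L"), c(0.792, 0.208)),
    mk(c("MAP", "BMI", "age"), c("H", "M", "L"), c(0.335, 0.664))),
    table9_partitions())
}

# crisp fixture: features are anchor-grid codes, so partition memberships
# are exact 0/1 indicators and the fuzzy machinery runs in its crisp limit
make_crisp_fixture <- function(n = 120, n_feat = 3, k = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(sample.int(k, n * n_feat, replace = TRUE), n, n_feat,
              dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  y <- as.integer((X[, 1] + X[, 2] >= k + 1) |
                    (X[, 3] == 1 & stats::runif(n) < 0.3))
  partitions <- lapply(colnames(X), function(f)
    strong_partition(f, seq_len(k)))
  names(partitions) <- colnames(X)
  schema <- lapply(colnames(X), function(f)
    feature_schema(f, "", 0.5, k + 0.5))
  names(schema) <- colnames(X)
  list(cohort = cohort(as.data.frame(X), y, schema = schema),
       partitions = partitions, X = X, y = y)
}
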