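test_that("fuzzy cardinality is a soft count", {
  expect_equal(fuzzy_cardinality(c(0, 0, 0)), 0)
  expect_equal(fuzzy_cardinality(c(1, 0, 1, 1)), 3)   # crisp indicator
  expect_equal(fuzzy_cardinality(c(0.5, 0.25, 1.0)), 1.75)
  expect_error(fuzzy_cardinality(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("child membership applies the configured t-norm", {
  expect_equal(child_membership(c(1, 1), c(0.3, 0.8)), c(0.3, 0.8))
  expect_equal(child_membership(c(0.3, 0.8), c(1, 1)), c(0.3, 0.8))
  expect_equal(child_membership(0.7, 0.4, "minimum"), 0.4)
  expect_equal(child_membership(0.7, 0.4, "product"), 0.28)
})

test_that("fuzzy entropy matches hand-computed values", {
  expect_equal(fuzzy_entropy(c(3.2, 3.2)), 1)
  expect_equal(fuzzy_entropy(c(5, 0)), 0)
  expect_equal(fuzzy_entropy(c(0.75, 0.25)),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_warning(z <- fuzzy_entropy(c(0, 0)), "zero")
  expect_equal(z, 0)
})

test_that("fuzzy gain: non-informative split, crisp limit, perfect split", {
  y <- c(0, 0, 1, 1, 1)
  w <- c(1, 0.5, 1, 0.2, 0.8)
  # single child identical to the parent carries no information
  expect_equal(fuzzy_gain(w, matrix(w, ncol = 1), y), 0, tolerance = 1e-12)
  # crisp limit equals classical information gain (independent oracle)
  set.seed(3)
  yc <- sample(c(0, 1), 60, TRUE)
  g <- sample(1:3, 60, TRUE)
  child <- vapply(1:3, function(v) as.numeric(g == v), numeric(60))
  expect_equal(fuzzy_gain(rep(1, 60), child, yc),
               crisp_info_gain(g, yc), tolerance = 1e-12)
  # perfectly separating crisp split recovers the full parent entropy
  child2 <- cbind(as.numeric(yc == 0), as.numeric(yc == 1))
  expect_equal(fuzzy_gain(rep(1, 60), child2, yc), crisp_entropy(yc),
               tolerance = 1e-12)
})

test_that("stopping criteria create the expected leaves", {
  parts <- list(x = strong_partition("x", c(0, 1)))
  pure <- cohort(data.frame(x = c(0.1, 0.5, 0.9)), c(1, 1, 1))
  t1 <- build_fuzzy_tree(pure, parts)
  expect_equal(t1$root$kind, "leaf")
  expect_equal(as.numeric(t1$root$class_distribution), c(0, 1))
  # depth cap of 1 gives a single split level
  fx <- make_crisp_fixture(n = 80)
  t2 <- build_fuzzy_tree(fx$cohort, fx$partitions,
                         tree_config(max_depth = 1, min_gain = 1e-9,
                                     min_num_examples = 1))
  expect_equal(t2$root$kind, "internal")
  for (ch in t2$root$children) expect_equal(ch$kind, "leaf")
  expect_error(build_fuzzy_tree(subset_cohort(pure, integer(0)), parts),
               "empty")
})

test_that("a separable cohort is classified almost perfectly", {
  sc <- make_separable_cohort(100, seed = 123)
  parts <- lapply(feature_names(sc), function(f) {
    rng <- range(sc$data[[f]])
    strong_partition(f, seq(rng[1], rng[2], length.out = 3))
  })
  names(parts) <- feature_names(sc)
  tree <- build_fuzzy_tree(sc, parts, tree_config(max_depth = 2))
  rb <- extract_rules(tree)
  pred <- predict_cohort(rb, sc)
  expect_gte(mean(!is.na(pred) & pred == sc$outcome), 0.95)
})

test_that("rule extraction is a bijection on leaves with path antecedents", {
  # degenerate single-leaf tree gives one catch-all rule
  parts <- list(x = strong_partition("x", c(0, 1)))
  pure <- cohort(data.frame(x = c(0.2, 0.8)), c(1, 1))
  rb0 <- extract_rules(build_fuzzy_tree(pure, parts))
  expect_equal(length(rb0), 1L)
  expect_equal(nrow(rb0$rules[[1]]$antecedents), 0L)
  expect_equal(rule_activation(rb0$rules[[1]], c(x = 0.33), parts), 1)
  # leaf count equals rule count on a real tree
  fx <- make_crisp_fixture(n = 150)
  tree <- build_fuzzy_tree(fx$cohort, fx$partitions,
                           tree_config(min_gain = 1e-9,
                                       min_num_examples = 1))
  count_leaves <- function(n) if (n$kind == "leaf") 1L else
    sum(vapply(n$children, count_leaves, integer(1)))
  expect_equal(length(extract_rules(tree)), count_leaves(tree$root))
  # the linguistic rendering follows the IF ... THEN p is k[...] format
  rb <- six_rules_fixture()
  expect_match(format_rule(rb$rules[[4]], 4),
               "^Rule 4: If MAP is H, then p is 1\\[0\\.48 0\\.52\\]$")
  expect_match(format_rule(rb$rules[[6]]),
               "If MAP is H and BMI is M and age is L, then p is 1")
})

test_that("fuzzy mass is conserved across a strong-partition split", {
  set.seed(14)
  p <- strong_partition("x", c(0, 0.3, 0.7, 1))
  x <- runif(200)
  w <- runif(200)            # arbitrary parent memberships
  m <- partition_membership(p, x)
  prod_children <- sweep(m, 1, w, `*`)
  expect_equal(sum(prod_children), sum(w), tolerance = 1e-9)
  # minimum t-norm conserves mass in the crisp limit
  xc <- sample(p$anchors, 200, TRUE)
  mc <- partition_membership(p, xc)
  wc <- as.numeric(runif(200) < 0.8)
  min_children <- pmin(mc, matrix(wc, 200, 4))
  expect_lte(sum(min_children), sum(wc) + 1e-9)
})

test_that("the crisp limit reproduces a textbook decision tree", {
  fx <- make_crisp_fixture(n = 180, n_feat = 3, k = 3, seed = 77)
  cfg <- tree_config(max_depth = 15, min_num_examples = 1,
                     min_gain = 1e-6)
  tree <- build_fuzzy_tree(fx$cohort, fx$partitions, cfg)
  oracle <- id3_build(fx$X, fx$y, max_depth = 15, min_n = 1, eps = 1e-6)
  count_leaves <- function(n) if (n$kind == "leaf") 1L else
    sum(vapply(n$children, count_leaves, integer(1)))
  expect_equal(count_leaves(tree$root), id3_count_leaves(oracle))
  rb <- extract_rules(tree)
  for (i in seq_len(nrow(fx$X))) {
    got <- classify(rb, fx$X[i, ], defuzz = "none")
    want <- id3_predict_dist(oracle, as.list(fx$X[i, ]))
    # on crisp inputs exactly one rule fires at degree 1, so the class
    # scores are the leaf distribution times its confidence weight
    expect_equal(as.numeric(got$class_scores) / sum(got$class_scores),
                 want, tolerance = 1e-9)
  }
})
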