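test_that("rule activation follows the t-norm over antecedent memberships", {
  rb <- six_rules_fixture()
  parts <- rb$partitions
  # at the antecedent peaks the activation is exactly 1
  r6 <- rb$rules[[6]]   # MAP H, BMI M, age L
  at_peaks <- c(MAP = 133.33, BMI = 30.27, age = 26.4)
  expect_equal(rule_activation(r6, at_peaks, parts), 1)
  # any zero membership annihilates the conjunction
  expect_equal(rule_activation(r6, c(MAP = 61.67, BMI = 30.27, age = 26.4),
                               parts), 0)
  # minimum vs product on intermediate degrees
  r2 <- rb$rules[[2]]   # MAP L, BMI L
  x <- c(MAP = 95, BMI = 25)
  mu_map <- membership(parts$MAP$sets[["L"]], 95)
  mu_bmi <- membership(parts$BMI$sets[["L"]], 25)
  expect_equal(rule_activation(r2, x, parts, "minimum"),
               min(mu_map, mu_bmi))
  expect_equal(rule_activation(r2, x, parts, "product"), mu_map * mu_bmi)
  # missing antecedent value: zero by default, error on request
  expect_equal(rule_activation(r2, c(MAP = 95), parts), 0)
  expect_error(rule_activation(r2, c(MAP = 95), parts,
                               missing_policy = "error"), "missing")
})

test_that("classify decides, abstains outside support, and abstains on ties", {
  parts <- list(x = strong_partition("x", c(0, 1, 2)))
  rb <- rule_base(list(
    fuzzy_rule(data.frame(feature = "x", term = "L"), c(1, 0)),
    fuzzy_rule(data.frame(feature = "x", term = "H"), c(0, 1))),
    parts, class_labels = c("No-PE", "PE"))
  r <- classify(rb, c(x = 0))
  expect_equal(r$decision, "0")
  expect_equal(as.numeric(r$class_scores), c(1, 0))
  # no support: the boundary sets are shouldered, so force a zero-rule base
  rb1 <- rule_base(list(
    fuzzy_rule(data.frame(feature = "x", term = "M"),
               c(0.5, 0.5))),
    list(x = strong_partition("x", c(0, 1, 2), c("L", "M", "H"))))
  r2 <- classify(rb1, c(x = 0))   # membership of M at 0 is 0
  expect_equal(r2$decision, "ABSTAIN")
  expect_true(all(r2$activations == 0))
  # exactly balanced evidence abstains rather than guessing
  rb_tie <- rule_base(list(
    fuzzy_rule(data.frame(feature = "x", term = "L"), c(1, 0)),
    fuzzy_rule(data.frame(feature = "x", term = "L"), c(0, 1))),
    parts)
  r4 <- classify(rb_tie, c(x = 0.2))
  expect_equal(r4$decision, "ABSTAIN")
  expect_error(classify(rule_base(list(), parts), c(x = 0)), "empty")
})

test_that("aggregation clips the class output sets and combines them", {
  parts <- list(x = strong_partition("x", c(0, 1)))
  rb <- rule_base(list(fuzzy_rule(data.frame(feature = "x", term = "L"),
                                  c(1, 0))), parts)
  res <- classify(rb, c(x = 0), defuzz = "none")
  agg <- aggregate_output(res)
  # one active class at full strength: the curve is that class's set
  expect_equal(agg$mu, membership(fuzzy_set("No-PE", 0, 0, 1), agg$x))
  # no activation gives a zero curve
  res0 <- classify(rb, c(x = 5), defuzz = "none")  # outside: shoulder -> 0?
  res0$class_scores[] <- 0
  expect_true(all(aggregate_output(res0)$mu == 0))
  # mixed strengths under max = pointwise max of the clipped sets
  res2 <- res
  res2$class_scores <- c(`No-PE` = 0.4, PE = 0.6)
  agg2 <- aggregate_output(res2)
  manual <- pmax(pmin(0.4, 1 - agg2$x), pmin(0.6, agg2$x))
  expect_equal(agg2$mu, manual)
})

test_that("defuzzification matches closed forms and a fine-grid oracle", {
  x <- seq(0, 1, length.out = 2001)
  tri <- pmax(0, 1 - abs(x - 0.5) / 0.3)
  expect_equal(defuzzify(x, tri, "centroid"), 0.5, tolerance = 1e-9)
  expect_equal(defuzzify(x, tri, "bisector"), 0.5, tolerance = 1e-3)
  rect <- as.numeric(x >= 0.2 & x <= 0.6)
  expect_equal(defuzzify(x, rect, "centroid"), 0.4, tolerance = 1e-3)
  expect_equal(defuzzify(x, rect, "bisector"), 0.4, tolerance = 1e-3)
  expect_true(is.na(defuzzify(x, rep(0, length(x)))))
  # asymmetric two-lobe curve vs a 1e5-point quadrature oracle
  lobes <- function(x) pmax(pmin(0.8, pmax(0, 1 - abs(x - 0.25) / 0.2)),
                            pmin(0.5, pmax(0, 1 - abs(x - 0.75) / 0.15)))
  xf <- seq(0, 1, length.out = 100001)
  oracle <- sum(xf * lobes(xf)) / sum(lobes(xf))   # Riemann on fine grid
  expect_equal(defuzzify(x, lobes(x), "centroid"), oracle,
               tolerance = 1e-3)
})

test_that("crisp score agrees with score argmax beyond a 0.05 margin", {
  rb <- six_rules_fixture()
  set.seed(17)
  n_checked <- 0
  for (i in 1:200) {
    s <- c(MAP = runif(1, 61.67, 133.33), BMI = runif(1, 17.31, 43.4),
           age = runif(1, 18, 45.2))
    r <- classify(rb, s)
    if (r$decision == "ABSTAIN") next
    sh <- r$class_scores / sum(r$class_scores)
    if (abs(sh[2] - sh[1]) <= 0.05) next
    n_checked <- n_checked + 1
    expect_true(r$crisp_score >= 0 && r$crisp_score <= 1)
    expect_equal(as.character(as.integer(r$crisp_score > 0.5)), r$decision)
  }
  expect_gt(n_checked, 50)
})

test_that("PE score is monotone in MAP through the high region", {
  rb <- six_rules_fixture()
  for (bmi in c(22, 28, 34)) {
    for (age in c(22, 30)) {
      maps <- seq(101.09, 133.33, length.out = 40)
      pe <- vapply(maps, function(m)
        classify(rb, c(MAP = m, BMI = bmi, age = age),
                 defuzz = "none")$class_scores[2], numeric(1))
      expect_true(all(diff(pe) > -1e-9))
    }
  }
})

test_that("classification is deterministic", {
  rb <- six_rules_fixture()
  s <- c(MAP = 112, BMI = 29, age = 24)
  r1 <- classify(rb, s)
  r2 <- classify(rb, s)
  expect_identical(r1, r2)
})

test_that("explanations narrate fired rules, scores and abstentions", {
  rb <- six_rules_fixture()
  # a PE-leaning case: high MAP, medium BMI, low age
  s <- c(MAP = 120, BMI = 29, age = 24)
  r <- classify(rb, s)
  tx <- explain(rb, s, r)
  expect_true(any(grepl("MAP is H", tx)))
  expect_true(any(grepl("BMI is M", tx)))
  expect_true(any(grepl("age is L", tx)))
  expect_true(any(grepl("threshold", tx)))
  # abstention case
  rb1 <- rule_base(list(
    fuzzy_rule(data.frame(feature = "MAP", term = "M"), c(0.5, 0.5))),
    table9_partitions())
  s0 <- c(MAP = 61.67)
  r0 <- classify(rb1, s0)
  expect_match(explain(rb1, s0, r0), "[Nn]o rule activated")
  # single firing rule produces a one-line trace plus the decision line
  rb2 <- rule_base(list(
    fuzzy_rule(data.frame(feature = "MAP", term = "H"), c(0.2, 0.8))),
    table9_partitions())
  s2 <- c(MAP = 133.33)
  tx2 <- explain(rb2, s2, classify(rb2, s2))
  expect_length(tx2, 2L)
  expect_match(tx2[1], "If MAP is H")
})

test_that("rule bases round-trip through JSON", {
  rb <- six_rules_fixture()
  f <- withr::local_tempfile(fileext = ".json")
  write_rule_base(rb, f)
  back <- read_rule_base(f)
  expect_equal(length(back), length(rb))
  for (i in seq_along(rb$rules)) {
    expect_equal(back$rules[[i]]$antecedents, rb$rules[[i]]$antecedents)
    expect_equal(back$rules[[i]]$class_distribution,
                 rb$rules[[i]]$class_distribution)
  }
  s <- c(MAP = 112, BMI = 29, age = 24)
  expect_equal(classify(back, s)$class_scores,
               classify(rb, s)$class_scores)
})

test_that("rule invariants are enforced", {
  expect_error(fuzzy_rule(data.frame(feature = c("MAP", "MAP"),
                                     term = c("L", "H")), c(0.5, 0.5)),
               "distinct")
  expect_error(fuzzy_rule(data.frame(feature = "MAP", term = "L"),
                          c(0.7, 0.6)), "sum to 1")
  expect_error(rule_base(list(fuzzy_rule(
    data.frame(feature = "MAP", term = "XX"), c(1, 0))),
    table9_partitions()), "not in partition")
})
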