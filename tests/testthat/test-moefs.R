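test_that("total rule length counts antecedent conjuncts", {
  rb <- six_rules_fixture()           # antecedent sizes 2,2,1,1,3,3
  expect_equal(total_rule_length(rb), 12L)
  # an empty-antecedent rule contributes nothing
  rb0 <- rule_base(list(fuzzy_rule(
    data.frame(feature = character(), term = character()), c(1, 0))),
    table9_partitions())
  expect_equal(total_rule_length(rb0), 0L)
  # dropping rules never increases TRL
  for (i in seq_along(rb$rules)) {
    mask <- rep(TRUE, 6); mask[i] <- FALSE
    expect_lte(total_rule_length(rb, mask), total_rule_length(rb))
  }
})

test_that("solution evaluation reports accuracy, balance and feasibility", {
  parts <- list(x = strong_partition("x", c(0, 1)))
  rb <- rule_base(list(
    fuzzy_rule(data.frame(feature = "x", term = "L"), c(1, 0)),
    fuzzy_rule(data.frame(feature = "x", term = "H"), c(0, 1))),
    parts)
  # one always-correct rule covering every sample
  co1 <- cohort(data.frame(x = c(0, 0.1, 0.2)), c(0, 0, 0))
  ev1 <- evaluate_solution(c(TRUE, FALSE), rb, co1)
  expect_equal(ev1$performance, 1)
  # full mask equals the unreduced rule base's accuracy
  co2 <- cohort(data.frame(x = c(0, 0, 1, 0)), c(0, 0, 1, 1))
  full <- evaluate_solution(c(TRUE, TRUE), rb, co2)
  pred <- predict_cohort(rb, co2)
  expect_equal(full$performance, mean(pred == co2$outcome))
  # balanced metric on TP=1 FN=1 TN=2 FP=0 is (0.5 + 1)/2
  bal <- evaluate_solution(c(TRUE, TRUE), rb, co2, metric = "balanced")
  expect_equal(bal$performance, 0.75)
  # empty masks are infeasible
  expect_false(evaluate_solution(c(FALSE, FALSE), rb, co2)$feasible)
})

test_that("non-dominated sorting matches a brute-force oracle", {
  # degenerate single solution
  ns1 <- nondominated_sort(0.8, 5)
  expect_equal(ns1$fronts[[1]], 1L)
  # strict domination pair
  ns2 <- nondominated_sort(c(0.9, 0.8), c(5, 7))
  expect_equal(ns2$rank, c(0L, 1L))
  # 50 random solutions vs O(n^2) enumeration
  set.seed(23)
  perf <- round(runif(50), 2)
  trl <- sample(1:30, 50, TRUE)
  ns <- nondominated_sort(perf, trl)
  expect_setequal(ns$fronts[[1]], brute_force_front(perf, trl))
  # peeled fronts partition the solutions
  expect_setequal(unlist(ns$fronts), 1:50)
})

test_that("the GA front is deterministic and respects elitism", {
  sc <- make_separable_cohort(60, seed = 5)
  fc_parts <- lapply(feature_names(sc), function(f) {
    rng <- range(sc$data[[f]])
    strong_partition(f, seq(rng[1], rng[2], length.out = 3))
  })
  names(fc_parts) <- feature_names(sc)
  rb <- extract_rules(build_fuzzy_tree(sc, fc_parts))
  cfg <- ga_config(population_size = 16, generations = 8, seed = 11)
  f1 <- evolve(rb, sc, cfg)
  f2 <- evolve(rb, sc, cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  # the full mask is in the initial population, so elitism guarantees the
  # final best performance is at least the unreduced rule base's
  full_perf <- evaluate_solution(rep(TRUE, length(rb)), rb, sc,
                                 metric = "balanced")$performance
  expect_gte(max(f1$performance), full_perf - 1e-12)
  # generations = 0 returns the non-dominated set of the initial population
  f0 <- evolve(rb, sc, ga_config(population_size = 8, generations = 0,
                                 seed = 11))
  expect_s3_class(f0, "pareto_front")
  expect_gte(nrow(f0), 1)
})

test_that("duplicated rules are pruned without losing performance", {
  sc <- make_separable_cohort(60, seed = 6)
  parts <- lapply(feature_names(sc), function(f) {
    rng <- range(sc$data[[f]])
    strong_partition(f, seq(rng[1], rng[2], length.out = 3))
  })
  names(parts) <- feature_names(sc)
  rb <- extract_rules(build_fuzzy_tree(sc, parts))
  dup <- rule_base(c(rb$rules, rb$rules), rb$partitions, rb$class_labels)
  front <- evolve(dup, sc, ga_config(population_size = 24,
                                     generations = 15, seed = 7))
  full_perf <- evaluate_solution(rep(TRUE, length(dup)), dup, sc,
                                 metric = "balanced")$performance
  full_trl <- total_rule_length(dup)
  hit <- any(front$performance >= full_perf - 1e-12 &
               front$trl < full_trl)
  expect_true(hit)
})

test_that("first/median/last selection orders the front trade-off", {
  sc <- make_separable_cohort(80, seed = 8)
  parts <- lapply(feature_names(sc), function(f) {
    rng <- range(sc$data[[f]])
    strong_partition(f, seq(rng[1], rng[2], length.out = 3))
  })
  names(parts) <- feature_names(sc)
  rb <- extract_rules(build_fuzzy_tree(sc, parts))
  front <- evolve(rb, sc, ga_config(population_size = 16,
                                    generations = 10, seed = 9))
  first <- select_solution(front, "first")
  med <- select_solution(front, "median")
  last <- select_solution(front, "last")
  expect_gte(attr(first, "performance"), attr(med, "performance"))
  expect_gte(attr(med, "performance"), attr(last, "performance"))
  expect_lte(attr(last, "trl"), attr(med, "trl"))
  expect_lte(attr(med, "trl"), attr(first, "trl"))
  # single-element front: all selectors agree; 3 elements: median is 2nd
  one <- front[1, , drop = FALSE]
  attr(one, "masks") <- attr(front, "masks")[1]
  attr(one, "rulebase") <- attr(front, "rulebase")
  class(one) <- class(front)
  expect_equal(attr(select_solution(one, "median"), "trl"), one$trl[1])
  if (nrow(front) >= 3) {
    three <- front[1:3, , drop = FALSE]
    attr(three, "masks") <- attr(front, "masks")[1:3]
    attr(three, "rulebase") <- attr(front, "rulebase")
    class(three) <- class(front)
    expect_equal(attr(select_solution(three, "median"), "trl"),
                 three$trl[2])
  }
})
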