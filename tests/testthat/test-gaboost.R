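test_that("the thresholded decision rule resolves qualifiers as documented", {
  expect_equal(decide(c(0.2, 0.7, 0.5), c(0, 0, 0)), 2)     # plain argmax
  expect_equal(decide(c(0.9, 0.2), c(0.95, 0.1)), 2)        # only class 2 qualifies
  expect_equal(decide(c(0.4, 0.3), c(0.9, 0.9)), 1)         # fallback argmax
  expect_equal(decide(c(0.6, 0.6), c(0.1, 0.1)), 1)         # tie -> lowest index
  # raw rule ranks qualifiers by probability, not margin
  expect_equal(decide(c(0.6, 0.5), c(0.55, 0.1), rule = "margin"), 2)
  expect_equal(decide(c(0.6, 0.5), c(0.55, 0.1), rule = "raw"), 1)
  expect_error(decide(c(0.5, 0.5), c(0.5)), "lengths")
})

test_that("additive mod-1 crossover matches hand arithmetic and stays in [0,1)", {
  kids <- ga_crossover(0.3, 0.4)
  expect_equal(kids[[1]], (0.3 + 0.8) %% 1)   # 0.1
  expect_equal(kids[[2]], (0.6 + 0.4) %% 1)   # 0.0
  expect_equal(ga_crossover(0, 0), list(0, 0))
  set.seed(2)
  for (i in 1:20) {
    x <- runif(4); y <- runif(4)
    kids <- ga_crossover(x, y)
    expect_true(all(kids[[1]] >= 0 & kids[[1]] < 1))
    expect_true(all(kids[[2]] >= 0 & kids[[2]] < 1))
    # algebraic identity: (X + Y) mod 1 == 3(x + y) mod 1
    expect_equal((kids[[1]] + kids[[2]]) %% 1, (3 * (x + y)) %% 1,
                 tolerance = 1e-12)
  }
  expect_error(ga_crossover(c(0.1, 0.2), 0.3), "lengths")
})

test_that("mutation resamples genes at the requested rate", {
  t <- seq(0.05, 0.95, length.out = 10)
  set.seed(1)
  expect_identical(ga_mutate(t, 0), t)
  mut <- ga_mutate(t, 1)
  expect_true(all(mut != t))
  set.seed(3)
  frac <- mean(replicate(400, mean(ga_mutate(t, 0.2) != t)))
  expect_equal(frac, 0.2, tolerance = 0.05)
  expect_error(ga_mutate(t, 1.5), "rate")
})

test_that("fitness is macro F1 of thresholded decisions", {
  pm <- make_probability_matrix(15, c(a = 0.5, b = 0.5), separation = 50, seed = 2)
  expect_equal(ga_fitness(c(0.5, 0.5), pm$probs, pm$labels), 1)
  # thresholds forcing a constant prediction: closed-form macro F1
  probs <- cbind(rep(0.9, 10), rep(0.1, 10))
  labels <- rep(1:2, each = 5)
  f1_const <- ga_fitness(c(0, 0.99), probs, labels)
  expect_equal(f1_const, (2 * 5 / (2 * 5 + 5) + 0) / 2)   # all predicted class 1
  # invariance to a consistent permutation of class columns
  pm4 <- make_probability_matrix(10, c(a = 0.3, b = 0.5, c = 0.7), seed = 4)
  perm <- c(3, 1, 2)
  t <- c(0.25, 0.45, 0.65)
  f_orig <- ga_fitness(t, pm4$probs, pm4$labels)
  f_perm <- ga_fitness(t[perm], pm4$probs[, perm], match(pm4$labels, perm))
  expect_equal(f_orig, f_perm)
})

test_that("the GA beats its fixed-threshold baseline with a monotone history", {
  planted <- c(a = 0.35, b = 0.55, c = 0.7)
  for (seed in 1:3) {
    pm <- make_probability_matrix(20, planted, separation = 6, seed = seed)
    res <- run_gaboost(pm$probs, pm$labels, ga_config(seed = seed))
    base <- ga_fitness(rep(0.5, 3), pm$probs, pm$labels)
    expect_gte(res$fitness, base)
    expect_false(is.unsorted(res$history))
    expect_length(res$history, 20)
    expect_true(all(res$thresholds >= 0 & res$thresholds < 1))
    res2 <- run_gaboost(pm$probs, pm$labels, ga_config(seed = seed))
    expect_identical(res2$thresholds, res$thresholds)   # seed reproducibility
  }
  expect_error(run_gaboost(matrix(0.5, 4, 2), rep(1L, 4), ga_config()),
               "single class|degenerate")
})

test_that("learned thresholds recover the planted ones (raw rule, 10-seed median)", {
  planted <- c(a = 0.3, b = 0.5, c = 0.7, d = 0.6)
  errs <- vapply(1:10, function(s) {
    pm <- make_probability_matrix(30, planted, separation = 10, seed = s,
                                  rule = "raw")
    res <- run_gaboost(pm$probs, pm$labels,
                       ga_config(seed = s + 50, rule = "raw"))
    abs(res$thresholds - planted)
  }, numeric(4))
  expect_true(all(apply(errs, 1, stats::median) <= 0.1))
})
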