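test_that("activation primitives satisfy their identities", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(2.5), 2.5)
  expect_equal(sigmoid(0), 0.5)
  x <- seq(-5, 5, by = 0.5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
})

test_that("forward pass equals hand arithmetic and the matrix oracle", {
  # 2-2-2 toy net with hand-set weights
  params <- list(W1 = matrix(c(1, 0, -1, 2), 2, 2), B1 = c(0.5, -0.5),
                 W2 = matrix(c(2, 1, 0, -1), 2, 2), B2 = c(0, 1),
                 W3 = matrix(c(1, -1, 0.5, 0.5), 2, 2), B3 = c(-1, 2))
  x <- c(0.2, 0.8)
  # hand evaluation of sigma(W3' relu(W2' relu(W1' x + B1) + B2) + B3)
  a1 <- pmax(c(1 * 0.2 + 0 * 0.8 + 0.5, -1 * 0.2 + 2 * 0.8 - 0.5), 0)  # (0.7, 0.9)
  a2 <- pmax(c(2 * a1[1] + 1 * a1[2] + 0, 0 * a1[1] - 1 * a1[2] + 1), 0) # (2.3, 0.1)
  z3 <- c(1 * a2[1] - 1 * a2[2] - 1, 0.5 * a2[1] + 0.5 * a2[2] + 2)
  expect_equal(net_forward(params, x), 1 / (1 + exp(-z3)), tolerance = 1e-12)
  # zero weights and biases: every output 0.5
  zero <- lapply(params, function(p) p * 0)
  expect_equal(net_forward(zero, x), c(0.5, 0.5))
  expect_error(net_forward(params, c(1, 2, 3)), "mismatch")
  # random small nets vs the independent explicit-arithmetic oracle
  set.seed(4)
  for (i in 1:5) {
    p <- list(W1 = matrix(rnorm(12), 3, 4), B1 = rnorm(4),
              W2 = matrix(rnorm(20), 4, 5), B2 = rnorm(5),
              W3 = matrix(rnorm(10), 5, 2), B3 = rnorm(2))
    x <- runif(3)
    expect_equal(net_forward(p, x), naive_forward(p, x), tolerance = 1e-10)
    expect_true(all(net_forward(p, x) > 0 & net_forward(p, x) < 1))
  }
})

test_that("optimizer step follows the printed update exactly", {
  hyper <- nadam_hyper(eta = 0.1, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  p <- list(w = 1)
  st <- nadam_state(p)
  # zero gradient, zero moments: parameters unchanged
  out <- nadam_step(p, list(w = 0), st, hyper)
  expect_equal(out$params$w, 1)
  # single scalar step, g = 1, t = 1: hand-evaluated update
  out <- nadam_step(p, list(w = 1), st, hyper)
  # m=0.1, v=0.001, m_hat=1, v_hat=1;
  # update = 0.1/(1+1e-8) * (0.9*1 + 0.1*1/0.1 + (0.9*0.999/0.1)*0.1) = 0.27991
  expect_equal(out$params$w, 1 - 0.1 / (1 + 1e-8) * 2.7991, tolerance = 1e-10)
  expect_error(nadam_step(p, list(w = NaN), st, hyper), "non-finite")
})

test_that("vectorized optimizer matches the scalar oracle on a quadratic", {
  # minimize (theta - 3)^2 / 2; gradient theta - 3
  hyper <- nadam_hyper(eta = 0.05)
  p <- list(th = 0)
  st <- nadam_state(p)
  for (i in 1:10) {
    out <- nadam_step(p, list(th = p$th - 3), st, hyper)
    p <- out$params; st <- out$state
  }
  oracle <- naive_nadam_scalar(0, function(th) th - 3, 0.05, 0.9, 0.999, 1e-8, 10)
  expect_equal(p$th, oracle, tolerance = 1e-6)
  expect_gt(p$th, 0)   # moved toward the minimum
})

test_that("training solves a separable toy problem deterministically", {
  toy <- toy_features(15, K = 2, d = 4, sep = 4, seed = 2)
  cfg <- net_config(out_units = 2, epochs = 100, seed = 7)
  net <- train_net(toy$X, toy$y, cfg)
  probs <- predict_proba(net, toy$X)
  expect_identical(dim(probs), c(30L, 2L))
  expect_true(all(probs > 0 & probs < 1))
  pred <- net$classes[apply(probs, 1, which.max)]
  expect_equal(mean(pred == toy$y), 1)               # training accuracy 1.0
  expect_lte(net$loss[length(net$loss)], net$loss[1]) # loss decreased
  net2 <- train_net(toy$X, toy$y, cfg)
  expect_identical(net$params, net2$params)           # seed reproducibility
  expect_error(train_net(toy$X, rep("a", 30), net_config(out_units = 2)),
               "2 classes")
})

test_that("tree baselines score feature sets sensibly", {
  toy <- toy_features(20, K = 3, d = 5, sep = 4, seed = 3)
  expect_equal(evaluate_feature_set(toy$X, toy$y, "decision_tree"), 1)
  set.seed(9)
  shuf <- sample(toy$y)
  f1_shuf <- mean(vapply(1:5, function(s)
    evaluate_feature_set(toy$X, shuf, "decision_tree", seed = s), numeric(1)))
  expect_lt(f1_shuf, 0.62)   # near the permutation baseline, far below signal
  # random forest at least matches the single tree on a noisy problem for
  # the majority of split seeds
  noisy <- toy_features(20, K = 3, d = 8, sep = 1.1, seed = 5)
  wins <- vapply(1:5, function(s) {
    rf <- evaluate_feature_set(noisy$X, noisy$y, "random_forest", seed = s)
    dt <- evaluate_feature_set(noisy$X, noisy$y, "decision_tree", seed = s)
    rf >= dt
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("random-combination feature selection returns the argmax subset", {
  toy <- toy_features(15, K = 2, d = 6, sep = 3, seed = 6)
  X <- toy$X
  attr(X, "spans") <- list(good = 1:3, noise = 4:6)
  sel <- select_features(X, toy$y, n_trials = 4, seed = 1)
  expect_true(all(sel$selected %in% c("good", "noise")))
  full_f1 <- sel$trace$f1[sel$trace$subset == "good+noise"]
  expect_gte(sel$f1, full_f1)          # argmax over candidates incl. full set
  sel2 <- select_features(X, toy$y, n_trials = 4, seed = 1)
  expect_identical(sel$selected, sel2$selected)
})
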