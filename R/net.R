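# The three-layer fusion classifier: two 64-unit ReLU layers and an
# independent-sigmoid output (one unit per class), trained on per-class
# binary cross-entropy with the Nadam-style optimizer. Output rows need
# not sum to 1 -- each column is that class's probability, which is what
# the per-class threshold stage consumes.

#' Rectified linear unit
#' @param x numeric.
#' @export
relu <- function(x) pmax(x, 0)  # argument order keeps dim/names of x

#' Logistic sigmoid
#' @param x numeric.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Optimizer hyperparameters
#' @param eta learning rate.
#' @param beta1,beta2 exponential decay rates for the moment estimates.
#' @param eps numerical stability constant.
#' @export
nadam_hyper <- function(eta = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(eta = eta, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' Fresh optimizer state for a parameter list
#' @param params named list of numeric arrays.
#' @export
nadam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Nadam-style update step
#'
#' Updates biased first/second moments and applies the update
#' `theta <- theta - eta / (sqrt(v_hat) + eps) *
#'   (beta1 * m_hat + (1 - beta1) g / (1 - beta1^t) +
#'    beta1 * beta2 / (1 - beta1^t) * m)`,
#' with `m_hat = m / (1 - beta1^t)` and `v_hat = v / (1 - beta2^t)`.
#' Note the third momentum term: this follows the printed formulation
#' this package reproduces, which is heavier on momentum than textbook
#' Nadam.
#'
#' @param params named list of numeric arrays.
#' @param grads matching named list of gradients.
#' @param state optimizer state from [nadam_state()].
#' @param hyper from [nadam_hyper()].
#' @return list with updated `params` and `state`.
#' @export
nadam_step <- function(params, grads, state, hyper = nadam_hyper()) {
  if (!all(names(params) %in% names(grads)))
    stop("parameter/gradient name mismatch", call. = FALSE)
  if (any(vapply(grads, function(g) any(!is.finite(g)), logical(1))))
    stop("non-finite gradient", call. = FALSE)
  t <- state$t + 1L
  b1 <- hyper$beta1; b2 <- hyper$beta2
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    m <- b1 * state$m[[nm]] + (1 - b1) * g
    v <- b2 * state$v[[nm]] + (1 - b2) * g^2
    m_hat <- m / bc1
    v_hat <- v / bc2
    upd <- hyper$eta / (sqrt(v_hat) + hyper$eps) *
      (b1 * m_hat + (1 - b1) * g / bc1 + (b1 * b2 / bc1) * m)
    params[[nm]] <- params[[nm]] - upd
    state$m[[nm]] <- m
    state$v[[nm]] <- v
  }
  state$t <- t
  list(params = params, state = state)
}

#' Network configuration
#'
#' Defaults: two hidden layers of 64 ReLU units, sigmoid output with one
#' unit per class, 100 epochs, Nadam-style optimizer defaults.
#'
#' @param out_units number of classes (>= 2).
#' @param hidden1,hidden2 hidden layer widths.
#' @param epochs training epochs (>= 1).
#' @param eta,beta1,beta2,eps optimizer hyperparameters.
#' @param loss `"bce"` (per-class binary cross-entropy, the default
#'   matching independent sigmoids) or `"softmax"` cross-entropy.
#' @param seed integer seed.
#' @export
net_config <- function(out_units, hidden1 = 64L, hidden2 = 64L, epochs = 100L,
                       eta = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       loss = c("bce", "softmax"), seed = 0L) {
  if (out_units < 2L) stop("out_units must be >= 2", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  list(hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
       out_units = as.integer(out_units), epochs = as.integer(epochs),
       hyper = nadam_hyper(eta, beta1, beta2, eps),
       loss = match.arg(loss), seed = as.integer(seed))
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

net_forward_matrix <- function(params, X) {
  A1 <- relu(sweep(X %*% params$W1, 2, params$B1, "+"))
  A2 <- relu(sweep(A1 %*% params$W2, 2, params$B2, "+"))
  Z3 <- sweep(A2 %*% params$W3, 2, params$B3, "+")
  list(A1 = A1, A2 = A2, Z3 = Z3, Y = sigmoid(Z3))
}

#' Forward pass of the three-layer network for one feature vector
#'
#' `Y = sigmoid(W3' relu(W2' relu(W1' x + B1) + B2) + B3)`; outputs lie
#' strictly inside (0, 1).
#'
#' @param net a trained `endo_net` (or a bare parameter list with
#'   `W1..W3`, `B1..B3`).
#' @param x feature vector scaled to \[0, 1\].
#' @return per-class probability vector.
#' @export
net_forward <- function(net, x) {
  params <- if (inherits(net, "endo_net")) net$params else net
  if (length(x) != nrow(params$W1))
    stop("feature dimension mismatch", call. = FALSE)
  drop(net_forward_matrix(params, matrix(x, 1))$Y)
}

#' Train the three-layer classifier
#'
#' Full-batch training for `config$epochs` epochs on per-class binary
#' cross-entropy (or softmax cross-entropy) with the Nadam-style
#' optimizer; deterministic per `config$seed`.
#'
#' @param features n x d matrix scaled to \[0, 1\].
#' @param labels factor/character/integer class labels (>= 2 classes).
#' @param config a [net_config()]; `out_units` must equal the number of
#'   classes.
#' @return an `endo_net` with elements `params`, `classes`, `loss`
#'   (per-epoch curve) and `config`.
#' @export
train_net <- function(features, labels, config = NULL) {
  classes <- sort(unique(as.character(labels)))
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(config)) config <- net_config(out_units = K)
  if (config$out_units != K)
    stop("config$out_units (", config$out_units, ") != number of classes (", K, ")",
         call. = FALSE)
  X <- as.matrix(features)
  Y <- outer(as.character(labels), classes, `==`) * 1.0
  n <- nrow(X); d <- ncol(X)
  withr_seed(config$seed, {
    params <- list(W1 = glorot(d, config$hidden1), B1 = rep(0, config$hidden1),
                   W2 = glorot(config$hidden1, config$hidden2), B2 = rep(0, config$hidden2),
                   W3 = glorot(config$hidden2, K), B3 = rep(0, K))
    state <- nadam_state(params)
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      fw <- net_forward_matrix(params, X)
      P <- pmin(pmax(fw$Y, 1e-12), 1 - 1e-12)
      if (config$loss == "bce") {
        loss <- -mean(Y * log(P) + (1 - Y) * log(1 - P))
        dZ3 <- (fw$Y - Y) / (n * K)
      } else {
        E <- exp(fw$Z3 - apply(fw$Z3, 1, max))
        S <- E / rowSums(E)
        loss <- -mean(log(pmax(S[Y == 1], 1e-12)))
        dZ3 <- (S - Y) / n
      }
      if (!is.finite(loss))
        stop("training aborted: non-finite loss at epoch ", ep,
             " (eta=", config$hyper$eta, ")", call. = FALSE)
      losses[ep] <- loss
      g <- list()
      g$W3 <- crossprod(fw$A2, dZ3); g$B3 <- colSums(dZ3)
      dA2 <- dZ3 %*% t(params$W3) * (fw$A2 > 0)
      g$W2 <- crossprod(fw$A1, dA2); g$B2 <- colSums(dA2)
      dA1 <- dA2 %*% t(params$W2) * (fw$A1 > 0)
      g$W1 <- crossprod(X, dA1); g$B1 <- colSums(dA1)
      st <- nadam_step(params, g, state, config$hyper)
      params <- st$params; state <- st$state
    }
    structure(list(params = params, classes = classes, loss = losses,
                   config = config),
              class = "endo_net")
  })
}

#' Per-class probability matrix for a feature matrix
#'
#' One row per sample, one column per class (named), values strictly in
#' (0, 1); rows do not sum to 1 (independent sigmoids).
#'
#' @param net an `endo_net`.
#' @param features n x d matrix scaled like the training features.
#' @export
predict_proba <- function(net, features) {
  stopifnot(inherits(net, "endo_net"))
  X <- as.matrix(features)
  P <- net_forward_matrix(net$params, X)$Y
  P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
  colnames(P) <- net$classes
  P
}
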