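# Deep feature extraction: a MobileNet-V2 style backbone implemented in
# base R (im2col + BLAS matrix products for regular/pointwise
# convolutions, shifted slices for depthwise convolutions). The
# classification head is truncated; the pooled output of the final 1x1
# convolution is the 1,280-dimensional deep feature. With random weights
# the architecture -- and hence every dimension contract -- is identical
# to the pretrained network, which is what the offline tests exercise.

MOBILENETV2_BLOCKS <- list(
  # expansion factor t, output channels c, repeats n, first stride s
  c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
  c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))

relu6 <- function(x) pmin(pmax(x, 0), 6)

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

conv3x3 <- function(x, wmat, bias, stride = 1L) {
  d <- dim(x)
  cin <- d[3]
  xp <- pad1(x)
  rs <- seq(1L, d[1], by = stride)
  cs <- seq(1L, d[2], by = stride)
  oh <- length(rs); ow <- length(cs)
  X <- matrix(0, oh * ow, 9L * cin)
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    sl <- xp[rs + dy, cs + dx, , drop = FALSE]
    X[, (k * cin + 1L):((k + 1L) * cin)] <- matrix(sl, oh * ow, cin)
    k <- k + 1L
  }
  y <- X %*% wmat
  y <- sweep(y, 2, bias, "+")
  array(y, dim = c(oh, ow, ncol(wmat)))
}

dwconv3x3 <- function(x, w, bias, stride = 1L) {
  # w is a 3 x 3 x C array, one 3x3 filter per channel
  d <- dim(x)
  xp <- pad1(x)
  rs <- seq(1L, d[1], by = stride)
  cs <- seq(1L, d[2], by = stride)
  oh <- length(rs); ow <- length(cs)
  out <- array(0, dim = c(oh, ow, d[3]))
  for (dy in 0:2) for (dx in 0:2) {
    sl <- xp[rs + dy, cs + dx, , drop = FALSE]
    out <- out + sweep(sl, 3, w[dy + 1L, dx + 1L, ], "*")
  }
  sweep(out, 3, bias, "+")
}

pwconv <- function(x, w, bias) {
  d <- dim(x)
  y <- matrix(x, d[1] * d[2], d[3]) %*% w
  y <- sweep(y, 2, bias, "+")
  array(y, dim = c(d[1], d[2], ncol(w)))
}

he_mat <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

#' Extractor configuration
#'
#' @param input_size spatial input size (square), default 224.
#' @param width_multiplier channel width multiplier; only 1.0 is
#'   supported.
#' @param weights `"random"` (seeded He initialization, the offline test
#'   surface) or `"pretrained"` (requires `weights_file`).
#' @param weights_file optional RDS file of weights saved by
#'   [save_extractor()].
#' @param seed seed for random weights.
#' @export
extractor_config <- function(input_size = 224L, width_multiplier = 1.0,
                             weights = c("random", "pretrained"),
                             weights_file = NULL, seed = 0L) {
  weights <- match.arg(weights)
  if (width_multiplier != 1.0)
    stop("unsupported width_multiplier (only 1.0)", call. = FALSE)
  list(input_size = as.integer(input_size), width_multiplier = width_multiplier,
       weights = weights, weights_file = weights_file, seed = as.integer(seed))
}

#' Build the truncated deep feature extractor
#'
#' Assembles the MobileNet-V2 topology (stem 3x3 stride-2 convolution,
#' seven inverted-residual stages, final 1x1 convolution to 1,280
#' channels, global average pool) plus the detachable 1,000-way
#' classification head. The pooled 1,280-vector is the deep feature.
#'
#' @param config an [extractor_config()].
#' @return an `endo_extractor`.
#' @export
build_extractor <- function(config = extractor_config()) {
  if (config$weights == "pretrained") {
    if (is.null(config$weights_file) || !file.exists(config$weights_file %||% ""))
      stop("pretrained weights require a local weights_file ",
           "(no download is possible offline)", call. = FALSE)
    wt <- readRDS(config$weights_file)
    return(structure(list(config = config, weights = wt), class = "endo_extractor"))
  }
  wt <- withr_seed(config$seed, {
    w <- list()
    w$stem <- list(w = he_mat(9L * 3L, 32L), b = stats::rnorm(32, 0, 0.01))
    cin <- 32L
    blocks <- list()
    for (bs in MOBILENETV2_BLOCKS) {
      t <- bs[1]; cout <- as.integer(bs[2]); n <- bs[3]; s <- bs[4]
      for (rep_i in seq_len(n)) {
        stride <- if (rep_i == 1L) as.integer(s) else 1L
        exp_c <- as.integer(t * cin)
        blk <- list(stride = stride, cin = cin, cout = cout, expand = t != 1)
        if (t != 1) blk$pw1 <- list(w = he_mat(cin, exp_c), b = stats::rnorm(exp_c, 0, 0.01))
        blk$dw <- list(w = array(stats::rnorm(9L * exp_c, 0, sqrt(2 / 9)), c(3L, 3L, exp_c)),
                       b = stats::rnorm(exp_c, 0, 0.01))
        blk$pw2 <- list(w = he_mat(exp_c, cout), b = stats::rnorm(cout, 0, 0.01))
        blocks[[length(blocks) + 1L]] <- blk
        cin <- cout
      }
    }
    w$blocks <- blocks
    w$tail <- list(w = he_mat(320L, 1280L), b = stats::rnorm(1280, 0, 0.01))
    w$head <- list(w = he_mat(1280L, 1000L), b = rep(0, 1000))
    w
  })
  structure(list(config = config, weights = wt), class = "endo_extractor")
}

#' @export
print.endo_extractor <- function(x, ...) {
  cat(sprintf("<endo_extractor: MobileNet-V2 style, input %dx%d, %s weights>\n",
              x$config$input_size, x$config$input_size, x$config$weights))
  invisible(x)
}

# Forward through stem + inverted residual stages; returns the feature
# map before the final 1x1 convolution (H/32 x W/32 x 320).
backbone_forward <- function(ex, x) {
  wt <- ex$weights
  a <- relu6(conv3x3(x, wt$stem$w, wt$stem$b, stride = 2L))
  for (blk in wt$blocks) {
    inp <- a
    if (blk$expand) a <- relu6(pwconv(a, blk$pw1$w, blk$pw1$b))
    a <- relu6(dwconv3x3(a, blk$dw$w, blk$dw$b, stride = blk$stride))
    a <- pwconv(a, blk$pw2$w, blk$pw2$b)   # linear bottleneck
    if (blk$stride == 1L && blk$cin == blk$cout) a <- a + inp
  }
  a
}

frame_to_input <- function(frame, size) {
  px <- resize_bilinear(frame$pixels * 1.0, size, size) / 255
  px * 2 - 1   # the backbone's published [-1, 1] preprocessing
}

#' Deep feature vector for one frame
#'
#' The frame is resized to the extractor's input size, normalized to
#' \[-1, 1\], passed through the truncated backbone and globally
#' average-pooled to a 1,280-length vector. Scale with the feature-bank
#' scaler before fusion.
#'
#' @param ex an `endo_extractor`.
#' @param frame an `endo_frame`.
#' @return numeric vector of length 1280.
#' @export
deep_features <- function(ex, frame) {
  stopifnot(inherits(ex, "endo_extractor"))
  x <- frame_to_input(frame, ex$config$input_size)
  fm <- backbone_forward(ex, x)
  a <- relu6(pwconv(fm, ex$weights$tail$w, ex$weights$tail$b))
  d <- dim(a)
  colMeans(matrix(a, d[1] * d[2], d[3]))
}

#' Deep features for a list of frames (input order preserved)
#' @param ex an `endo_extractor`.
#' @param data an `endo_dataset` or list of frames.
#' @return matrix, one 1280-length row per frame.
#' @export
deep_features_matrix <- function(ex, data) {
  frames <- if (inherits(data, "endo_dataset")) data$frames else data
  do.call(rbind, lapply(frames, function(f) deep_features(ex, f)))
}

#' Untruncated 1,000-way head output
#'
#' The backbone's original classification output: softmax probabilities
#' over the 1,000 upstream classes.
#'
#' @param ex an `endo_extractor`.
#' @param frame an `endo_frame`.
#' @return numeric vector of length 1000 summing to 1.
#' @export
predict_head <- function(ex, frame) {
  f <- deep_features(ex, frame)
  z <- drop(f %*% ex$weights$head$w) + ex$weights$head$b
  e <- exp(z - max(z))
  e / sum(e)
}

#' Fine-tune the extractor on labeled frames
#'
#' Attaches a temporary sigmoid classification head, unfreezes the final
#' 1x1 convolution (320 to 1,280 channels) and trains both with the
#' Nadam-style optimizer on per-class binary cross-entropy; the head is
#' then detached. Earlier layers stay frozen, so their activations are
#' computed once and cached. Deterministic per seed; `epochs = 0` returns
#' the extractor unchanged.
#'
#' @param ex an `endo_extractor`.
#' @param data an `endo_dataset` with at least two classes.
#' @param epochs non-negative training epochs (default 10).
#' @param seed integer seed.
#' @param eta learning rate.
#' @return list with the updated `extractor` and the per-epoch `loss`
#'   curve.
#' @export
fine_tune <- function(ex, data, epochs = 10L, seed = 0L, eta = 1e-3) {
  stopifnot(inherits(ex, "endo_extractor"))
  labels <- vapply(data$frames, function(f) f$label, character(1))
  classes <- unique(labels)
  if (length(classes) < 2L) stop("fine-tuning needs >= 2 classes", call. = FALSE)
  if (epochs == 0L) return(list(extractor = ex, loss = numeric(0)))
  y <- outer(labels, classes, `==`) * 1.0
  K <- length(classes)
  maps <- lapply(data$frames, function(f) {
    fm <- backbone_forward(ex, frame_to_input(f, ex$config$input_size))
    d <- dim(fm)
    matrix(fm, d[1] * d[2], d[3])   # P x 320
  })
  P <- nrow(maps[[1]])
  W1 <- ex$weights$tail$w; b1 <- ex$weights$tail$b
  withr_seed(seed, {
    W2 <- he_mat(1280L, K) * 0.05
    b2 <- rep(0, K)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    state <- nadam_state(params)
    hyper <- nadam_hyper(eta = eta)
    losses <- numeric(epochs)
    n <- length(maps)
    for (ep in seq_len(epochs)) {
      g <- list(W1 = 0 * params$W1, b1 = 0 * params$b1,
                W2 = 0 * params$W2, b2 = 0 * params$b2)
      loss <- 0
      for (i in seq_len(n)) {
        Z <- sweep(maps[[i]] %*% params$W1, 2, params$b1, "+")
        A <- relu6(Z)
        f <- colMeans(A)
        logit <- drop(f %*% params$W2) + params$b2
        p <- 1 / (1 + exp(-logit))
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loss <- loss - mean(y[i, ] * log(p) + (1 - y[i, ]) * log(1 - p))
        dlogit <- (p - y[i, ]) / (K * n)
        g$W2 <- g$W2 + outer(f, dlogit)
        g$b2 <- g$b2 + dlogit
        df <- drop(params$W2 %*% dlogit)
        dZ <- matrix(df / P, P, 1280L, byrow = TRUE) * (Z > 0 & Z < 6)
        g$W1 <- g$W1 + crossprod(maps[[i]], dZ)
        g$b1 <- g$b1 + colSums(dZ)
      }
      st <- nadam_step(params, g, state, hyper)
      params <- st$params; state <- st$state
      losses[ep] <- loss / n
    }
    ex$weights$tail$w <- params$W1
    ex$weights$tail$b <- params$b1
    list(extractor = ex, loss = losses)
  })
}

#' Persist / restore extractor weights
#' @param ex an `endo_extractor`.
#' @param path RDS file path.
#' @export
save_extractor <- function(ex, path) {
  saveRDS(ex$weights, path)
  invisible(path)
}
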