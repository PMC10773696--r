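# Independent brute-force oracles used to check the vectorized
# implementations. These deliberately use naive per-pixel loops and stay
# separate from the package code paths they verify.

# grayscale frame helpers -----------------------------------------------------

gray_frame <- function(gray) {
  # frame whose BT.601 luma equals `gray` exactly (equal channels)
  px <- array(rep(as.integer(gray), 3L), dim = c(nrow(gray), ncol(gray), 3L))
  new_frame(px, id = "gray")
}

rand_gray <- function(h, w, seed, lo = 0L, hi = 255L) {
  set.seed(seed)
  matrix(sample(lo:hi, h * w, replace = TRUE), h, w)
}

rand_frame <- function(h, w, seed, hi = 255L) {
  set.seed(seed)
  new_frame(array(sample(0:hi, h * w * 3L, replace = TRUE), dim = c(h, w, 3L)),
            id = paste0("rand", seed))
}

# naive LBP / LTP at radius 1 ------------------------------------------------
# Neighbors sit on the Euclidean circle starting at the top-middle pixel,
# clockwise; the four diagonal samples land at +-1/sqrt(2) and are read
# with scalar bilinear interpolation, written out longhand here.

naive_circle_sample <- function(gray, i, j, p, r = 1) {
  theta <- p * pi / 4
  y <- i - r * cos(theta)
  x <- j + r * sin(theta)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  if (fy < 1e-9) fy <- 0
  if (fy > 1 - 1e-9) { fy <- 0; y0 <- y0 + 1 }
  if (fx < 1e-9) fx <- 0
  if (fx > 1 - 1e-9) { fx <- 0; x0 <- x0 + 1 }
  a <- gray[y0, x0]
  v <- a
  if (fx > 0) v <- v + fx * (gray[y0, x0 + 1] - a)
  if (fy > 0) v <- v + fy * (gray[y0 + 1, x0] - a)
  if (fy > 0 && fx > 0)
    v <- v + fy * fx * (a - gray[y0, x0 + 1] - gray[y0 + 1, x0] + gray[y0 + 1, x0 + 1])
  v
}

naive_lbp_map_r1 <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(0L, h - 2L, w - 2L)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    code <- 0L
    for (p in 0:7)
      if (naive_circle_sample(gray, i, j, p) >= gray[i, j]) code <- code + 2L^p
    out[i - 1L, j - 1L] <- code
  }
  storage.mode(out) <- "integer"
  out
}

naive_ltp_maps_r1 <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  up <- matrix(0L, h - 2L, w - 2L); lo <- matrix(0L, h - 2L, w - 2L)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    cu <- 0L; cl <- 0L
    for (p in 0:7) {
      v <- naive_circle_sample(gray, i, j, p)
      if (v > gray[i, j]) cu <- cu + 2L^p
      if (v < gray[i, j]) cl <- cl + 2L^p
    }
    up[i - 1L, j - 1L] <- cu; lo[i - 1L, j - 1L] <- cl
  }
  storage.mode(up) <- "integer"
  storage.mode(lo) <- "integer"
  list(upper = up, lower = lo)
}

# brute-force GLCM by pair enumeration ----------------------------------------

naive_glcm <- function(gray, levels, distance, direction) {
  q <- pmin(floor(gray * levels / 256) + 1L, levels)
  off <- switch(direction,
    horizontal = c(0, distance), vertical = c(distance, 0),
    diag_up = c(-distance, distance), diag_down = c(distance, distance))
  m <- matrix(0L, levels, levels)
  h <- nrow(gray); w <- ncol(gray)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w) {
      m[q[i, j], q[i2, j2]] <- m[q[i, j], q[i2, j2]] + 1L
      m[q[i2, j2], q[i, j]] <- m[q[i2, j2], q[i, j]] + 1L  # both orders
    }
  }
  m
}

# brute-force auto color correlogram ------------------------------------------

naive_acc <- function(frame, levels, distances) {
  nb <- round(levels^(1 / 3))
  px <- frame$pixels
  cmap <- (pmin(floor(px[, , 1] * nb / 256), nb - 1L)) * nb * nb +
    (pmin(floor(px[, , 2] * nb / 256), nb - 1L)) * nb +
    pmin(floor(px[, , 3] * nb / 256), nb - 1L) + 1L
  h <- nrow(cmap); w <- ncol(cmap)
  out <- numeric(0)
  for (k in distances) {
    num <- numeric(levels); den <- numeric(levels)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      for (i2 in seq_len(h)) for (j2 in seq_len(w)) {
        if (max(abs(i - i2), abs(j - j2)) != k) next
        c1 <- cmap[i, j]
        den[c1] <- den[c1] + 1
        if (cmap[i2, j2] == c1) num[c1] <- num[c1] + 1
      }
    }
    out <- c(out, ifelse(den > 0, num / den, 0))
  }
  out
}

# multiclass MCC, covariance form written independently -----------------------

naive_mcc <- function(cm) {
  cm <- cm * 1.0
  K <- nrow(cm)
  n <- sum(cm)
  num <- 0
  for (k in seq_len(K)) for (l in seq_len(K)) for (m in seq_len(K))
    num <- num + cm[k, k] * cm[l, m] - cm[k, l] * cm[m, k]
  d1 <- 0; d2 <- 0
  for (k in seq_len(K)) {
    pk <- sum(cm[k, ])
    d1 <- d1 + pk * (n - pk)
    tk <- sum(cm[, k])
    d2 <- d2 + tk * (n - tk)
  }
  if (d1 == 0 || d2 == 0) return(0)
  num / sqrt(d1 * d2)
}

# pairwise-comparison AUC (probability a positive outranks a negative) --------

naive_auc_binary <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# explicit three-layer forward pass -------------------------------------------

naive_forward <- function(params, x) {
  z1 <- as.vector(t(params$W1) %*% x) + params$B1
  a1 <- ifelse(z1 > 0, z1, 0)
  z2 <- as.vector(t(params$W2) %*% a1) + params$B2
  a2 <- ifelse(z2 > 0, z2, 0)
  z3 <- as.vector(t(params$W3) %*% a2) + params$B3
  1 / (1 + exp(-z3))
}

# scalar re-implementation of the printed optimizer update --------------------

naive_nadam_scalar <- function(theta, gfun, eta, beta1, beta2, eps, steps) {
  m <- 0; v <- 0
  for (t in seq_len(steps)) {
    g <- gfun(theta)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    theta <- theta - eta / (sqrt(vh) + eps) *
      (beta1 * mh + (1 - beta1) * g / (1 - beta1^t) +
         (beta1 * beta2 / (1 - beta1^t)) * m)
  }
  theta
}

# small synthetic feature set for classifier tests ----------------------------

toy_features <- function(n_per_class, K = 2L, d = 6L, sep = 3, seed = 0L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(K), function(k) {
    matrix(stats::rnorm(n_per_class * d, mean = (k - 1) * sep), n_per_class, d)
  }))
  X <- (X - min(X)) / (max(X) - min(X))
  list(X = X, y = rep(letters[seq_len(K)], each = n_per_class))
}
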