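# LIRE-family global descriptors. These follow the cited standard designs
# (MPEG-7 color layout and edge histogram, Tamura's six statistics, CEDD,
# FCTH, JCD, Gabor filter-bank energies, PHOG) at their conventional
# dimensions; where a published definition leaves freedom (fuzzy
# memberships, thresholds) a crisp, documented variant is used. All are
# deterministic.

# ---- shared helpers --------------------------------------------------------

frame_luma <- function(frame) to_grayscale(frame) * 1.0

# 2D DCT-II of an n x n block (orthonormal).
dct2 <- function(x) {
  n <- nrow(x)
  k <- seq_len(n) - 1L
  C <- sqrt(2 / n) * cos(outer(k, (2 * k + 1) / (2 * n) * pi))
  C[1, ] <- sqrt(1 / n)
  C %*% x %*% t(C)
}

zigzag_order <- function(n) {
  ord <- order(outer(seq_len(n), seq_len(n), `+`),
               outer(seq_len(n), seq_len(n), function(i, j) ifelse((i + j) %% 2 == 0, i, -i)))
  ord
}

# MPEG-7 2x2 edge filters: vertical, horizontal, 45, 135, non-directional.
edge_filter_responses <- function(blk) {
  a <- blk[1, 1]; b <- blk[1, 2]; c2 <- blk[2, 1]; d <- blk[2, 2]
  c(ver = abs(a + c2 - b - d),
    hor = abs(a + b - c2 - d),
    d45 = abs(sqrt(2) * (a - d)),
    d135 = abs(sqrt(2) * (b - c2)),
    nond = abs(2 * (a - b - c2 + d)))
}

# Per 2x2-block edge classification over the whole image, vectorized.
# Returns list of matrices: type (0 none, 1..5 edge class) and the four
# block corner means grid size floor(h/2) x floor(w/2).
block_edge_types <- function(g, threshold = 11) {
  h <- 2L * (nrow(g) %/% 2L); w <- 2L * (ncol(g) %/% 2L)
  a <- g[seq(1L, h, 2L), seq(1L, w, 2L), drop = FALSE]
  b <- g[seq(1L, h, 2L), seq(2L, w, 2L), drop = FALSE]
  c2 <- g[seq(2L, h, 2L), seq(1L, w, 2L), drop = FALSE]
  d <- g[seq(2L, h, 2L), seq(2L, w, 2L), drop = FALSE]
  resp <- list(ver = abs(a + c2 - b - d),
               hor = abs(a + b - c2 - d),
               d45 = abs(sqrt(2) * (a - d)),
               d135 = abs(sqrt(2) * (b - c2)),
               nond = abs(2 * (a - b - c2 + d)))
  stack <- array(unlist(resp), dim = c(nrow(a), ncol(a), 5L))
  mx <- pmax(resp$ver, resp$hor, resp$d45, resp$d135, resp$nond)
  ty <- matrix(0L, nrow(a), ncol(a))
  for (k in 5:1) ty[stack[, , k] == mx] <- k
  ty[mx < threshold] <- 0L
  list(type = ty, mean = (a + b + c2 + d) / 4)
}

# ---- individual descriptors ------------------------------------------------

# MPEG-7 style color layout: 8x8 downsample, YCbCr, DCT, zigzag
# coefficients (6 Y + 3 Cb + 3 Cr = 12 dims).
desc_color_layout <- function(frame) {
  px <- resize_bilinear(frame$pixels * 1.0, 8L, 8L)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- -0.168736 * r - 0.331264 * g + 0.5 * b + 128
  cr <- 0.5 * r - 0.418688 * g - 0.081312 * b + 128
  zz <- zigzag_order(8L)
  c(dct2(y)[zz][1:6], dct2(cb)[zz][1:3], dct2(cr)[zz][1:3]) / 255
}

# MPEG-7 style edge histogram: 4x4 subimages x 5 edge types = 80 bins,
# each subimage block-count normalized.
desc_edge_histogram <- function(frame) {
  ehd_from_types(block_edge_types(frame_luma(frame))$type)
}

ehd_from_types <- function(ty) {
  gh <- nrow(ty); gw <- ncol(ty)
  out <- numeric(80)
  ri <- pmin(4L, ceiling(4 * seq_len(gh) / gh))
  ci <- pmin(4L, ceiling(4 * seq_len(gw) / gw))
  for (sr in 1:4) for (sc in 1:4) {
    sub <- ty[ri == sr, ci == sc, drop = FALSE]
    n <- length(sub)
    if (n == 0) next
    for (e in 1:5)
      out[((sr - 1) * 4 + (sc - 1)) * 5 + e] <- sum(sub == e) / n
  }
  out
}

tamura_core <- function(g) {
  h <- nrow(g); w <- ncol(g)
  # coarseness via neighborhood-average differences at dyadic scales
  kmax <- max(1L, min(5L, floor(log2(min(h, w))) - 2L))
  ii <- rbind(0, cbind(0, apply(apply(g, 2, cumsum), 1, cumsum)))
  win_mean <- function(k) {
    s <- 2L^k
    rows <- seq_len(h - 2 * s + 1L); cols <- seq_len(w - 2 * s + 1L)
    top <- rows; bot <- rows + 2L * s; lef <- cols; rig <- cols + 2L * s
    (ii[bot, rig, drop = FALSE] - ii[top, rig, drop = FALSE] -
       ii[bot, lef, drop = FALSE] + ii[top, lef, drop = FALSE]) / (4 * s * s)
  }
  hh <- h - 2L^(kmax + 1L) + 1L; ww <- w - 2L^(kmax + 1L) + 1L
  if (hh < 1L || ww < 1L) { kmax <- 1L; hh <- h - 3L; ww <- w - 3L }
  ebest <- matrix(0, hh, ww); sbest <- matrix(1, hh, ww)
  for (k in seq_len(kmax)) {
    s <- 2L^k
    A <- win_mean(k - 1L)   # window side 2^k centered comparisons below
    # E_k horizontal / vertical: difference of window means separated by s
    half <- 2L^(k - 1L)
    Eh <- abs(A[, seq_len(ncol(A) - s), drop = FALSE] -
                A[, seq_len(ncol(A) - s) + s, drop = FALSE])
    Ev <- abs(A[seq_len(nrow(A) - s), , drop = FALSE] -
                A[seq_len(nrow(A) - s) + s, , drop = FALSE])
    E <- pmax(Eh[seq_len(hh), seq_len(ww), drop = FALSE],
              Ev[seq_len(hh), seq_len(ww), drop = FALSE])
    upd <- E > ebest
    ebest[upd] <- E[upd]
    sbest[upd] <- s
  }
  coarseness <- mean(sbest)
  # contrast
  sd_g <- stats::sd(g)
  contrast <- if (sd_g > 0) {
    a4 <- mean((g - mean(g))^4) / sd_g^4
    sd_g / a4^0.25
  } else 0
  # directionality from Prewitt gradients
  gx <- g[, c(2:w, w)] - g[, c(1, 1:(w - 1))]
  gy <- g[c(2:h, h), ] - g[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  strong <- mag > max(mag) * 0.1 & mag > 1e-9
  directionality <- if (any(strong)) {
    th2 <- 2 * atan2(gy[strong], gx[strong])  # axial data doubled
    wgt <- mag[strong] / sum(mag[strong])
    sqrt(sum(wgt * cos(th2))^2 + sum(wgt * sin(th2))^2)  # circular coherence
  } else 0
  # line-likeness: coherence of direction along horizontally adjacent
  # strong-edge pixels
  line <- {
    thm <- atan2(gy, gx)
    sA <- strong[, -w, drop = FALSE] & strong[, -1, drop = FALSE]
    if (any(sA)) mean(abs(cos(thm[, -w, drop = FALSE][sA] - thm[, -1, drop = FALSE][sA])))
    else 0
  }
  c(coarseness = coarseness, contrast = contrast,
    directionality = directionality, linelikeness = line)
}

# Tamura's six statistics: coarseness, contrast, directionality,
# line-likeness, regularity (stability of the first three over the four
# image quadrants), roughness (coarseness + contrast).
desc_tamura <- function(frame) {
  g <- frame_luma(frame)
  base <- tamura_core(g)
  h <- nrow(g); w <- ncol(g)
  quads <- list(g[1:(h %/% 2), 1:(w %/% 2)], g[1:(h %/% 2), (w %/% 2 + 1):w],
                g[(h %/% 2 + 1):h, 1:(w %/% 2)], g[(h %/% 2 + 1):h, (w %/% 2 + 1):w])
  qs <- vapply(quads, tamura_core, numeric(4))
  norm_sd <- function(v) if (mean(v) > 1e-9) stats::sd(v) / (mean(v) + 1e-9) else 0
  regularity <- max(0, 1 - mean(c(norm_sd(qs[1, ]), norm_sd(qs[2, ]), norm_sd(qs[3, ]))))
  c(base[1:4], regularity = regularity,
    roughness = unname(base["coarseness"] + base["contrast"]))
}

# Crisp 24-color HSV quantization shared by CEDD/FCTH/JCD:
# 4 achromatic bins (by value) + 10 hue bins x 2 saturation levels.
color24 <- function(frame) {
  px <- frame$pixels
  hsv <- grDevices::rgb2hsv(r = as.numeric(px[, , 1]), g = as.numeric(px[, , 2]),
                            b = as.numeric(px[, , 3]), maxColorValue = 255)
  hch <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  idx <- integer(length(hch))
  achro <- s < 0.2 | v < 0.12
  idx[achro] <- pmin(floor(v[achro] * 4), 3) + 1L          # bins 1..4
  hue_bin <- pmin(floor(hch * 10), 9)
  sat_hi <- s >= 0.55
  idx[!achro] <- 5L + hue_bin[!achro] + 10L * sat_hi[!achro]  # bins 5..24
  matrix(idx, nrow = dim(px)[1])
}

# block-mode of the 24-color map on the 2x2 block grid (top-left sample;
# blocks are near-constant at this scale)
block_color24 <- function(cmap) {
  h <- 2L * (nrow(cmap) %/% 2L); w <- 2L * (ncol(cmap) %/% 2L)
  cmap[seq(1L, h, 2L), seq(1L, w, 2L), drop = FALSE]
}

# CEDD-style: 6 texture categories (non-edge + 5 MPEG-7 edge types) x 24
# colors = 144 bins, normalized to sum 1.
desc_cedd <- function(frame) {
  cedd_from_parts(block_edge_types(frame_luma(frame))$type,
                  block_color24(color24(frame)))
}

cedd_from_parts <- function(ty, cb) {
  idx <- as.integer(ty) * 24L + as.integer(cb)
  cnt <- tabulate(idx, nbins = 144L)
  cnt / max(1L, sum(cnt))
}

# FCTH-style: 8 texture categories from 2x2 Haar wavelet band energies
# (each of HL, LH, HH above/below threshold) x 24 colors = 192 bins.
fcth_texture_types <- function(g, threshold = 14) {
  h <- 2L * (nrow(g) %/% 2L); w <- 2L * (ncol(g) %/% 2L)
  a <- g[seq(1L, h, 2L), seq(1L, w, 2L), drop = FALSE]
  b <- g[seq(1L, h, 2L), seq(2L, w, 2L), drop = FALSE]
  c2 <- g[seq(2L, h, 2L), seq(1L, w, 2L), drop = FALSE]
  d <- g[seq(2L, h, 2L), seq(2L, w, 2L), drop = FALSE]
  hl <- abs(a - b + c2 - d) / 2
  lh <- abs(a + b - c2 - d) / 2
  hh <- abs(a - b - c2 + d) / 2
  (hl > threshold) * 4L + (lh > threshold) * 2L + (hh > threshold) * 1L  # 0..7
}

desc_fcth <- function(frame) {
  fcth_from_parts(fcth_texture_types(frame_luma(frame)),
                  block_color24(color24(frame)))
}

fcth_from_parts <- function(ty, cb) {
  idx <- as.integer(ty) * 24L + as.integer(cb)
  cnt <- tabulate(idx, nbins = 192L)
  cnt / max(1L, sum(cnt))
}

# JCD-style joint compaction: 7 joint texture areas x 24 colors = 168.
# Areas: 0 flat, 1 vertical, 2 horizontal, 3 diagonal (45 or 135),
# 4 non-directional edge, 5 mid-frequency texture, 6 high-frequency
# texture (from the wavelet energies when no MPEG-7 edge fires).
desc_jcd <- function(frame) {
  g <- frame_luma(frame)
  jcd_from_parts(block_edge_types(g)$type, fcth_texture_types(g),
                 block_color24(color24(frame)))
}

jcd_from_parts <- function(be, wv, cb) {
  area <- matrix(0L, nrow(be), ncol(be))
  area[be == 1L] <- 1L
  area[be == 2L] <- 2L
  area[be == 3L | be == 4L] <- 3L
  area[be == 5L] <- 4L
  noedge <- be == 0L
  area[noedge & wv > 0L & wv < 4L] <- 5L
  area[noedge & wv >= 4L] <- 6L
  idx <- area * 24L + as.integer(cb)
  cnt <- tabulate(idx, nbins = 168L)
  cnt / max(1L, sum(cnt))
}

gabor_kernel <- function(sigma, theta, lambda, gamma = 0.5, n = NULL) {
  if (is.null(n)) n <- 2L * ceiling(2.5 * sigma) + 1L
  half <- (n - 1L) / 2
  yy <- matrix(-half:half, n, n)
  xx <- t(yy)
  xr <- xx * cos(theta) + yy * sin(theta)
  yr <- -xx * sin(theta) + yy * cos(theta)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  list(re = env * cos(2 * pi * xr / lambda),
       im = env * sin(2 * pi * xr / lambda))
}

fft_convolve_same <- function(g, k) {
  h <- nrow(g); w <- ncol(g)
  kh <- nrow(k); kw <- ncol(k)
  ph <- h + kh - 1L; pw <- w + kw - 1L
  G <- matrix(0, ph, pw); G[1:h, 1:w] <- g
  K <- matrix(0, ph, pw); K[1:kh, 1:kw] <- k
  full <- Re(stats::fft(stats::fft(G) * stats::fft(K), inverse = TRUE)) / (ph * pw)
  r0 <- (kh + 1L) %/% 2; c0 <- (kw + 1L) %/% 2
  full[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
}

# Gabor filter-bank energies: 4 scales x 6 orientations, mean and sd of
# the complex magnitude = 48 dims.
desc_gabor <- function(frame) {
  g <- frame_luma(frame) / 255
  sigmas <- c(1.5, 2.5, 4, 6)
  thetas <- (0:5) * pi / 6
  out <- numeric(0)
  for (s in sigmas) for (th in thetas) {
    k <- gabor_kernel(s, th, lambda = 2.5 * s)
    re <- fft_convolve_same(g, k$re)
    im <- fft_convolve_same(g, k$im)
    mag <- sqrt(re^2 + im^2)
    out <- c(out, mean(mag), stats::sd(mag))
  }
  out
}

# PHOG: pyramid (levels 0..2 -> 1 + 4 + 16 cells) of 8-bin unsigned
# gradient-orientation histograms, magnitude-weighted, whole vector
# normalized to sum 1. 168 dims.
desc_phog <- function(frame) {
  g <- frame_luma(frame)
  h <- nrow(g); w <- ncol(g)
  gx <- g[, c(2:w, w)] - g[, c(1, 1:(w - 1))]
  gy <- g[c(2:h, h), ] - g[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ori / pi * 8) + 1L, 8L)
  out <- numeric(0)
  for (lev in 0:2) {
    nc <- 2L^lev
    ri <- pmin(nc, ceiling(nc * seq_len(h) / h))
    ci <- pmin(nc, ceiling(nc * seq_len(w) / w))
    for (rr in seq_len(nc)) for (cc in seq_len(nc)) {
      sel <- outer(ri == rr, ci == cc)
      hvec <- vapply(1:8, function(b2) sum(mag[sel & bin == b2]), numeric(1))
      out <- c(out, hvec)
    }
  }
  tot <- sum(out)
  if (tot > 0) out / tot else out
}

#' Compute a LIRE-family descriptor by name
#'
#' Supported names and dimensions: `color_layout` (12), `edge_histogram`
#' (80), `tamura` (6), `cedd` (144), `fcth` (192), `jcd` (168), `gabor`
#' (48), `phog` (168).
#'
#' @param frame an `endo_frame`.
#' @param name descriptor name.
#' @return numeric feature vector of the documented fixed length.
#' @export
lire_descriptor <- function(frame, name) {
  fn <- switch(name,
    color_layout = desc_color_layout,
    edge_histogram = desc_edge_histogram,
    tamura = desc_tamura,
    cedd = desc_cedd,
    fcth = desc_fcth,
    jcd = desc_jcd,
    gabor = desc_gabor,
    phog = desc_phog,
    stop("unknown LIRE descriptor: ", name, call. = FALSE))
  unname(fn(frame))
}
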