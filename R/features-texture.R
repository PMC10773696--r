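# Formula-defined texture descriptors: local binary/ternary patterns,
# color histograms, the gray-level co-occurrence matrix with Haralick
# statistics, and the auto color correlogram. All are deterministic and
# checked in the tests against brute-force enumerations on tiny images.

# Sample the 8 circular neighbors of every interior pixel at the given
# radius. Returns a list of 8 matrices of size (H-2r) x (W-2r), ordered
# from the top-middle neighbor clockwise. Non-integer positions use
# bilinear interpolation.
circular_neighbors <- function(gray, radius) {
  h <- nrow(gray); w <- ncol(gray)
  r <- radius
  if (h <= 2 * r || w <= 2 * r)
    stop("image too small for radius ", r, call. = FALSE)
  rows <- (r + 1):(h - r)
  cols <- (r + 1):(w - r)
  out <- vector("list", 8L)
  for (p in 0:7) {
    theta <- p * pi / 4
    dy <- -r * cos(theta)   # p = 0 is the top-middle neighbor, then clockwise
    dx <- r * sin(theta)
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0; fx <- dx - x0
    # snap nearly-integer offsets to avoid spurious interpolation
    if (abs(fy) < 1e-9) fy <- 0
    if (abs(1 - fy) < 1e-9) { fy <- 0; y0 <- y0 + 1L }
    if (abs(fx) < 1e-9) fx <- 0
    if (abs(1 - fx) < 1e-9) { fx <- 0; x0 <- x0 + 1L }
    g <- function(ddy, ddx) gray[rows + y0 + ddy, cols + x0 + ddx, drop = FALSE]
    # difference form of bilinear interpolation: exact on constant patches
    a <- g(0L, 0L)
    acc <- a
    if (fx > 0) acc <- acc + fx * (g(0L, 1L) - a)
    if (fy > 0) acc <- acc + fy * (g(1L, 0L) - a)
    if (fy > 0 && fx > 0)
      acc <- acc + fy * fx * (a - g(0L, 1L) - g(1L, 0L) + g(1L, 1L))
    out[[p + 1L]] <- acc
  }
  out
}

#' Local binary pattern map
#'
#' For each interior pixel, bit p is set iff the p-th circular neighbor
#' (starting at the top-middle neighbor, clockwise, bilinear interpolation
#' at non-integer positions) is greater than or equal to the center; the
#' code is the sum of `2^p`. Pixels within `radius` of the border are
#' excluded.
#'
#' @param gray integer grayscale matrix.
#' @param radius circle radius in pixels, 1..5.
#' @return integer matrix of codes in \[0, 255\], with attribute `radius`.
#' @export
lbp_map <- function(gray, radius = 1L) {
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  if (radius > 5L) stop("radius must be <= 5", call. = FALSE)
  nb <- circular_neighbors(gray, radius)
  center <- gray[(radius + 1):(nrow(gray) - radius),
                 (radius + 1):(ncol(gray) - radius), drop = FALSE]
  code <- matrix(0L, nrow(center), ncol(center))
  for (p in 0:7)
    code <- code + bitwShiftL(1L, p) * (nb[[p + 1L]] >= center)
  structure(code, radius = radius)
}

#' LBP histogram feature
#'
#' Per radius, a 256-bin normalized histogram of LBP codes; blocks are
#' concatenated over `radii` (the published pipeline uses radii 1 to 5,
#' giving 1280 dimensions).
#'
#' @param gray integer grayscale matrix.
#' @param radii non-empty vector of radii.
#' @return numeric vector of length `256 * length(radii)`.
#' @export
lbp_histogram <- function(gray, radii = 1:5) {
  if (!length(radii)) stop("radii must be non-empty", call. = FALSE)
  unlist(lapply(radii, function(r) {
    codes <- lbp_map(gray, r)
    tabulate(as.integer(codes) + 1L, nbins = 256L) / length(codes)
  }))
}

#' Local ternary pattern maps
#'
#' Each neighbor compares three ways against the center (+1 above, -1
#' below, 0 equal); the ternary code splits into the standard upper
#' (+1 -> 1) and lower (-1 -> 1) binary maps, each encoded like LBP.
#'
#' @param gray integer grayscale matrix.
#' @param radius circle radius.
#' @return list with integer matrices `upper` and `lower`.
#' @export
ltp_maps <- function(gray, radius = 1L) {
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  nb <- circular_neighbors(gray, radius)
  center <- gray[(radius + 1):(nrow(gray) - radius),
                 (radius + 1):(ncol(gray) - radius), drop = FALSE]
  up <- matrix(0L, nrow(center), ncol(center))
  lo <- matrix(0L, nrow(center), ncol(center))
  for (p in 0:7) {
    up <- up + bitwShiftL(1L, p) * (nb[[p + 1L]] > center)
    lo <- lo + bitwShiftL(1L, p) * (nb[[p + 1L]] < center)
  }
  list(upper = structure(up, radius = radius),
       lower = structure(lo, radius = radius))
}

ltp_histogram <- function(gray, radii = 1L) {
  unlist(lapply(radii, function(r) {
    m <- ltp_maps(gray, r)
    c(tabulate(as.integer(m$upper) + 1L, nbins = 256L) / length(m$upper),
      tabulate(as.integer(m$lower) + 1L, nbins = 256L) / length(m$lower))
  }))
}

#' Per-channel color histogram
#'
#' Normalized per-channel histograms (each channel block sums to 1),
#' concatenated over the three channels of the chosen color space.
#'
#' @param frame an `endo_frame`.
#' @param space `"RGB"` or `"HSV"`.
#' @param bins_per_channel number of equal-width bins per channel (>= 2).
#' @return numeric vector of length `3 * bins_per_channel`.
#' @export
color_histogram <- function(frame, space = c("RGB", "HSV"), bins_per_channel = 64L) {
  space <- match.arg(space)
  if (bins_per_channel < 2L) stop("bins_per_channel must be >= 2", call. = FALSE)
  px <- frame$pixels
  n <- prod(dim(px)[1:2])
  chans <- if (space == "RGB") {
    lapply(1:3, function(ch) as.numeric(px[, , ch]) / 256)
  } else {
    hsv <- grDevices::rgb2hsv(r = as.numeric(px[, , 1]), g = as.numeric(px[, , 2]),
                              b = as.numeric(px[, , 3]), maxColorValue = 255)
    lapply(1:3, function(ch) hsv[ch, ] * 0.999999)
  }
  unlist(lapply(chans, function(v) {
    b <- pmin(floor(v * bins_per_channel) + 1L, bins_per_channel)
    tabulate(b, nbins = bins_per_channel) / n
  }))
}

#' Gray-level co-occurrence matrix
#'
#' Intensities are quantized to `levels` equal-width bins over \[0, 255\];
#' ordered neighbor pairs at the given distance and direction are counted
#' in both orders, so the matrix is symmetric and sums to twice the number
#' of unordered pairs.
#'
#' @param gray integer grayscale matrix.
#' @param levels number of quantization levels (>= 2).
#' @param distance neighbor offset in pixels (>= 1).
#' @param direction one of `"horizontal"`, `"vertical"`, `"diag_up"`,
#'   `"diag_down"`.
#' @return levels x levels integer matrix with attributes `levels`,
#'   `distance`, `direction`.
#' @export
glcm <- function(gray, levels = 8L, distance = 1L,
                 direction = c("horizontal", "vertical", "diag_up", "diag_down")) {
  direction <- match.arg(direction)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  q <- pmin(floor(gray * levels / 256) + 1L, levels)
  d <- as.integer(distance)
  off <- switch(direction,
    horizontal = c(0L, d),
    vertical = c(d, 0L),
    diag_up = c(-d, d),
    diag_down = c(d, d))
  r0 <- max(1L, 1L - off[1]); r1 <- min(h, h - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(w, w - off[2])
  m <- matrix(0L, levels, levels)
  if (r0 > r1 || c0 > c1) {
    warning("distance exceeds image extent; empty GLCM")
  } else {
    a <- q[r0:r1, c0:c1, drop = FALSE]
    b <- q[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]), drop = FALSE]
    idx <- (as.integer(b) - 1L) * levels + as.integer(a)
    cnt <- tabulate(idx, nbins = levels * levels)
    m <- matrix(cnt, levels, levels)
    m <- m + t(m)   # count both orders
  }
  structure(m, levels = levels, distance = d, direction = direction)
}

#' Haralick statistics of a GLCM
#'
#' Normalizes the matrix to `P = counts / R` (R the total count) and emits
#' seven values: the normalization-identity sum `sum(P)` (always 1),
#' angular second moment, contrast, correlation, variance, inverse
#' difference moment, and entropy (natural log).
#'
#' @param m a [glcm()] matrix.
#' @return named numeric vector of length 7.
#' @export
haralick <- function(m) {
  R <- sum(m)
  if (R == 0) stop("zero-count GLCM", call. = FALSE)
  L <- nrow(m)
  P <- m / R
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu_x <- sum(i * P); mu_y <- sum(j * P)
  sd_x <- sqrt(sum((i - mu_x)^2 * P)); sd_y <- sqrt(sum((j - mu_y)^2 * P))
  corr <- if (sd_x > 0 && sd_y > 0) sum((i - mu_x) * (j - mu_y) * P) / (sd_x * sd_y) else 0
  pos <- P > 0
  c(sum = sum(P),
    asm = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    variance = sum((i - mu_x)^2 * P),
    idm = sum(P / (1 + (i - j)^2)),
    entropy = -sum(P[pos] * log(P[pos])))
}

# 7 Haralick statistics averaged over the four GLCM directions.
haralick_bank <- function(gray, levels = 8L, distance = 1L) {
  dirs <- c("horizontal", "vertical", "diag_up", "diag_down")
  stats <- suppressWarnings(
    vapply(dirs, function(d) haralick(glcm(gray, levels, distance, d)),
           numeric(7)))
  rowMeans(stats)
}

# Joint RGB quantization to nb^3 colors; returns an integer matrix of
# color indices in 1..nb^3.
quantize_colors <- function(px, levels) {
  nb <- round(levels^(1 / 3))
  if (nb^3 != levels)
    stop("levels must be a perfect cube (e.g. 8, 27, 64)", call. = FALSE)
  q <- function(ch) pmin(floor(px[, , ch] * nb / 256), nb - 1L)
  m <- q(1) * nb * nb + q(2) * nb + q(3) + 1L
  storage.mode(m) <- "integer"
  m
}

#' Auto color correlogram
#'
#' For each quantized color c and distance k, the probability that a pixel
#' at chessboard (Chebyshev) distance exactly k from a pixel of color c
#' also has color c. Dimension is `levels * length(distances)`; entries
#' with no feasible pair are 0.
#'
#' @param frame an `endo_frame`.
#' @param levels number of quantized colors (perfect cube, default 64).
#' @param distances vector of small positive distances.
#' @return numeric vector, color-major within each distance.
#' @export
auto_color_correlogram <- function(frame, levels = 64L, distances = c(1L, 3L, 5L, 7L)) {
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  cmap <- quantize_colors(frame$pixels, levels)
  h <- nrow(cmap); w <- ncol(cmap)
  out <- numeric(0)
  for (k in distances) {
    num <- numeric(levels); den <- numeric(levels)
    # ring of chessboard distance exactly k: max(|dy|,|dx|) == k
    offs <- list()
    for (dy in -k:k) for (dx in -k:k)
      if (max(abs(dy), abs(dx)) == k) offs[[length(offs) + 1L]] <- c(dy, dx)
    for (o in offs) {
      dy <- o[1]; dx <- o[2]
      r0 <- max(1L, 1L - dy); r1 <- min(h, h - dy)
      c0 <- max(1L, 1L - dx); c1 <- min(w, w - dx)
      if (r0 > r1 || c0 > c1) next
      a <- cmap[r0:r1, c0:c1, drop = FALSE]
      b <- cmap[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx), drop = FALSE]
      den <- den + tabulate(as.integer(a), nbins = levels)
      same <- a == b
      num <- num + tabulate(as.integer(a)[same], nbins = levels)
    }
    acc <- ifelse(den > 0, num / den, 0)
    out <- c(out, acc)
  }
  out
}
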