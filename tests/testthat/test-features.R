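test_that("LBP maps match the naive per-pixel oracle at radius 1", {
  for (seed in 1:5) {
    g <- rand_gray(8, 8, seed)
    m <- lbp_map(g, 1L)
    expect_identical(unclass(m)[,], naive_lbp_map_r1(g)[,],
                     info = paste("seed", seed))
  }
  expect_true(all(lbp_map(matrix(7L, 6, 6), 1L) == 255L))  # ties set every bit
  g <- matrix(0L, 5, 5); g[3, 3] <- 200L
  expect_identical(as.integer(lbp_map(g, 1L)[2, 2]), 0L)   # bright isolated center
  expect_error(lbp_map(g, 0L), "radius")
})

test_that("LBP histograms normalize per block and ignore shared offsets", {
  g <- rand_gray(16, 16, 3, hi = 240)
  h <- lbp_histogram(g, radii = 1:5)
  expect_length(h, 1280)
  for (b in 1:5) expect_equal(sum(h[(b - 1) * 256 + 1:256]), 1)
  expect_equal(lbp_histogram(g + 10L, radii = 1:2), lbp_histogram(g, radii = 1:2))
})

test_that("LTP maps split the ternary code with mutually exclusive bits", {
  cst <- ltp_maps(matrix(9L, 6, 6), 1L)
  expect_true(all(cst$upper == 0L) && all(cst$lower == 0L))
  ring <- matrix(200L, 3, 3); ring[2, 2] <- 10L
  m <- ltp_maps(ring, 1L)
  expect_identical(as.integer(m$upper[1, 1]), 255L)
  expect_identical(as.integer(m$lower[1, 1]), 0L)
  for (seed in 1:5) {
    g <- rand_gray(8, 8, seed + 10)
    m <- ltp_maps(g, 1L)
    o <- naive_ltp_maps_r1(g)
    expect_identical(unclass(m$upper)[,], o$upper[,])
    expect_identical(unclass(m$lower)[,], o$lower[,])
    expect_true(all(bitwAnd(as.integer(m$upper), as.integer(m$lower)) == 0L))
  }
})

test_that("color histograms put mass where the pixels are", {
  uni <- new_frame(array(rep(c(32L, 160L, 240L), each = 12), dim = c(3, 4, 3)))
  h <- color_histogram(uni, "RGB", 16)
  expect_length(h, 48)
  for (b in 1:3) {
    blk <- h[(b - 1) * 16 + 1:16]
    expect_equal(sum(blk), 1)
    expect_equal(max(blk), 1)     # uniform color: all mass in one bin
  }
  two <- new_frame(array(rep(c(0L, 255L), each = 1, times = 6 * 3),
                         dim = c(2, 6, 3)))
  h2 <- color_histogram(two, "RGB", 4)
  expect_equal(h2[1], 0.5)        # 50/50 two-tone image
  expect_equal(h2[4], 0.5)
  hsv <- color_histogram(rand_frame(6, 6, 1), "HSV", 8)
  expect_length(hsv, 24)
  expect_equal(sum(hsv), 3)
})

test_that("GLCM counts ordered pairs per the brute-force enumerator", {
  img <- matrix(c(0L, 0L, 0L, 200L), 2, 2)   # quantizes to levels 1,1,1,2
  m <- glcm(img, levels = 2, distance = 1, direction = "horizontal")
  expect_identical(m[1, 1], 2L)
  expect_identical(m[1, 2], 1L)
  expect_identical(m[2, 1], 1L)
  expect_identical(m[2, 2], 0L)
  cst <- glcm(matrix(100L, 4, 4), levels = 4, distance = 1, "horizontal")
  expect_equal(sum(cst), 24)
  expect_equal(cst[2, 2], 24L)                 # constant image: single cell
  for (seed in 1:4) for (dir in c("horizontal", "vertical", "diag_up", "diag_down")) {
    g <- rand_gray(7, 6, seed * 7)
    m <- glcm(g, levels = 4, distance = 2, direction = dir)
    expect_identical(unclass(m)[,], naive_glcm(g, 4, 2, dir)[,])
    expect_identical(unclass(m), t(unclass(m)))   # symmetry
  }
  g <- rand_gray(6, 6, 1)
  expect_identical(unclass(glcm(t(g), levels = 4, distance = 1, "horizontal"))[,],
                   unclass(glcm(g, levels = 4, distance = 1, "vertical"))[,])
  expect_warning(m <- glcm(rand_gray(3, 3, 2), levels = 2, distance = 5), "extent")
  expect_equal(sum(m), 0)
})

test_that("Haralick statistics match hand arithmetic", {
  m <- structure(matrix(c(4L, 2L, 2L, 0L), 2, 2), levels = 2L)
  h <- haralick(m)
  expect_equal(unname(h["sum"]), 1)                    # normalization identity
  P <- matrix(c(4, 2, 2, 0), 2, 2) / 8
  expect_equal(unname(h["asm"]), sum(P^2))
  expect_equal(unname(h["contrast"]), 2 * 2 / 8)       # |i-j|=1 cells
  mu <- sum(c(1, 2, 1, 2) * c(4, 2, 2, 0) / 8)
  expect_equal(unname(h["variance"]), sum((c(1, 2, 1, 2) - mu)^2 * c(4, 2, 2, 0) / 8))
  expect_equal(unname(h["entropy"]), -sum(P[P > 0] * log(P[P > 0])))
  cst <- haralick(glcm(matrix(100L, 5, 5), levels = 4, distance = 1, "horizontal"))
  expect_equal(unname(cst["contrast"]), 0)
  expect_equal(unname(cst["asm"]), 1)
  for (seed in 1:3)
    expect_equal(unname(haralick(glcm(rand_gray(6, 6, seed), 4, 1, "vertical"))["sum"]), 1)
  expect_error(haralick(matrix(0L, 2, 2)), "zero-count")
})

test_that("auto color correlogram equals exhaustive pair counting", {
  uni <- new_frame(array(rep(c(10L, 100L, 220L), each = 16), dim = c(4, 4, 3)))
  acc <- auto_color_correlogram(uni, levels = 8, distances = c(1, 2))
  expect_true(all(acc[acc > 0] == 1))   # single color: probability 1 where feasible
  for (seed in 1:3) {
    f <- rand_frame(6, 5, seed)
    got <- auto_color_correlogram(f, levels = 8, distances = c(1, 2))
    expect_equal(got, naive_acc(f, 8, c(1, 2)), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
  expect_error(auto_color_correlogram(rand_frame(4, 4, 1), levels = 10), "cube")
})

test_that("LIRE descriptors have their documented dimensions and determinism", {
  f <- make_frame(endoscopy_class_specs(2)[[2]], 48, 48, seed = 9)
  dims <- c(color_layout = 12, edge_histogram = 80, tamura = 6, cedd = 144,
            fcth = 192, jcd = 168, gabor = 48, phog = 168)
  for (nm in names(dims)) {
    v <- lire_descriptor(f, nm)
    expect_length(v, dims[[nm]])
    expect_identical(v, lire_descriptor(f, nm))
    expect_true(all(is.finite(v)))
  }
  uni <- new_frame(array(120L, dim = c(32L, 32L, 3L)))
  expect_true(all(lire_descriptor(uni, "edge_histogram") == 0))  # no gradients
  expect_true(sum(lire_descriptor(uni, "phog")) == 0)
  expect_error(lire_descriptor(f, "sift"), "unknown")
})

test_that("scaler maps the training range to [0,1] with clamping", {
  X <- rbind(c(0, 5, 7), c(10, 5, 9))
  sc <- fit_scaler(X)
  expect_equal(scale_features(sc, c(0, 5, 7)), c(0, 0, 0))   # min -> 0, const -> 0
  expect_equal(scale_features(sc, c(10, 5, 9)), c(1, 0, 1))  # max -> 1
  expect_equal(scale_features(sc, c(-3, 99, 8)), c(0, 0, 0.5))
  expect_error(scale_features(list(), c(1, 2, 3)), "fit_scaler")
  expect_error(scale_features(sc, c(1, 2)), "mismatch")
})

test_that("extract_bank concatenates with contiguous, sliceable spans", {
  f <- make_frame(endoscopy_class_specs(1)[[1]], 48, 48, seed = 2)
  only_lbp <- extract_bank(f, "lbp")
  expect_length(only_lbp, 1280)
  v <- extract_bank(f, c("tamura", "color_layout", "edge_histogram"))
  spans <- attr(v, "spans")
  expect_identical(names(spans), c("color_layout", "edge_histogram", "tamura"))
  flat <- unlist(spans)
  expect_identical(as.integer(sort(flat)), seq_along(v))     # contiguous cover
  v2 <- extract_bank(f, c("color_layout", "tamura"))
  expect_equal(unname(v[c(spans$color_layout, spans$tamura)]), as.vector(v2))
  expect_error(extract_bank(f, character(0)), "empty")
  expect_error(extract_bank(f, "surf"), "unknown")
})
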