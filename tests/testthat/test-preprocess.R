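test_that("grayscale conversion follows BT.601 with half-up rounding", {
  f <- new_frame(array(c(255L, 0L, 100L, 255L, 0L, 200L, 255L, 0L, 50L),
                       dim = c(1L, 3L, 3L))[, , , drop = FALSE], id = "t")
  # pixels along the row: white, black, (100, 200, 50)
  g <- to_grayscale(f)
  expect_identical(g[1, 1], 255L)
  expect_identical(g[1, 2], 0L)
  expect_identical(g[1, 3], 153L)   # round(0.299*100 + 0.587*200 + 0.114*50)
})

test_that("strong detection is a strict threshold and monotone in it", {
  g <- matrix(c(200L, 180L, 181L, 100L), 2, 2)
  m <- detect_strong(g)
  expect_identical(m, matrix(c(255L, 0L, 255L, 0L), 2, 2))
  expect_equal(sum(detect_strong(matrix(100L, 4, 4))), 0)
  for (seed in 1:5) {
    g <- rand_gray(10, 10, seed)
    m_low <- detect_strong(g, strong = 120)
    m_high <- detect_strong(g, strong = 200)
    expect_true(all(m_high[m_low == 0] == 0))   # raising threshold shrinks mask
  }
})

test_that("weak expansion reaches its fixed point, monotone and idempotent", {
  g <- matrix(0L, 5, 5)
  g[3, 3] <- 200L; g[3, 4] <- 160L; g[3, 5] <- 160L
  g[1, 1] <- 160L                              # weak but never connected
  strong <- detect_strong(g)
  m <- expand_weak(g, strong)
  expect_identical(m[3, 4], 255L)              # adjacent weak pixel absorbed
  expect_identical(m[3, 5], 255L)              # chain continues to fixed point
  expect_identical(m[1, 1], 0L)                # disconnected weak pixel stays out
  expect_true(all(m[strong == 255L] == 255L))  # superset of the strong mask
  expect_identical(expand_weak(g, m), m)       # idempotent at the fixed point
  empty <- matrix(0L, 5, 5)
  expect_equal(sum(expand_weak(g, empty)), 0)  # nothing to expand from
  expect_error(expand_weak(g, matrix(0L, 2, 2)), "shape")
})

test_that("build_mask covers injected ground truth and behaves at the edges", {
  f <- make_frame(endoscopy_class_specs(1)[[1]], 64, 64, seed = 1)
  z <- inject_reflections(f, 3, seed = 2)
  m <- build_mask(z$frame)
  expect_true(all(m[z$mask == 255L] == 255L))  # mask superset of ground truth
  m0 <- build_mask(z$frame, dilate_px = 0)
  g <- to_grayscale(z$frame)
  expect_identical(m0, expand_weak(g, detect_strong(g)))
  expect_equal(sum(build_mask(f)), 0)          # reflection-free frame
  expect_error(build_mask(f, dilate_px = -1), "dilate_px")
})

test_that("inpainting replaces only masked pixels and removes detections", {
  f <- make_frame(endoscopy_class_specs(2)[[2]], 64, 64, seed = 4)
  z <- inject_reflections(f, 3, seed = 5)
  m <- build_mask(z$frame)
  for (method in c("fmm_telea", "navier_stokes")) {
    out <- remove_reflections(z$frame, m, method = method)
    keep <- array(rep(m == 0L, 3), dim = dim(f$pixels))
    expect_identical(out$pixels[keep], z$frame$pixels[keep])
    n_before <- sum(detect_strong(to_grayscale(z$frame)) > 0)
    n_after <- sum(detect_strong(to_grayscale(out)) > 0)
    expect_lt(n_after, n_before)
  }
  expect_identical(remove_reflections(f, matrix(0L, 64, 64))$pixels, f$pixels)
  # full-coverage inpaint of a constant frame stays (nearly) constant
  const <- new_frame(array(90L, dim = c(16L, 16L, 3L)), id = "c")
  full <- matrix(255L, 16, 16); full[1, ] <- 0L   # known boundary row
  out <- remove_reflections(const, full)
  expect_true(all(abs(out$pixels * 1.0 - 90) <= 1))
  expect_error(remove_reflections(f, matrix(0L, 64, 64), method = "magic"))
})

test_that("augmentation quota follows the balancing formula", {
  q <- augmentation_quota(c(out_of_patient = 9, stool_plenty = 2331))
  expect_identical(q[["out_of_patient"]], 2555L)   # floor(2331*1.1 - 9)
  expect_identical(q[["stool_plenty"]], 233L)      # floor(2331*0.1)
  expect_identical(augmentation_quota(c(A = 10))[["A"]], 1L)
  expect_error(augmentation_quota(numeric(0)), "non-empty")
  # invariant: post-augmentation totals differ by at most 1
  set.seed(11)
  for (i in 1:20) {
    counts <- sample(1:500, sample(2:8, 1))
    names(counts) <- paste0("c", seq_along(counts))
    tot <- counts + augmentation_quota(counts)
    expect_lte(max(tot) - min(tot), 1)
  }
})

test_that("manipulations keep frames valid and honor their contracts", {
  f <- make_frame(endoscopy_class_specs(3)[[3]], 48, 48, seed = 6)
  ff <- apply_manipulation(apply_manipulation(f, "flip", axis = "horizontal"),
                           "flip", axis = "horizontal")
  expect_identical(ff$pixels, f$pixels)            # flip is an involution
  expect_identical(apply_manipulation(f, "noise", sigma = 0)$pixels, f$pixels)
  set.seed(1)
  for (kind in c("rotate", "crop", "resize", "noise")) {
    out <- apply_manipulation(f, kind)
    expect_identical(dim(out$pixels), dim(f$pixels))
    expect_true(all(out$pixels >= 0L & out$pixels <= 255L))
  }
  expect_error(apply_manipulation(f, "sharpen"), "unknown manipulation")
})

test_that("augment_dataset balances classes deterministically with provenance", {
  specs <- endoscopy_class_specs(2)
  counts <- stats::setNames(c(4, 10), vapply(specs, function(s) s$name, character(1)))
  d <- make_dataset(specs, counts, seed = 1, height = 32, width = 32)
  plan <- list(quota = augmentation_quota(counts), seed = 42)
  a1 <- augment_dataset(d, plan)
  labs <- vapply(a1$frames, function(f) f$label, character(1))
  expect_true(all(table(labs) == 11))              # both classes at floor(11)
  a2 <- augment_dataset(d, plan)
  expect_identical(dataset_manifest(a1), dataset_manifest(a2))
  new_ids <- setdiff(vapply(a1$frames, function(f) f$id, character(1)),
                     vapply(d$frames, function(f) f$id, character(1)))
  expect_true(all(grepl("_aug\\d+$", new_ids)))    # provenance ids
  src <- sub("_aug\\d+$", "", new_ids)
  expect_true(all(src %in% vapply(d$frames, function(f) f$id, character(1))))
  plan_extra <- list(quota = c(plan$quota, ghost = 5L), seed = 42)
  expect_warning(augment_dataset(d, plan_extra), "unseen class")
})
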