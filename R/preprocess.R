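# Specular reflection detection and removal, plus class-balancing
# augmentation.
#
# Detection is a two-stage threshold scheme on the grayscale frame: pixels
# brighter than `strong` (default 180) are certain reflections; pixels
# brighter than `weak` (default 130) are absorbed into the mask when they
# touch it, iterated to a fixed point (hysteresis). The masked region is
# then reconstructed by inpainting, either a fast-marching scheme in the
# style of Telea (2004) or a diffusion (harmonic) fill standing in for the
# Navier-Stokes variant.

REFLECT_STRONG <- 180L
REFLECT_WEAK <- 130L

#' Convert a frame to 8-bit grayscale
#'
#' Uses BT.601 luma (0.299 R + 0.587 G + 0.114 B), rounded half-up and
#' clamped to \[0, 255\]. This is the grayscale every threshold in the
#' reflection pipeline is defined on.
#'
#' @param frame an `endo_frame`.
#' @return an integer H x W matrix in \[0, 255\].
#' @export
to_grayscale <- function(frame) {
  stopifnot(is_frame(frame))
  px <- frame$pixels
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  g <- floor(g + 0.5)  # half-up, not banker's rounding
  g[g < 0] <- 0; g[g > 255] <- 255
  dim(g) <- dim(px)[1:2]   # keep matrix shape even for 1-pixel-high frames
  storage.mode(g) <- "integer"
  g
}

#' Detect strong specular reflections
#'
#' A pixel is a strong reflection iff its grayscale value strictly exceeds
#' `strong` (default 180).
#'
#' @param gray integer grayscale matrix.
#' @param strong strong-reflection threshold.
#' @return binary mask matrix with values in \{0, 255\}.
#' @export
detect_strong <- function(gray, strong = REFLECT_STRONG) {
  stopifnot(is.matrix(gray))
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[gray > strong] <- 255L
  m
}

#' Expand a reflection mask into the weak-reflection band
#'
#' Iterates to a fixed point: a pixel joins the mask when its grayscale
#' value strictly exceeds `weak` (default 130) and at least one of its 8
#' neighbors is already masked. Strong pixels are always retained; the
#' result is a superset of the input mask.
#'
#' @param gray integer grayscale matrix.
#' @param strong binary mask of strong reflections.
#' @param weak weak-band threshold.
#' @return binary mask matrix in \{0, 255\}.
#' @export
expand_weak <- function(gray, strong, weak = REFLECT_WEAK) {
  if (!all(dim(gray) == dim(strong)))
    stop("gray and mask shapes differ", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  cand <- gray > weak
  cur <- strong != 0
  repeat {
    # 8-neighbor dilation of the current mask by shifted logical ORs
    nb <- matrix(FALSE, h, w)
    nb[-1, ] <- nb[-1, ] | cur[-h, ]
    nb[-h, ] <- nb[-h, ] | cur[-1, ]
    nb[, -1] <- nb[, -1] | cur[, -w]
    nb[, -w] <- nb[, -w] | cur[, -1]
    nb[-1, -1] <- nb[-1, -1] | cur[-h, -w]
    nb[-1, -w] <- nb[-1, -w] | cur[-h, -1]
    nb[-h, -1] <- nb[-h, -1] | cur[-1, -w]
    nb[-h, -w] <- nb[-h, -w] | cur[-1, -1]
    nxt <- cur | (cand & nb)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  m <- matrix(0L, h, w)
  m[cur] <- 255L
  m
}

square_dilate <- function(mask, px) {
  if (px == 0L) return(mask)
  cur <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  for (k in seq_len(px)) {
    nb <- cur
    nb[-1, ] <- nb[-1, ] | cur[-h, ]
    nb[-h, ] <- nb[-h, ] | cur[-1, ]
    nb[, -1] <- nb[, -1] | cur[, -w]
    nb[, -w] <- nb[, -w] | cur[, -1]
    nb[-1, -1] <- nb[-1, -1] | cur[-h, -w]
    nb[-1, -w] <- nb[-1, -w] | cur[-h, -1]
    nb[-h, -1] <- nb[-h, -1] | cur[-1, -w]
    nb[-h, -w] <- nb[-h, -w] | cur[-1, -1]
    cur <- nb
  }
  m <- matrix(0L, h, w)
  m[cur] <- 255L
  m
}

#' Build the full reflection mask for a frame
#'
#' Composition of strong-threshold detection, weak-band fixed-point
#' expansion and a square morphological dilation (default 1 px) so the
#' inpainting boundary is not itself reflection-contaminated.
#'
#' @param frame an `endo_frame`.
#' @param dilate_px non-negative dilation amount in pixels.
#' @param strong,weak thresholds, see [detect_strong()] and
#'   [expand_weak()].
#' @return binary mask matrix in \{0, 255\}.
#' @export
build_mask <- function(frame, dilate_px = 1L, strong = REFLECT_STRONG,
                       weak = REFLECT_WEAK) {
  if (dilate_px < 0) stop("dilate_px must be >= 0", call. = FALSE)
  g <- to_grayscale(frame)
  square_dilate(expand_weak(g, detect_strong(g, strong), weak),
                as.integer(dilate_px))
}

#' Remove reflections by inpainting the masked region
#'
#' Pixels where the mask is zero are returned bit-identical; masked pixels
#' are reconstructed from the surrounding image. `fmm_telea` is a
#' fast-marching inpainting in the style of Telea (2004): masked pixels are
#' filled in increasing distance from the known region, each as a
#' distance-, direction- and level-weighted average (with a first-order
#' gradient term) of already-known pixels within `radius`.
#' `navier_stokes` is a diffusion fill: the masked region is relaxed to the
#' harmonic interpolant of its boundary, a light-weight stand-in for the
#' fluid-dynamics formulation.
#'
#' @param frame an `endo_frame`.
#' @param mask binary mask (nonzero = inpaint).
#' @param method `"fmm_telea"` or `"navier_stokes"`.
#' @param radius positive inpainting neighborhood radius in pixels.
#' @return an `endo_frame` with the masked region reconstructed.
#' @export
remove_reflections <- function(frame, mask, method = c("fmm_telea", "navier_stokes"),
                               radius = 3) {
  stopifnot(is_frame(frame))
  method <- match.arg(method)
  if (!all(dim(frame$pixels)[1:2] == dim(mask)))
    stop("frame and mask shapes differ", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (!any(mask != 0)) return(frame)
  px <- frame$pixels * 1.0
  out <- if (method == "fmm_telea") inpaint_fmm(px, mask != 0, radius)
         else inpaint_diffusion(px, mask != 0)
  res <- clamp8(out)
  # contract: unmasked pixels bit-identical
  keep <- array(rep(mask == 0, 3L), dim = dim(px))
  res[keep] <- frame$pixels[keep]
  new_frame(res, id = frame$id, label = frame$label)
}

# Fast-marching inpainting. `px` is a numeric H x W x 3 array, `inside`
# a logical matrix of pixels to fill. Distances T are propagated from the
# mask boundary by solving the eikonal update on a narrow band; pixels are
# finalized in increasing T and painted from KNOWN neighbors.
inpaint_fmm <- function(px, inside, radius) {
  h <- dim(px)[1]; w <- dim(px)[2]
  BIG <- 1e6
  KNOWN <- 0L; BAND <- 1L; INSIDE <- 2L
  state <- matrix(KNOWN, h, w)
  state[inside] <- INSIDE
  tt <- matrix(0, h, w)
  tt[inside] <- BIG
  # initial band: known pixels adjacent (4-conn) to the inside
  band <- integer(0)
  ins_idx <- which(inside)
  for (p in ins_idx) {
    r <- (p - 1L) %% h + 1L; cl <- (p - 1L) %/% h + 1L
    for (k in 1:4) {
      rr <- r + c(-1L, 1L, 0L, 0L)[k]; cc <- cl + c(0L, 0L, -1L, 1L)[k]
      if (rr < 1L || rr > h || cc < 1L || cc > w) next
      q <- (cc - 1L) * h + rr
      if (state[q] == KNOWN && !(q %in% band)) band <- c(band, q)
    }
  }
  if (!length(band)) {  # fully-masked frame: fall back to diffusion fill
    return(inpaint_diffusion(px, inside))
  }
  state[band] <- BAND
  tt[band] <- 0
  eikonal <- function(r, cl) {
    # quadrant-wise two-neighbor eikonal solution, min over quadrants
    sol <- BIG
    for (s in list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
      r1 <- r + s[1]; c1 <- cl + s[2]
      t1 <- if (r1 >= 1L && r1 <= h && state[r1, cl] == KNOWN) tt[r1, cl] else BIG
      t2 <- if (c1 >= 1L && c1 <= w && state[r, c1] == KNOWN) tt[r, c1] else BIG
      tm <- min(t1, t2)
      cand <- if (abs(t1 - t2) < 1) {
        d <- 2 - (t1 - t2)^2
        if (d > 0) (t1 + t2 + sqrt(d)) / 2 else tm + 1
      } else tm + 1
      sol <- min(sol, cand)
    }
    sol
  }
  paint <- function(r, cl) {
    rr0 <- max(1L, r - ceiling(radius)); rr1 <- min(h, r + ceiling(radius))
    cc0 <- max(1L, cl - ceiling(radius)); cc1 <- min(w, cl + ceiling(radius))
    num <- c(0, 0, 0); den <- 0
    gy <- tt_grad(r, cl, 1L); gx <- tt_grad(r, cl, 2L)
    for (rr in rr0:rr1) for (cc in cc0:cc1) {
      if (state[rr, cc] != KNOWN) next
      dy <- r - rr; dx <- cl - cc
      d2 <- dy * dy + dx * dx
      if (d2 > radius * radius || d2 == 0) next
      # Telea weights: direction, geometric distance, level-set distance
      dir <- abs(dy * gy + dx * gx) / sqrt(d2)
      if (dir < 1e-6) dir <- 1e-6
      wgt <- dir * (1 / (d2 * sqrt(d2))) * (1 / (1 + abs(tt[rr, cc] - tt[r, cl])))
      # first-order term from the image gradient at the known pixel
      for (ch in 1:3) {
        gr <- img_grad(rr, cc, ch)
        num[ch] <- num[ch] + wgt * (px[rr, cc, ch] + gr[1] * dy + gr[2] * dx)
      }
      den <- den + wgt
    }
    if (den > 0) num / den else px[r, cl, ]
  }
  tt_grad <- function(r, cl, axis) {
    if (axis == 1L) {
      a <- if (r > 1L && state[r - 1L, cl] != INSIDE) tt[r - 1L, cl] else NA
      b <- if (r < h && state[r + 1L, cl] != INSIDE) tt[r + 1L, cl] else NA
    } else {
      a <- if (cl > 1L && state[r, cl - 1L] != INSIDE) tt[r, cl - 1L] else NA
      b <- if (cl < w && state[r, cl + 1L] != INSIDE) tt[r, cl + 1L] else NA
    }
    if (!is.na(a) && !is.na(b)) (b - a) / 2
    else if (!is.na(b)) b - tt[r, cl]
    else if (!is.na(a)) tt[r, cl] - a
    else 0
  }
  img_grad <- function(r, cl, ch) {
    gy <- 0; gx <- 0
    if (r > 1L && r < h && state[r - 1L, cl] == KNOWN && state[r + 1L, cl] == KNOWN)
      gy <- (px[r + 1L, cl, ch] - px[r - 1L, cl, ch]) / 2
    if (cl > 1L && cl < w && state[r, cl - 1L] == KNOWN && state[r, cl + 1L] == KNOWN)
      gx <- (px[r, cl, ch] - px[r, cl - 1L, ch]) / 2
    c(gy, gx)
  }
  band_t <- tt[band]
  while (length(band)) {
    i <- which.min(band_t)
    p <- band[i]
    band <- band[-i]; band_t <- band_t[-i]
    r <- (p - 1L) %% h + 1L; cl <- (p - 1L) %/% h + 1L
    state[r, cl] <- KNOWN
    for (k in 1:4) {
      rr <- r + c(-1L, 1L, 0L, 0L)[k]; cc <- cl + c(0L, 0L, -1L, 1L)[k]
      if (rr < 1L || rr > h || cc < 1L || cc > w) next
      if (state[rr, cc] == KNOWN) next
      if (state[rr, cc] == INSIDE) {
        tt[rr, cc] <- eikonal(rr, cc)
        px[rr, cc, ] <- paint(rr, cc)
        state[rr, cc] <- BAND
        band <- c(band, (cc - 1L) * h + rr)
        band_t <- c(band_t, tt[rr, cc])
      } else {
        nt <- eikonal(rr, cc)
        if (nt < tt[rr, cc]) {
          tt[rr, cc] <- nt
          band_t[band == (cc - 1L) * h + rr] <- nt
        }
      }
    }
  }
  px
}

# Harmonic (diffusion) inpainting: Jacobi relaxation of the Laplace
# equation on the masked region with the known pixels as boundary data.
inpaint_diffusion <- function(px, inside, max_iter = 2000L, tol = 1e-3) {
  h <- dim(px)[1]; w <- dim(px)[2]
  if (all(inside)) {  # nothing known: leave as-is
    return(px)
  }
  # initialize masked pixels at the mean of the known region
  for (ch in 1:3) {
    pl <- px[, , ch]
    pl[inside] <- mean(pl[!inside])
    px[, , ch] <- pl
  }
  idx <- which(inside)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (ch in 1:3) {
      pl <- px[, , ch]
      up <- rbind(pl[1, , drop = FALSE], pl[-h, , drop = FALSE])
      dn <- rbind(pl[-1, , drop = FALSE], pl[h, , drop = FALSE])
      lf <- cbind(pl[, 1, drop = FALSE], pl[, -w, drop = FALSE])
      rt <- cbind(pl[, -1, drop = FALSE], pl[, w, drop = FALSE])
      avg <- (up + dn + lf + rt) / 4
      delta <- max(delta, max(abs(avg[idx] - pl[idx])))
      pl[idx] <- avg[idx]
      px[, , ch] <- pl
    }
    if (delta < tol) break
  }
  px
}

#' Per-class augmentation quota for class balancing
#'
#' The total number of images to generate for class C is
#' `floor(1.1 * max_count - count(C))`, clamped at zero, so originals plus
#' generated images leave every class within one image of 1.1 times the
#' majority count.
#'
#' @param counts named numeric/integer vector (or list) of per-class image
#'   counts, all >= 1.
#' @return named integer vector of per-class generation quotas.
#' @export
augmentation_quota <- function(counts) {
  counts <- if (is.table(counts)) stats::setNames(as.vector(counts), names(counts))
            else unlist(counts)
  if (!length(counts)) stop("counts must be non-empty", call. = FALSE)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  top <- max(counts)
  quota <- pmax(floor(1.1 * top - counts), 0)  # pmax(x, 0) keeps names
  storage.mode(quota) <- "integer"
  quota
}

#' Apply one random image manipulation
#'
#' The five manipulations used for balancing: `rotate` (random angle),
#' `flip` (random axis, or a fixed `axis`), `crop` (random square between
#' the working floor and the original, resized back), `resize` (down and
#' back up through a random intermediate size) and `noise` (clipped
#' Gaussian noise). The crop/resize floor is 256 px, or the image size when
#' smaller.
#'
#' @param frame an `endo_frame`.
#' @param kind one of `"rotate"`, `"flip"`, `"crop"`, `"resize"`, `"noise"`.
#' @param rng ignored placeholder for API symmetry; randomness is drawn from
#'   the current RNG stream.
#' @param axis optional fixed flip axis (`"horizontal"` or `"vertical"`).
#' @param sigma Gaussian noise standard deviation (default 8 intensity
#'   levels).
#' @return a manipulated `endo_frame` of the same size.
#' @export
apply_manipulation <- function(frame, kind, rng = NULL, axis = NULL, sigma = 8) {
  stopifnot(is_frame(frame))
  px <- frame$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  floor_sz <- min(256L, h, w)
  out <- switch(kind,
    rotate = clamp8(rotate_raster(px * 1.0, stats::runif(1, 0, 360))),
    flip = {
      ax <- if (is.null(axis)) sample(c("horizontal", "vertical"), 1L) else axis
      if (ax == "horizontal") px[, w:1, , drop = FALSE]
      else px[h:1, , , drop = FALSE]
    },
    crop = {
      side <- sample_range(floor_sz, min(h, w))
      r0 <- sample_range(1L, h - side + 1L)
      c0 <- sample_range(1L, w - side + 1L)
      sub <- px[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , drop = FALSE]
      clamp8(resize_bilinear(sub * 1.0, h, w))
    },
    resize = {
      side <- sample_range(floor_sz, min(h, w))
      clamp8(resize_bilinear(resize_bilinear(px * 1.0, side, side), h, w))
    },
    noise = {
      if (sigma == 0) px
      else clamp8(px + stats::rnorm(length(px), 0, sigma))
    },
    stop("unknown manipulation kind: ", kind, call. = FALSE)
  )
  dim(out) <- c(h, w, 3L)
  new_frame(out, id = frame$id, label = frame$label)
}

#' Balance a labeled dataset by augmentation
#'
#' Appends exactly `plan$quota[C]` generated frames per class C. Source
#' frames are chosen round-robin within their class and each generated
#' frame applies one randomly chosen manipulation from `plan$manipulations`.
#' Originals are untouched; generated frames carry the provenance id of
#' their source (`<source_id>_aug<k>`). Deterministic for a fixed
#' `plan$seed`.
#'
#' @param data an `endo_dataset` (see [make_dataset()]).
#' @param plan list with `quota` (named integer vector), `manipulations`
#'   (character subset of the five kinds) and `seed`.
#' @return an augmented `endo_dataset`.
#' @export
augment_dataset <- function(data, plan) {
  stopifnot(inherits(data, "endo_dataset"))
  quota <- plan$quota
  manip <- plan$manipulations %||% c("rotate", "flip", "crop", "resize", "noise")
  labels <- vapply(data$frames, function(f) f$label, character(1))
  missing_q <- setdiff(unique(labels), names(quota))
  if (length(missing_q))
    stop("plan quota missing classes: ", paste(missing_q, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(quota), unique(labels))
  if (length(extra))
    warning("quota for unseen class(es) ignored: ",
            paste(extra, collapse = ", "))
  new_frames <- list()
  withr_seed(plan$seed %||% 0L, {
    for (cls in intersect(names(quota), unique(labels))) {
      src <- which(labels == cls)
      q <- quota[[cls]]
      if (q <= 0) next
      for (k in seq_len(q)) {
        f <- data$frames[[src[(k - 1L) %% length(src) + 1L]]]
        kind <- sample(manip, 1L)
        g <- apply_manipulation(f, kind)
        g$id <- sprintf("%s_aug%d", f$id, k)
        new_frames[[length(new_frames) + 1L]] <- g
      }
    }
  })
  out <- data
  out$frames <- c(data$frames, new_frames)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform integer draw on [lo, hi]; sample(x, 1) misbehaves when length 1
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Evaluate `expr` under a local, restored RNG seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
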