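# Synthetic endoscopy-like fixtures: class-conditional frames, injected
# specular reflections with ground-truth masks, imbalanced labeled
# datasets, and probability matrices with planted per-class thresholds.
# Everything downstream of this file is testable offline against these
# generators.

#' Specification of a synthetic image class
#'
#' @param name class label.
#' @param base_color RGB triple in \[0, 255\]. Choose colors whose BT.601
#'   luma stays below ~120 so the weak-reflection band (>130) is reached
#'   only by injected highlights.
#' @param texture one of `"smooth"`, `"speckle"`, `"striped"`.
#' @param texture_scale positive integer texture period in pixels.
#' @return a `class_spec` list.
#' @export
class_spec <- function(name, base_color, texture = c("smooth", "speckle", "striped"),
                       texture_scale = 8L) {
  texture <- match.arg(texture)
  base_color <- as.numeric(base_color)
  if (length(base_color) != 3L || any(base_color < 0) || any(base_color > 255))
    stop("base_color must be an RGB triple in [0, 255]", call. = FALSE)
  if (texture_scale < 1) stop("texture_scale must be >= 1", call. = FALSE)
  structure(list(name = as.character(name), base_color = base_color,
                 texture = texture, texture_scale = as.integer(texture_scale)),
            class = "class_spec")
}

#' Built-in endoscopy-like class palette
#'
#' Mucosa-inspired base colors (reddish/pinkish, mid-dark so the grayscale
#' stays clear of the reflection thresholds) with varied textures.
#'
#' @param n number of classes (up to 8).
#' @return list of [class_spec()] objects.
#' @export
endoscopy_class_specs <- function(n = 4L) {
  pal <- list(
    class_spec("mucosa_smooth",  c(150,  60,  55), "smooth",  8L),
    class_spec("polyp_speckle",  c(120,  85,  60), "speckle", 6L),
    class_spec("vascular_stripe", c(90,  50,  95), "striped", 7L),
    class_spec("dyed_speckle",   c(55,  75, 140), "speckle", 10L),
    class_spec("bile_smooth",    c(120, 110,  40), "smooth",  8L),
    class_spec("ulcer_stripe",   c(140,  90,  90), "striped", 12L),
    class_spec("stool_speckle",  c(110,  90,  35), "speckle", 4L),
    class_spec("lumen_smooth",   c(60,  45,  45), "smooth",  8L))
  if (n < 1L || n > length(pal)) stop("n must be in 1..8", call. = FALSE)
  pal[seq_len(n)]
}

#' Generate one synthetic frame
#'
#' Deterministic for a fixed seed. The raster is the class base color
#' modulated by the class texture plus Gaussian noise, then rescaled so
#' that no pixel's BT.601 grayscale value exceeds 170 -- headroom that
#' guarantees injected reflections are the only pixels the strong
#' threshold (180) can fire on.
#'
#' @param spec a [class_spec()].
#' @param height,width frame size, both >= 32.
#' @param seed integer seed.
#' @return an `endo_frame` labeled with `spec$name`.
#' @export
make_frame <- function(spec, height = 64L, width = 64L, seed = 0L) {
  stopifnot(inherits(spec, "class_spec"))
  if (height < 32L || width < 32L)
    stop("frame size must be at least 32 x 32", call. = FALSE)
  withr_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    base <- spec$base_color
    mod <- switch(spec$texture,
      smooth = matrix(0, h, w),
      speckle = {
        # low-resolution blob field upsampled to frame size
        gh <- max(2L, ceiling(h / spec$texture_scale))
        gw <- max(2L, ceiling(w / spec$texture_scale))
        resize_bilinear(matrix(stats::rnorm(gh * gw, 0, 28), gh, gw), h, w)
      },
      striped = {
        ph <- stats::runif(1, 0, 2 * pi)
        ang <- stats::runif(1, 0, pi)
        gy <- matrix(seq_len(h), h, w); gx <- matrix(seq_len(w), h, w, byrow = TRUE)
        25 * sin(2 * pi * (gy * cos(ang) + gx * sin(ang)) / spec$texture_scale + ph)
      })
    px <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3)
      px[, , ch] <- base[ch] + mod + stats::rnorm(h * w, 0, 5)
    px <- clamp8(px)
    f <- new_frame(px, id = sprintf("%s_s%d", spec$name, seed), label = spec$name)
    # enforce the <= 170 grayscale headroom with the production converter
    repeat {
      g <- to_grayscale(f)
      if (max(g) <= 170L) break
      f$pixels <- clamp8(f$pixels * (169 / max(g)))
    }
    f
  })
}

#' Inject specular reflections with a ground-truth mask
#'
#' Each spot is a filled ellipse core whose grayscale strictly exceeds 180,
#' surrounded by a Gaussian-faded halo with grayscale in (130, 180\].
#' Spots are placed fully inside the frame and far enough apart that the
#' returned mask has exactly `n_spots` 8-connected components. Pixels
#' outside the mask are unchanged.
#'
#' @param frame an `endo_frame`.
#' @param n_spots non-negative number of reflection spots.
#' @param seed integer seed.
#' @return list with elements `frame` (contaminated copy) and `mask`
#'   (ground-truth binary matrix, core plus halo).
#' @export
inject_reflections <- function(frame, n_spots = 3L, seed = 0L) {
  stopifnot(is_frame(frame))
  if (n_spots < 0) stop("n_spots must be >= 0", call. = FALSE)
  h <- dim(frame$pixels)[1]; w <- dim(frame$pixels)[2]
  mask <- matrix(0L, h, w)
  if (n_spots == 0L) return(list(frame = frame, mask = mask))
  px <- frame$pixels * 1.0
  withr_seed(seed, {
    ext <- 8L            # max spot extent (core radius <= 4 + halo 3 + 1)
    min_sep <- 2L * ext + 3L
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(centers) < n_spots) {
      attempts <- attempts + 1L
      if (attempts > 2000L)
        stop("could not place ", n_spots, " non-touching spots in a ",
             h, "x", w, " frame", call. = FALSE)
      cy <- stats::runif(1, ext + 1, h - ext)
      cx <- stats::runif(1, ext + 1, w - ext)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >= min_sep))
        centers <- rbind(centers, c(cy, cx))
    }
    for (s in seq_len(n_spots)) {
      cy <- centers[s, 1]; cx <- centers[s, 2]
      ry <- stats::runif(1, 2, 4); rx <- stats::runif(1, 2, 4)
      th <- stats::runif(1, 0, pi)
      rho_halo <- 1 + 3 / min(ry, rx)   # halo width ~3 px
      core_v <- stats::runif(1, 215, 245)
      r0 <- max(1L, floor(cy - ext)); r1 <- min(h, ceiling(cy + ext))
      c0 <- max(1L, floor(cx - ext)); c1 <- min(w, ceiling(cx + ext))
      for (r in r0:r1) for (cc in c0:c1) {
        dy <- r - cy; dx <- cc - cx
        u <- cos(th) * dy + sin(th) * dx
        v <- -sin(th) * dy + cos(th) * dx
        rho <- sqrt((u / ry)^2 + (v / rx)^2)
        if (rho <= 1) {
          px[r, cc, ] <- core_v
          mask[r, cc] <- 255L
        } else if (rho <= rho_halo) {
          # Gaussian fade from just under 180 into the weak band
          val <- 140 + 38 * exp(-2 * ((rho - 1) / (rho_halo - 1))^2)
          px[r, cc, ] <- val
          mask[r, cc] <- 255L
        }
      }
    }
  })
  out <- frame
  out$pixels <- clamp8(px)
  list(frame = out, mask = mask)
}

#' Generate an imbalanced labeled dataset
#'
#' Per-class counts match `imbalance` exactly; generation is deterministic
#' per seed (each frame gets its own derived seed). Emulates the severe
#' class imbalance of public GI endoscopy collections, where minority
#' classes can have under ten images against majority classes in the
#' thousands.
#'
#' @param specs list of [class_spec()] covering every label in `imbalance`.
#' @param imbalance named vector/list mapping label to a positive count.
#' @param seed integer seed.
#' @param height,width frame size.
#' @return an `endo_dataset`: list with `frames` (list of `endo_frame`)
#'   and `classes` (label ordering).
#' @export
make_dataset <- function(specs, imbalance, seed = 0L, height = 64L, width = 64L) {
  counts <- unlist(imbalance)
  if (length(counts) < 1L || any(counts < 1))
    stop("imbalance needs positive counts", call. = FALSE)
  spec_names <- vapply(specs, function(s) s$name, character(1))
  missing <- setdiff(names(counts), spec_names)
  if (length(missing))
    stop("no class_spec for: ", paste(missing, collapse = ", "), call. = FALSE)
  frames <- list()
  for (cls in names(counts)) {
    sp <- specs[[match(cls, spec_names)]]
    for (i in seq_len(counts[[cls]])) {
      fseed <- (as.numeric(seed) * 1000003 + match(cls, names(counts)) * 7919 + i) %%
        .Machine$integer.max
      f <- make_frame(sp, height, width, seed = fseed)
      f$id <- sprintf("%s_%04d", cls, i)
      frames[[length(frames) + 1L]] <- f
    }
  }
  structure(list(frames = frames, classes = names(counts)),
            class = "endo_dataset")
}

#' @export
print.endo_dataset <- function(x, ...) {
  labs <- vapply(x$frames, function(f) f$label, character(1))
  cat("<endo_dataset>", length(x$frames), "frames\n")
  print(table(labs))
  invisible(x)
}

#' Dataset manifest as a data frame
#' @param data an `endo_dataset`.
#' @return data.frame with columns `id`, `label`.
#' @export
dataset_manifest <- function(data) {
  data.frame(id = vapply(data$frames, function(f) f$id, character(1)),
             label = vapply(data$frames, function(f) f$label, character(1)),
             stringsAsFactors = FALSE)
}

#' Write a dataset as a class-per-directory PNG tree
#'
#' Writes `<dir>/<label>/<id>.png` for every frame plus a `manifest.csv`
#' (columns: path, label) at the root.
#'
#' @param data an `endo_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(data$frames, function(f) {
    d <- file.path(dir, f$label)
    dir.create(d, showWarnings = FALSE)
    p <- file.path(d, paste0(f$id, ".png"))
    write_frame_png(f, p)
    data.frame(path = file.path(f$label, paste0(f$id, ".png")),
               label = f$label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a class-per-directory dataset
#'
#' Reads via `manifest.csv` when present, otherwise by scanning
#' per-class subdirectories of PNG files.
#'
#' @param dir dataset root.
#' @return an `endo_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  } else {
    dirs <- list.dirs(dir, recursive = FALSE)
    manifest <- do.call(rbind, lapply(dirs, function(d) {
      fs <- list.files(d, pattern = "\\.png$")
      if (!length(fs)) return(NULL)
      data.frame(path = file.path(basename(d), fs), label = basename(d),
                 stringsAsFactors = FALSE)
    }))
  }
  frames <- lapply(seq_len(nrow(manifest)), function(i) {
    read_frame_png(file.path(dir, manifest$path[i]),
                   id = sub("\\.png$", "", basename(manifest$path[i])),
                   label = manifest$label[i])
  })
  structure(list(frames = frames, classes = unique(manifest$label)),
            class = "endo_dataset")
}

#' Synthetic probability matrix with planted per-class thresholds
#'
#' Scores keep a symmetric margin band of half-width
#' `m = min(1 / (2 (1 + s)), t/2, (1-t)/2)` around each planted threshold
#' `t`: own-class scores are `(t + m) + (1 - t - m) * Beta(1, s)` (above
#' the band) and off-class scores `(t - m) * (1 - Beta(1, s))` (below
#' it), with `s` the per-class separation. Larger `s` both narrows the
#' band and concentrates the scores against its edges, so the planted
#' vector becomes the unique grid optimum; the band midpoint is the
#' planted threshold, which is what the maximum-margin tie-break of the
#' grid-search oracle recovers. Oracle thresholds are recomputed by
#' [grid_search_thresholds()].
#'
#' @param n_per_class samples per class.
#' @param planted_thresholds numeric vector of per-class thresholds in
#'   (0, 1); class names taken from its names (or `class1..K`).
#' @param separation per-class (or scalar) separation > 0.
#' @param seed integer seed.
#' @return list with `probs` (n x K matrix, values in (0,1)), `labels`
#'   (integer class indices 1..K), `oracle_thresholds` and `oracle_f1`.
#' @export
make_probability_matrix <- function(n_per_class = 30L, planted_thresholds,
                                    separation = 6, seed = 0L, rule = "margin") {
  t <- as.numeric(planted_thresholds)
  K <- length(t)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(t <= 0) || any(t >= 1))
    stop("planted thresholds must lie strictly inside (0, 1)", call. = FALSE)
  s <- rep_len(as.numeric(separation), K)
  if (any(s <= 0)) stop("separation must be > 0", call. = FALSE)
  cls_names <- names(planted_thresholds) %||% paste0("class", seq_len(K))
  n <- n_per_class * K
  labels <- rep(seq_len(K), each = n_per_class)
  probs <- matrix(0, n, K, dimnames = list(NULL, cls_names))
  withr_seed(seed, {
    for (k in seq_len(K)) {
      m <- min(1 / (2 * (1 + s[k])), t[k] / 2, (1 - t[k]) / 2)
      own <- labels == k
      probs[own, k] <- (t[k] + m) + (1 - t[k] - m) * stats::rbeta(sum(own), 1, s[k])
      probs[!own, k] <- (t[k] - m) * (1 - stats::rbeta(sum(!own), 1, s[k]))
    }
  })
  probs <- pmin(pmax(probs, 1e-6), 1 - 1e-6)
  orac <- grid_search_thresholds(probs, labels, rule = rule)
  list(probs = probs, labels = labels,
       oracle_thresholds = orac$thresholds, oracle_f1 = orac$f1)
}

#' Coordinate-wise exhaustive grid search for per-class thresholds
#'
#' Independent oracle for the genetic threshold search: sweeps each class
#' threshold over \{0.00, 0.01, ..., 0.99\} maximizing macro F1 under the
#' [decide()] rule, holding the others fixed, repeating passes until the
#' threshold vector stabilizes. Ties break toward the median tied grid
#' value -- the maximum-margin choice, which centers the threshold in the
#' empty band between the score groups.
#'
#' @param probs n x K probability matrix.
#' @param labels integer class indices 1..K.
#' Under the default margin rule, thresholds are identifiable only up to
#' a uniform shift (equal shifts preserve every margin comparison); use
#' `rule = "raw"` when the planted thresholds themselves must be
#' recovered.
#'
#' @param grid candidate threshold values.
#' @param rule decision rule, see [decide()].
#' @return list with `thresholds` and `f1`.
#' @export
grid_search_thresholds <- function(probs, labels, grid = seq(0, 0.99, by = 0.01),
                                   rule = "margin") {
  K <- ncol(probs)
  th <- rep(0.5, K)
  for (pass in 1:6) {
    prev <- th
    for (k in seq_len(K)) {
      f1s <- vapply(grid, function(g) {
        cand <- th; cand[k] <- g
        ga_fitness(cand, probs, labels, rule = rule)
      }, numeric(1))
      tied <- grid[f1s >= max(f1s) - 1e-12]
      th[k] <- tied[ceiling(length(tied) / 2)]
    }
    if (identical(th, prev)) break
  }
  list(thresholds = th, f1 = ga_fitness(th, probs, labels, rule = rule))
}

#' Write / read a probability matrix as CSV
#'
#' The matrix CSV has the class names as header and one row per sample; a
#' parallel labels CSV holds the true class of each row.
#'
#' @param probs n x K matrix.
#' @param labels integer labels.
#' @param probs_path,labels_path file paths.
#' @export
write_probability_csv <- function(probs, labels, probs_path, labels_path) {
  utils::write.csv(as.data.frame(probs), probs_path, row.names = FALSE)
  utils::write.csv(data.frame(label = labels), labels_path, row.names = FALSE)
  invisible(probs_path)
}

#' @rdname write_probability_csv
#' @export
read_probability_csv <- function(probs_path, labels_path) {
  probs <- as.matrix(utils::read.csv(probs_path, check.names = FALSE))
  labels <- utils::read.csv(labels_path)$label
  list(probs = probs, labels = labels)
}
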