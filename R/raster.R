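# Internal raster utilities shared by the fixture generator, the
# preprocessing stage and the descriptor bank. Frames are plain R lists
# holding an H x W x 3 integer array in [0, 255] -- deliberately simple so
# every operation is inspectable and deterministic.

#' Construct an endoscopy frame
#'
#' A frame is the unit flowing through the pipeline: an 8-bit RGB raster
#' plus an identifier and an optional class label.
#'
#' @param pixels integer array of dimension H x W x 3 with values in
#'   \[0, 255\].
#' @param id character identifier.
#' @param label optional class label (`NA` when unlabeled).
#' @return an object of class `endo_frame`.
#' @export
new_frame <- function(pixels, id = "frame", label = NA_character_) {
  pixels <- check_pixels(pixels)
  structure(list(pixels = pixels, id = as.character(id),
                 label = as.character(label)),
            class = "endo_frame")
}

check_pixels <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("frame must have positive extent", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must be integers in [0, 255]", call. = FALSE)
  pixels
}

#' @export
print.endo_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<endo_frame %s: %d x %d, label=%s>\n", x$id, d[1], d[2],
              x$label))
  invisible(x)
}

is_frame <- function(x) inherits(x, "endo_frame")

clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

# Bilinear resize of a matrix or an H x W x C array.
resize_bilinear <- function(x, out_h, out_w) {
  was_matrix <- is.matrix(x)
  if (was_matrix) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  h <- d[1]; w <- d[2]; nc <- d[3]
  # sample centers aligned to pixel centers
  ys <- if (out_h == 1L) rep((h + 1) / 2, 1L) else (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- if (out_w == 1L) rep((w + 1) / 2, 1L) else (seq_len(out_w) - 0.5) * w / out_w + 0.5
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1L); y0[h == 1L] <- 1L
  x0 <- pmin(floor(xs), w - 1L); x0[w == 1L] <- 1L
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  fy <- ys - y0; fx <- xs - x0
  out <- array(0, dim = c(out_h, out_w, nc))
  for (ch in seq_len(nc)) {
    pl <- x[, , ch]
    dim(pl) <- c(h, w)   # guard against dim dropping for 1-pixel planes
    a <- pl[y0, x0, drop = FALSE]; b <- pl[y0, x1, drop = FALSE]
    c2 <- pl[y1, x0, drop = FALSE]; d2 <- pl[y1, x1, drop = FALSE]
    wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
    out[, , ch] <- a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
      c2 * wy * (1 - wx) + d2 * wy * wx
  }
  if (was_matrix) out <- out[, , 1L]
  out
}

# Reflect (mirror) index into [1, n]; used for rotation padding.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period
  ifelse(i < n, i + 1L, period - i)
}

# Rotate an H x W x C array by `angle` degrees about its center,
# bilinear sampling with reflection padding for exposed corners.
rotate_raster <- function(x, angle) {
  was_matrix <- is.matrix(x)
  if (was_matrix) dim(x) <- c(dim(x), 1L)
  d <- dim(x); h <- d[1]; w <- d[2]; nc <- d[3]
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(seq_len(h), h, w) - cy
  gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: source = R(-th) %*% target
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- reflect_index(as.integer(y0), h)
  iy1 <- reflect_index(as.integer(y0) + 1L, h)
  ix0 <- reflect_index(as.integer(x0), w)
  ix1 <- reflect_index(as.integer(x0) + 1L, w)
  out <- array(0, dim = d)
  for (ch in seq_len(nc)) {
    pl <- x[, , ch]
    a <- pl[cbind(c(iy0), c(ix0))]; b <- pl[cbind(c(iy0), c(ix1))]
    c2 <- pl[cbind(c(iy1), c(ix0))]; d2 <- pl[cbind(c(iy1), c(ix1))]
    v <- a * (1 - fy) * (1 - fx) + b * (1 - fy) * fx +
      c2 * fy * (1 - fx) + d2 * fy * fx
    out[, , ch] <- matrix(v, h, w)
  }
  if (was_matrix) out <- out[, , 1L]
  out
}

# 8-connected component labelling of a binary matrix (TRUE/nonzero = fg).
# Small masks only; iterative BFS with an explicit queue.
label_components <- function(mask) {
  fg <- mask != 0
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(fg)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% h + 1L
      cl <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        q <- (cc - 1L) * h + rr
        if (fg[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  attr(lab, "n") <- cur
  lab
}

#' Write a frame to a PNG file
#' @param frame an `endo_frame`.
#' @param path output file path.
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(is_frame(frame))
  png::writePNG(frame$pixels / 255, target = path)
  invisible(path)
}

#' Read a PNG file into a frame
#' @param path PNG file path.
#' @param id,label metadata attached to the frame.
#' @export
read_frame_png <- function(path, id = basename(path), label = NA_character_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  new_frame(clamp8(px * 255), id = id, label = label)
}
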