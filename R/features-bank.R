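# The descriptor bank: a fixed registry of named descriptors, a
# concatenating extractor that records per-descriptor spans, and the
# train-time min-max scaler that maps every dimension to [0, 1].

#' Available descriptor names
#'
#' The full bank, alphabetical (the concatenation order used by
#' [extract_bank()]). `acc` is the auto color correlogram;
#' `glcm_haralick` is the 7 direction-averaged Haralick statistics;
#' `color_hist_rgb`/`color_hist_hsv`, `ltp` and `glcm_haralick` belong to
#' the misleading list and are excluded from [selected_descriptors()].
#'
#' @return character vector.
#' @export
bank_descriptors <- function() {
  c("acc", "cedd", "color_hist_hsv", "color_hist_rgb", "color_layout",
    "edge_histogram", "fcth", "gabor", "glcm_haralick", "jcd", "lbp",
    "ltp", "phog", "tamura")
}

#' The published selected descriptor set
#'
#' The handcrafted half of the feature set that screening retained:
#' auto color correlogram, color layout, edge histogram, Gabor, JCD,
#' PHOG, Tamura and LBP (radii 1-5). Deep features are fused separately
#' by the pipeline. The screened-out (misleading) descriptors are the
#' color histograms, LTP and GLCM/Haralick.
#'
#' @return character vector.
#' @export
selected_descriptors <- function() {
  c("acc", "color_layout", "edge_histogram", "gabor", "jcd", "lbp",
    "phog", "tamura")
}

#' Misleading descriptors (implemented but excluded by default)
#' @return character vector.
#' @export
misleading_descriptors <- function() {
  c("color_hist_hsv", "color_hist_rgb", "glcm_haralick", "ltp")
}

# Lazy per-frame cache of intermediates shared by several descriptors
# (grayscale, 24-color map, MPEG-7 block edge types, wavelet types).
frame_context <- function(frame) {
  ctx <- new.env(parent = emptyenv())
  ctx$frame <- frame
  ctx$get <- function(key, fn) {
    if (is.null(ctx[[key]])) assign(key, fn(), envir = ctx)
    ctx[[key]]
  }
  ctx
}

ctx_gray <- function(ctx) ctx$get("gray", function() to_grayscale(ctx$frame))
ctx_c24 <- function(ctx) ctx$get("c24", function() block_color24(color24(ctx$frame)))
ctx_edges <- function(ctx) ctx$get("edges", function() block_edge_types(ctx_gray(ctx) * 1.0))
ctx_wavelet <- function(ctx) ctx$get("wavelet", function() fcth_texture_types(ctx_gray(ctx) * 1.0))

descriptor_fun <- function(name) {
  switch(name,
    acc = function(f, ctx) auto_color_correlogram(f),
    cedd = function(f, ctx) cedd_from_parts(ctx_edges(ctx)$type, ctx_c24(ctx)),
    color_hist_hsv = function(f, ctx) color_histogram(f, "HSV"),
    color_hist_rgb = function(f, ctx) color_histogram(f, "RGB"),
    color_layout = function(f, ctx) lire_descriptor(f, "color_layout"),
    edge_histogram = function(f, ctx) ehd_from_types(ctx_edges(ctx)$type),
    fcth = function(f, ctx) fcth_from_parts(ctx_wavelet(ctx), ctx_c24(ctx)),
    gabor = function(f, ctx) lire_descriptor(f, "gabor"),
    glcm_haralick = function(f, ctx) haralick_bank(ctx_gray(ctx)),
    jcd = function(f, ctx) jcd_from_parts(ctx_edges(ctx)$type, ctx_wavelet(ctx), ctx_c24(ctx)),
    lbp = function(f, ctx) lbp_histogram(ctx_gray(ctx), radii = 1:5),
    ltp = function(f, ctx) ltp_histogram(ctx_gray(ctx), radii = 1L),
    phog = function(f, ctx) lire_descriptor(f, "phog"),
    tamura = function(f, ctx) lire_descriptor(f, "tamura"),
    stop("unknown descriptor: ", name, call. = FALSE))
}

#' Extract a concatenated descriptor vector from one frame
#'
#' Descriptors are computed and concatenated in alphabetical order of
#' their names (reproducible spans); the `spans` attribute maps each
#' descriptor name to its index range so selection can slice by name.
#'
#' @param frame an `endo_frame`.
#' @param config character vector of descriptor names (subset of
#'   [bank_descriptors()]); defaults to the published selected set.
#' @return numeric vector with attribute `spans` (named list of integer
#'   ranges).
#' @export
extract_bank <- function(frame, config = selected_descriptors()) {
  if (!length(config)) stop("empty descriptor config", call. = FALSE)
  bad <- setdiff(config, bank_descriptors())
  if (length(bad))
    stop("unknown descriptor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  config <- sort(unique(config))
  ctx <- frame_context(frame)
  pieces <- lapply(config, function(nm) unname(descriptor_fun(nm)(frame, ctx)))
  lens <- vapply(pieces, length, integer(1))
  ends <- cumsum(lens)
  spans <- Map(function(e, l) (e - l + 1L):e, ends, lens)
  names(spans) <- config
  structure(unlist(pieces), spans = spans)
}

#' Extract the descriptor bank for a whole dataset
#'
#' @param data an `endo_dataset` (or list of frames).
#' @param config descriptor names.
#' @return numeric matrix, one row per frame, with attribute `spans`.
#' @export
extract_bank_matrix <- function(data, config = selected_descriptors()) {
  frames <- if (inherits(data, "endo_dataset")) data$frames else data
  rows <- lapply(frames, extract_bank, config = config)
  m <- do.call(rbind, rows)
  attr(m, "spans") <- attr(rows[[1]], "spans")
  m
}

#' Fit a per-dimension min-max scaler on training vectors
#'
#' @param x numeric matrix (rows = training samples) or list of vectors.
#' @return an `endo_scaler` holding per-dimension min and range.
#' @export
fit_scaler <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  structure(list(min = lo, range = hi - lo), class = "endo_scaler")
}

#' Scale feature vectors to \[0, 1\]
#'
#' Training minimum maps to 0 and maximum to 1; out-of-range values at
#' inference clamp into \[0, 1\]; dimensions constant at training time
#' map to 0.
#'
#' @param scaler an `endo_scaler` from [fit_scaler()].
#' @param x numeric vector or matrix.
#' @export
scale_features <- function(scaler, x) {
  if (!inherits(scaler, "endo_scaler"))
    stop("scale_features called before fit_scaler", call. = FALSE)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(scaler$min))
    stop("dimension mismatch with fitted scaler", call. = FALSE)
  rng <- scaler$range
  out <- sweep(x, 2, scaler$min)
  const <- rng == 0
  out[, !const] <- sweep(out[, !const, drop = FALSE], 2, rng[!const], "/")
  out[, const] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (vec) out[1, ] else out
}
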