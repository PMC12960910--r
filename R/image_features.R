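#' Patch extraction settings
#'
#' @param size square patch side in pixels (default 250, sized to cover a
#'   cell and its immediate neighbours at typical imaging resolution).
#' @param pad_mode how to fill patch regions outside the image: `"zero"`
#'   (default, unambiguous) or `"reflect"` (mirror the border).
#' @return an object of class `"patch_spec"`.
#' @export
patch_spec <- function(size = 250, pad_mode = c("zero", "reflect")) {
  pad_mode <- match.arg(pad_mode)
  size <- as.integer(size)
  if (size < 1L) stopf("patch size must be >= 1")
  structure(list(size = size, pad_mode = pad_mode), class = "patch_spec")
}

## Reflect indices into 1..n (mirror boundary without repeating the edge
## pixel when possible).
reflect_index <- function(ix, n) {
  if (n == 1L) return(rep(1L, length(ix)))
  period <- 2L * (n - 1L)
  r <- (ix - 1L) %% period
  r <- ifelse(r < 0L, r + period, r)
  ifelse(r >= n, period - r, r) + 1L
}

#' Crop a square patch centred on a unit
#'
#' The patch covers raster rows `floor(y) - size %/% 2` through
#' `floor(y) - size %/% 2 + size - 1` (0-based; same rule for columns with
#' `floor(x)`), matching the floor convention used for coordinate-to-pixel
#' conversion. Regions outside the image are filled per `spec$pad_mode`.
#' Single-channel images are broadcast to three identical channels so any
#' extractor can assume RGB input.
#'
#' @param image raster (`H x W` or `H x W x C` numeric) or a
#'   [spatial_dataset()] image handle resolved via [get_image()].
#' @param center numeric `(x, y)` in continuous pixel coordinates; must lie
#'   inside the image (out-of-image units are removed by [align_to_image()]).
#' @param spec a [patch_spec()].
#' @return numeric array `size x size x 3`.
#' @export
crop_patch <- function(image, center, spec = patch_spec()) {
  img <- as_image_array(image)
  H <- dim(img)[1L]; W <- dim(img)[2L]; C <- dim(img)[3L]
  x <- center[[1L]]; y <- center[[2L]]
  r0 <- floor(y); c0 <- floor(x)
  if (r0 < 0 || r0 >= H || c0 < 0 || c0 >= W)
    stopf("patch center (%g, %g) outside image %d x %d", x, y, H, W)
  half <- spec$size %/% 2L
  rows <- (r0 - half):(r0 - half + spec$size - 1L) + 1L   # 1-based
  cols <- (c0 - half):(c0 - half + spec$size - 1L) + 1L
  if (spec$pad_mode == "reflect") {
    patch <- img[reflect_index(rows, H), reflect_index(cols, W), ,
                 drop = FALSE]
  } else {
    patch <- array(0, dim = c(spec$size, spec$size, C))
    rin <- which(rows >= 1L & rows <= H)
    cin <- which(cols >= 1L & cols <= W)
    if (length(rin) && length(cin))
      patch[rin, cin, ] <- img[rows[rin], cols[cin], , drop = FALSE]
  }
  if (C == 1L) patch <- array(rep(patch, 3L), dim = c(spec$size, spec$size, 3L))
  patch
}

## ---- pluggable feature extractors ------------------------------------------

.extractor_registry <- new.env(parent = emptyenv())

#' Register a patch feature extractor
#'
#' An extractor is a deterministic function mapping a `size x size x 3` patch
#' to a fixed-length numeric vector. The built-in `"histogram"` extractor
#' needs no external weights; a pretrained-CNN extractor (e.g. a ResNet18
#' backbone with its classification layer removed, d = 512) can be plugged in
#' here when a deep-learning runtime and checkpoint are available.
#'
#' @param name extractor identifier.
#' @param fn function(patch) -> numeric vector, constant output length.
#' @export
register_feature_extractor <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .extractor_registry)
  invisible(name)
}

#' Look up a registered feature extractor
#' @param name extractor identifier (e.g. `"histogram"`).
#' @return the extractor function, with attribute `extractor_id`.
#' @export
feature_extractor <- function(name) {
  if (is.function(name)) return(name)
  if (!exists(name, envir = .extractor_registry))
    stopf("unknown feature extractor '%s'; registered: %s", name,
          paste(ls(.extractor_registry), collapse = ", "))
  fn <- get(name, envir = .extractor_registry)
  attr(fn, "extractor_id") <- name
  fn
}

#' Histogram patch embedding (deterministic, weight-free)
#'
#' Concatenates per-channel intensity histograms (`bins` equal-width bins on
#' `[0, 1]`, clamped, normalised to sum 1 per channel) with a
#' gradient-orientation histogram (8 bins over `(-pi, pi]` of
#' `atan2(dy, dx)` on the channel-mean image, weighted by gradient magnitude,
#' normalised to sum 1; all-zero when the patch is flat). Output length
#' `3 * bins + 8`.
#'
#' @param patch numeric array `s x s x 3`.
#' @param bins intensity bins per channel (default 16).
#' @return numeric vector of length `3 * bins + 8`.
#' @export
histogram_embed <- function(patch, bins = 16L) {
  if (length(dim(patch)) != 3L || dim(patch)[3L] != 3L)
    stopf("extractor expects an s x s x 3 patch")
  breaks <- seq(0, 1, length.out = bins + 1L)
  hs <- lapply(1:3, function(ch) {
    v <- pmin(pmax(as.vector(patch[, , ch]), 0), 1)
    h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                            1L), bins), nbins = bins)
    h / length(v)
  })
  g <- (patch[, , 1L] + patch[, , 2L] + patch[, , 3L]) / 3
  s <- nrow(g)
  if (s >= 2L) {
    dx <- g[, c(2:s, s)] - g[, c(1L, 1:(s - 1L))]
    dy <- g[c(2:s, s), ] - g[c(1L, 1:(s - 1L)), ]
  } else dx <- dy <- matrix(0, 1L, 1L)
  mag <- sqrt(dx^2 + dy^2)
  ori <- atan2(dy, dx)
  ob <- pmin(pmax(ceiling((ori + pi) / (2 * pi / 8)), 1L), 8L)
  oh <- vapply(1:8, function(b) sum(mag[ob == b]), numeric(1L))
  tot <- sum(oh)
  if (tot > 0) oh <- oh / tot else oh <- rep(0, 8L)
  c(unlist(hs, use.names = FALSE), oh)
}

#' Embed a sequence of patches
#'
#' @param patches list of `s x s x 3` arrays.
#' @param extractor extractor name (see [feature_extractor()]) or function.
#' @return an `"image_embedding_table"`: `E` (`n x d` matrix), `d`,
#'   `extractor_id`.
#' @export
embed_patches <- function(patches, extractor = "histogram") {
  fn <- feature_extractor(extractor)
  id <- attr(fn, "extractor_id") %||%
    (if (is.character(extractor)) extractor else "custom")
  rows <- lapply(patches, fn)
  d <- unique(lengths(rows))
  if (length(d) != 1L) stopf("extractor returned varying lengths")
  E <- do.call(rbind, rows)
  if (anyNA(E) && any(apply(is.na(E), 1L, all)))
    stopf("extractor produced an all-NaN embedding row")
  structure(list(E = E, d = as.integer(d), extractor_id = id),
            class = "image_embedding_table")
}

#' Crop and embed one patch per unit
#'
#' Patches are cropped at each unit's (pixel-space) coordinate and embedded
#' once, before training; the cached table is reused across epochs.
#'
#' @param ds a [spatial_dataset()] with pixel-space coordinates and an image.
#' @param spec a [patch_spec()].
#' @param extractor see [embed_patches()].
#' @return an `"image_embedding_table"` with one row per unit.
#' @export
embed_units <- function(ds, spec = patch_spec(), extractor = "histogram") {
  img <- get_image(ds)
  if (is.null(img)) stopf("dataset has no image")
  fn <- feature_extractor(extractor)
  id <- attr(fn, "extractor_id") %||%
    (if (is.character(extractor)) extractor else "custom")
  n <- nrow(ds$coords)
  first <- fn(crop_patch(img, ds$coords[1L, ], spec))
  E <- matrix(0, n, length(first))
  E[1L, ] <- first
  if (n > 1L) for (i in 2:n)
    E[i, ] <- fn(crop_patch(img, ds$coords[i, ], spec))
  structure(list(E = E, d = ncol(E), extractor_id = id),
            class = "image_embedding_table")
}

#' In-batch cosine image neighbours
#'
#' For each embedding row, the indices of the `k` rows with smallest cosine
#' distance (1 - cosine similarity), self excluded. Zero-norm rows are at
#' distance 1 from everything (similarity 0 by convention). Ties break by
#' lower index. Cosine distance is invariant to positive rescaling of rows.
#'
#' @param E `b x d` numeric matrix of embeddings (or an
#'   `"image_embedding_table"`).
#' @param k neighbours per row, `k < b`.
#' @return `b x k` integer matrix of neighbour indices.
#' @export
image_neighbors <- function(E, k = 8) {
  if (inherits(E, "image_embedding_table")) E <- E$E
  E <- as.matrix(E)
  b <- nrow(E)
  if (b <= k) stopf("batch size (%d) must exceed k (%d)", b, k)
  nrm <- sqrt(rowSums(E^2))
  En <- E / ifelse(nrm > 0, nrm, 1)
  S <- En %*% t(En)
  S[nrm == 0, ] <- 0
  S[, nrm == 0] <- 0
  D <- 1 - S
  diag(D) <- Inf
  out <- matrix(0L, b, k)
  for (i in seq_len(b)) {
    o <- order(D[i, ], seq_len(b))
    out[i, ] <- o[seq_len(k)]
  }
  out
}

register_feature_extractor("histogram", histogram_embed)
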