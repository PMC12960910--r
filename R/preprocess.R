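#' Filter empty units and features
#'
#' Removes units whose total raw count is below `min_counts`, then features
#' whose total count (over the surviving units) is below `min_counts`, in that
#' order. Coordinates, labels and identifiers are subset consistently;
#' retained units keep their relative order.
#'
#' @param ds a [spatial_dataset()] holding raw non-negative values.
#' @param min_counts minimum total count for a unit / feature to survive.
#' @return the filtered dataset.
#' @export
filter_units_and_features <- function(ds, min_counts = 1) {
  stopifnot(inherits(ds, "spatial_dataset"))
  keep_units <- rowSums(ds$X) >= min_counts
  if (!any(keep_units)) stopf("no units survive filtering")
  ds <- subset_units(ds, which(keep_units))
  keep_feat <- colSums(ds$X) >= min_counts
  if (!any(keep_feat)) stopf("no features survive filtering")
  subset_features(ds, which(keep_feat))
}

#' Drop features whose names start with given prefixes
#'
#' Some platforms include negative-control probes (e.g. names starting with
#' `"NegPrb"`) that should not enter clustering; this removes any feature
#' whose name matches one of the prefixes. The default empty list is a no-op.
#'
#' @param ds a [spatial_dataset()].
#' @param prefixes character vector of literal name prefixes to exclude.
#' @return the dataset without the matching features.
#' @export
drop_feature_prefixes <- function(ds, prefixes = character()) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (length(prefixes) == 0L) return(ds)
  pat <- paste0("^(", paste(vapply(prefixes, function(p)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p), character(1L)),
    collapse = "|"), ")")
  keep <- !grepl(pat, ds$feature_names)
  if (!any(keep)) stopf("no features survive prefix exclusion")
  subset_features(ds, which(keep))
}

## Dispersion statistics on log-normalised counts: per-feature mean and
## normalized dispersion (within-mean-bin z-score of var/mean), the ranking
## quantity for highly variable feature selection.
hvg_dispersion <- function(X_raw, n_bins = 20L) {
  totals <- rowSums(X_raw)
  target <- stats::median(totals)
  scale_f <- ifelse(totals > 0, target / totals, 0)
  L <- log1p(X_raw * scale_f)
  mu <- colMeans(L)
  v <- apply(L, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency mean bins; z-score dispersion within each bin
  bins <- if (length(mu) <= n_bins) rep(1L, length(mu)) else
    as.integer(cut(rank(mu, ties.method = "first"), breaks = n_bins,
                   labels = FALSE, include.lowest = TRUE))
  norm_disp <- disp
  for (b in unique(bins)) {
    ix <- bins == b
    s <- stats::sd(disp[ix])
    m <- mean(disp[ix])
    norm_disp[ix] <- if (is.na(s) || s == 0) 0 else (disp[ix] - m) / s
  }
  list(mean = mu, dispersion = disp, norm_dispersion = norm_disp)
}

#' Select highly variable features
#'
#' Keeps the `n_top` features with the highest normalized dispersion, computed
#' Seurat-style on log-normalised counts: library sizes are scaled to the
#' median total, values log1p-transformed, per-feature dispersion taken as
#' variance/mean and z-scored within 20 equal-frequency mean bins. Ties rank
#' by lower feature index. When `m <= n_top` the dataset is returned
#' unchanged (e.g. small protein panels). Feature order among the kept set is
#' preserved.
#'
#' @param ds a [spatial_dataset()] holding raw counts.
#' @param n_top number of features to keep (default 3000).
#' @return the dataset restricted to the selected features.
#' @export
select_hvg <- function(ds, n_top = 3000) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (n_top < 1) stopf("n_top must be >= 1")
  m <- ncol(ds$X)
  if (m <= n_top) return(ds)
  st <- hvg_dispersion(ds$X)
  ord <- order(-st$norm_dispersion, seq_len(m))
  keep <- sort(ord[seq_len(n_top)])
  subset_features(ds, keep)
}

#' Normalise, log-transform and z-score the matrix
#'
#' Three steps: (1) library-size normalisation — each unit's counts are scaled
#' so its total equals the median pre-normalisation total; (2) `log(1 + x)`;
#' (3) per-feature z-scoring across units (mean 0, sd 1). Features constant
#' after the log step get z-score 0 by convention rather than NaN.
#'
#' @param ds a [spatial_dataset()] holding raw counts.
#' @return the dataset with real-valued `X` and `normalized = TRUE`.
#' @export
normalize_log_scale <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  totals <- rowSums(ds$X)
  target <- stats::median(totals)
  scale_f <- ifelse(totals > 0, target / totals, 0)
  L <- log1p(ds$X * scale_f)
  mu <- colMeans(L)
  s <- apply(L, 2L, stats::sd)
  s[is.na(s) | s == 0] <- Inf           # constant feature -> z-score 0
  ds$X <- sweep(sweep(L, 2L, mu, "-"), 2L, s, "/")
  ds$normalized <- TRUE
  ds
}

#' Affine transform in homogeneous 2-D coordinates
#'
#' @param matrix a 3 x 3 real matrix; bottom row must be `(0, 0, 1)` and the
#'   matrix invertible.
#' @return an object of class `"affine_transform"`.
#' @export
affine_transform <- function(matrix) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (!all(dim(m) == c(3L, 3L))) stopf("affine matrix must be 3 x 3")
  if (max(abs(m[3L, ] - c(0, 0, 1))) > 1e-9)
    stopf("affine bottom row must be (0, 0, 1)")
  d <- det(m)
  if (!is.finite(d) || abs(d) < 1e-12) stopf("affine matrix is singular")
  structure(list(matrix = m), class = "affine_transform")
}

#' Invert an affine transform
#' @param T an [affine_transform()].
#' @return the inverse transform.
#' @export
affine_inverse <- function(T) affine_transform(solve(T$matrix))

#' Apply an affine transform to coordinates
#'
#' Maps each `(x, y)` row homogeneously: `(x', y', 1)^T = M (x, y, 1)^T`.
#' Used to carry assay coordinates into image pixel space (translation,
#' rotation, scaling).
#'
#' @param coords `n x 2` numeric matrix.
#' @param T an [affine_transform()].
#' @return `n x 2` matrix of transformed coordinates.
#' @export
apply_affine <- function(coords, T) {
  stopifnot(inherits(T, "affine_transform"))
  coords <- as.matrix(coords)
  h <- cbind(coords, 1) %*% t(T$matrix)
  out <- h[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Align dataset coordinates to image pixel space
#'
#' Applies the affine transform (identity when `T` is `NULL`, i.e. the
#' coordinates already live in pixel space) and removes units whose
#' transformed coordinates fall outside the image raster. Pixel convention:
#' coordinates are continuous 0-based `(x, y)`; a unit is inside the image
#' when `0 <= floor(y) < H` and `0 <= floor(x) < W`.
#'
#' @param ds a [spatial_dataset()] with an image.
#' @param T optional [affine_transform()].
#' @return the dataset with pixel-space coordinates, out-of-image units
#'   removed.
#' @export
align_to_image <- function(ds, T = NULL) {
  stopifnot(inherits(ds, "spatial_dataset"))
  img <- get_image(ds)
  if (is.null(img)) stopf("dataset has no image to align to")
  if (!is.null(T)) ds$coords <- apply_affine(ds$coords, T)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  r <- floor(ds$coords[, 2L]); cc <- floor(ds$coords[, 1L])
  inside <- r >= 0 & r < H & cc >= 0 & cc < W
  if (!any(inside)) stopf("no units fall inside the image")
  subset_units(ds, which(inside))
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying, in order: feature-prefix exclusion, unit and
#' feature count filtering, highly-variable-feature selection, and
#' normalisation (library size to the median total, log1p, per-feature
#' z-score).
#'
#' @param ds a [spatial_dataset()] with raw counts.
#' @param min_counts see [filter_units_and_features()].
#' @param n_top see [select_hvg()].
#' @param exclude_prefixes see [drop_feature_prefixes()].
#' @return the preprocessed dataset (real-valued, z-scored `X`).
#' @export
preprocess_dataset <- function(ds, min_counts = 1, n_top = 3000,
                               exclude_prefixes = character()) {
  ds <- drop_feature_prefixes(ds, exclude_prefixes)
  ds <- filter_units_and_features(ds, min_counts = min_counts)
  ds <- select_hvg(ds, n_top = n_top)
  normalize_log_scale(ds)
}
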