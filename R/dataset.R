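#' Spatial omics dataset container
#'
#' Bundles a units-by-features matrix (spots or cells in rows, genes or
#' proteins in columns) with per-unit 2-D spatial coordinates, an optional
#' whole-tissue morphology image and optional ground-truth labels.
#'
#' @param X numeric matrix (or `Matrix` sparse matrix, densified on
#'   construction) of `n` units by `m` features. Raw non-negative counts or
#'   abundances before preprocessing; real-valued after.
#' @param coords numeric `n x 2` matrix of spatial positions, columns `(x, y)`.
#'   Interpreted as continuous 0-based pixel coordinates once aligned to an
#'   image (`x` runs along image columns, `y` along rows).
#' @param image optional image: either a numeric array (`H x W` or
#'   `H x W x C`, `C` 1 or 3, intensities in `[0, 1]`) or a file path to a
#'   TIFF/PNG, loaded lazily by [get_image()].
#' @param labels optional length-`n` vector of ground-truth labels.
#' @param unit_ids,feature_names optional identifier vectors; defaults are
#'   `unit_1..n` / `feature_1..m` or existing dimnames.
#' @return an object of class `"spatial_dataset"` with elements `X`, `coords`,
#'   `image`, `labels`, `unit_ids`, `feature_names`.
#' @export
spatial_dataset <- function(X, coords, image = NULL, labels = NULL,
                            unit_ids = NULL, feature_names = NULL) {
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); m <- ncol(X)
  if (n < 1L || m < 1L) stopf("X must have at least one unit and one feature")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stopf("coords must have exactly 2 columns")
  if (nrow(coords) != n)
    stopf("coordinate rows (%d) != units (%d)", nrow(coords), n)
  if (!is.null(labels) && length(labels) != n)
    stopf("labels length (%d) != units (%d)", length(labels), n)
  unit_ids <- unit_ids %||% rownames(X) %||% paste0("unit_", seq_len(n))
  feature_names <- feature_names %||% colnames(X) %||%
    paste0("feature_", seq_len(m))
  if (length(unit_ids) != n) stopf("unit_ids length != units")
  if (length(feature_names) != m) stopf("feature_names length != features")
  dimnames(X) <- NULL
  colnames(coords) <- c("x", "y")
  structure(
    list(X = X, coords = coords, image = image, labels = labels,
         unit_ids = as.character(unit_ids),
         feature_names = as.character(feature_names),
         normalized = FALSE),
    class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d units x %d features\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  values: %s\n",
              if (isTRUE(x$normalized)) "normalized (z-scored)" else "raw"))
  cat(sprintf("  image: %s\n",
              if (is.null(x$image)) "none"
              else if (is.character(x$image)) x$image else "in-memory raster"))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d classes\n", length(unique(x$labels))))
  invisible(x)
}

#' Resolve the image of a dataset to an in-memory raster
#'
#' Images referenced by path are loaded on first use (lazy loading); in-memory
#' arrays are returned as is, always as `H x W x C` with `C` 1 or 3.
#'
#' @param ds a [spatial_dataset()].
#' @return numeric array `H x W x C`, or `NULL` when the dataset has no image.
#' @export
get_image <- function(ds) {
  img <- ds$image
  if (is.null(img)) return(NULL)
  if (is.character(img)) img <- read_image(img)
  as_image_array(img)
}

## Coerce H x W or H x W x C numeric data to an H x W x C array.
as_image_array <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  if (length(dim(img)) != 3L || !(dim(img)[3L] %in% c(1L, 3L, 4L)))
    stopf("image must be H x W or H x W x C with C in {1, 3}")
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

## Row subset of a dataset, keeping coords/labels/ids aligned.
subset_units <- function(ds, idx) {
  ds$X <- ds$X[idx, , drop = FALSE]
  ds$coords <- ds$coords[idx, , drop = FALSE]
  if (!is.null(ds$labels)) ds$labels <- ds$labels[idx]
  ds$unit_ids <- ds$unit_ids[idx]
  ds
}

## Column subset of a dataset.
subset_features <- function(ds, idx) {
  ds$X <- ds$X[, idx, drop = FALSE]
  ds$feature_names <- ds$feature_names[idx]
  ds
}
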