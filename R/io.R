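#' Read a spatial omics dataset from files
#'
#' Supported matrix containers: MatrixMarket triplet files (`.mtx`, with
#' side-car index files `<path>.rows` and `<path>.cols` holding one unit /
#' feature identifier per line) and delimited text (`.tsv`/`.csv`/`.txt`,
#' header row of feature names, first column of unit identifiers). Units are
#' rows. The coordinate file is delimited text with one row per unit and two
#' numeric columns `(x, y)` (an optional leading identifier column is
#' detected). Labels are one per line, or two tab-separated columns
#' `(unit_id, label)`. The image is loaded lazily; only its path is recorded.
#'
#' @param matrix_path path to the expression/abundance matrix.
#' @param coords_path path to the coordinates file.
#' @param image_path optional path to a TIFF or PNG morphology image.
#' @param labels_path optional path to a labels file.
#' @return a [spatial_dataset()].
#' @export
read_spatial_dataset <- function(matrix_path, coords_path,
                                 image_path = NULL, labels_path = NULL) {
  if (!file.exists(matrix_path)) stopf("matrix file not found: %s", matrix_path)
  if (!file.exists(coords_path)) stopf("coords file not found: %s", coords_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    X <- as.matrix(Matrix::readMM(matrix_path))
    unit_ids <- feature_names <- NULL
    rows_file <- paste0(matrix_path, ".rows")
    cols_file <- paste0(matrix_path, ".cols")
    if (file.exists(rows_file)) unit_ids <- readLines(rows_file)
    if (file.exists(cols_file)) feature_names <- readLines(cols_file)
  } else {
    sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                             row.names = 1L, check.names = FALSE)
    X <- as.matrix(tab)
    unit_ids <- rownames(tab)
    feature_names <- colnames(tab)
  }

  sep <- if (grepl("\\.csv$", coords_path, ignore.case = TRUE)) "," else "\t"
  ctab <- utils::read.table(coords_path, header = TRUE, sep = sep,
                            check.names = FALSE)
  num <- vapply(ctab, is.numeric, logical(1L))
  if (sum(num) < 2L) stopf("coordinate file needs two numeric columns")
  coords <- as.matrix(ctab[, which(num)[1:2], drop = FALSE])
  if (nrow(coords) != nrow(X))
    stopf("coordinate rows (%d) != units (%d)", nrow(coords), nrow(X))

  labels <- NULL
  if (!is.null(labels_path)) {
    ltab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (nrow(ltab) == nrow(X) + 1L)    # header row present
      ltab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    labels <- ltab[[ncol(ltab)]]
    if (length(labels) != nrow(X))
      stopf("label rows (%d) != units (%d)", length(labels), nrow(X))
  }

  if (!is.null(image_path) && !file.exists(image_path))
    stopf("image file not readable: %s", image_path)
  spatial_dataset(X, coords, image = image_path, labels = labels,
                  unit_ids = unit_ids, feature_names = feature_names)
}

#' Read a raster image from TIFF or PNG
#'
#' @param path image file path.
#' @return numeric array `H x W x C` with intensities in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not readable: %s", path)
  img <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path)
  else stopf("unsupported image format: %s", path)
  as_image_array(img)
}

#' Write a raster image to TIFF
#'
#' @param img numeric array `H x W` or `H x W x C`, values in `[0, 1]`.
#' @param path output path ending in `.tif`/`.tiff`.
#' @export
write_image <- function(img, path) {
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a 3 x 3 affine transform from a delimited text file
#'
#' @param path file with three rows of three whitespace/tab-separated numbers.
#' @return an [affine_transform()].
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  affine_transform(m)
}

#' Write a fitted model's outputs as plain-text side-car files
#'
#' Writes, under `dir`: `labels.tsv` (unit_id, cluster), `soft_assignments.tsv`
#' (row-stochastic soft labels), `embeddings.tsv` (latent embeddings) and
#' `loss_history.tsv` (per-epoch loss breakdown).
#'
#' @param fit a fitted [stamix()] model.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cluster_result <- function(fit, dir) {
  stopifnot(inherits(fit, "stamix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(unit_id = fit$unit_ids, cluster = fit$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  soft <- as.data.frame(fit$soft)
  names(soft) <- paste0("cluster_", seq_len(ncol(soft)))
  utils::write.table(cbind(unit_id = fit$unit_ids, soft),
                     file.path(dir, "soft_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emb <- as.data.frame(fit$embeddings)
  names(emb) <- paste0("z_", seq_len(ncol(emb)))
  utils::write.table(cbind(unit_id = fit$unit_ids, emb),
                     file.path(dir, "embeddings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$loss_history, file.path(dir, "loss_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
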