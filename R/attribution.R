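## Integrated-gradients attribution of cluster probabilities to input
## features, and the per-cluster spatially-variable-gene ranking built on it.

#' Integrated gradients of a scalar function
#'
#' Attribution of `f(x) - f(baseline)` to the coordinates of `x` along the
#' straight-line path from `baseline` to `x`:
#' `IG_d = (x_d - baseline_d) * mean_s df/dx_d(baseline + t_s (x - baseline))`
#' with `t_s` the midpoint grid `(s - 1/2)/steps`. For linear `f` this is
#' exact for any number of steps; for smooth `f` the attributions sum to
#' `f(x) - f(baseline)` as `steps` grows (completeness).
#'
#' @param f function of a length-`m` numeric vector returning a scalar.
#' @param x input point.
#' @param baseline reference point (same length).
#' @param steps number of path points (midpoint rule; >= 2).
#' @param grad optional gradient function of `f` (same signature, returns a
#'   length-`m` vector); when `NULL`, central finite differences are used.
#' @return length-`m` vector of attributions.
#' @export
integrated_gradients <- function(f, x, baseline, steps = 50L, grad = NULL) {
  if (steps < 2L) stopf("steps must be >= 2")
  m <- length(x)
  if (length(baseline) != m) stopf("baseline length != x length")
  diff_ <- x - baseline
  if (is.null(grad))
    grad <- function(p) {
      h <- 1e-5 * (1 + abs(p))
      vapply(seq_len(m), function(d) {
        pp <- p; pm <- p
        pp[d] <- p[d] + h[d]; pm[d] <- p[d] - h[d]
        (f(pp) - f(pm)) / (2 * h[d])
      }, numeric(1L))
    }
  ts <- (seq_len(steps) - 0.5) / steps
  G <- rowMeans(vapply(ts, function(t) grad(baseline + t * diff_),
                       numeric(m)))
  diff_ * G
}

## Forward + gradient of the soft label of ONE unit along an IG path, with
## the unit's neighbourhood features held fixed. `Xpath` stacks the path
## points (steps x m); `Xnb` (K x m) are the fixed neighbour profiles.
## Returns soft labels at each path point and d y[, comp] / d x_self
## (steps x m). Gradients flow only through the unit's own features.
unit_soft_path <- function(params, cfg, Xpath, Xnb, comp) {
  S <- nrow(Xpath); K <- nrow(Xnb)
  U_nb <- Xnb %*% params$W                    # K x h
  U_self <- Xpath %*% params$W                # S x h
  sl_self <- drop(U_self %*% params$al)
  sr_nb <- drop(U_nb %*% params$ar)
  sr_self <- drop(U_self %*% params$ar)
  scores <- cbind(outer(sl_self, sr_nb, "+"), sl_self + sr_self)
  gsc <- leaky_relu(scores, cfg$leaky_slope)
  alpha <- row_softmax(gsc)
  A <- alpha[, seq_len(K), drop = FALSE] %*% U_nb +
    alpha[, K + 1L] * U_self
  Hpre <- sweep(A, 2L, params$b, "+")
  H <- elu(Hpre)
  logits <- sweep(H %*% params$Wy, 2L, params$by, "+")
  Y <- row_softmax(logits)

  dlogits <- -Y * Y[, comp]
  dlogits[, comp] <- dlogits[, comp] + Y[, comp]
  dH <- dlogits %*% t(params$Wy)
  dHpre <- dH * elu_grad(Hpre)
  dA <- dHpre
  dalpha <- cbind(dA %*% t(U_nb), rowSums(dA * U_self))
  dg <- alpha * (dalpha - rowSums(alpha * dalpha))
  dsc <- dg * leaky_relu_grad(scores, cfg$leaky_slope)
  dU_self <- tcrossprod(rowSums(dsc), params$al) +
    tcrossprod(dsc[, K + 1L], params$ar) +
    alpha[, K + 1L] * dA
  list(Y = Y, grad = dU_self %*% t(params$W))
}

#' Rank spatially variable features per cluster by integrated gradients
#'
#' For each cluster `c`, the attributed function is the model's soft
#' probability for `c` at a unit, with the unit's spatial neighbourhood held
#' fixed at its observed profiles (attribution is unit-local). Integrated
#' gradients run from the all-unit feature-mean baseline (approximately zero
#' on z-scored data) to each unit assigned to `c` (a seeded subsample when
#' the cluster is large), are averaged over those units, and features are
#' ranked by descending mean attribution.
#'
#' @param fit a fitted `"stamix"` model.
#' @param ds the (preprocessed) [spatial_dataset()] the model was fitted on.
#' @param top_n ranked features kept per cluster (default 50, truncated at
#'   `m`).
#' @param steps IG path points (midpoint rule, default 50).
#' @param units_per_cluster cap on units averaged per cluster (default 100;
#'   larger clusters are subsampled with `seed`).
#' @param seed seed for the subsample.
#' @return an object of class `"svg_ranking"`: `ig_matrix` (`k x m` mean
#'   attributions), `top_features` (per-cluster character vectors, ordered),
#'   `top_index` (the same as column indices), `feature_names`.
#' @export
rank_svgs <- function(fit, ds, top_n = 50L, steps = 50L,
                      units_per_cluster = 100L, seed = 0L) {
  stopifnot(inherits(fit, "stamix"), inherits(ds, "spatial_dataset"))
  cfg <- fit$config$cfg
  if (ncol(ds$X) != cfg$m)
    stopf("model features (%d) != data features (%d)", cfg$m, ncol(ds$X))
  m <- cfg$m; k <- cfg$k
  baseline <- colMeans(ds$X)
  ig_matrix <- matrix(0, k, m)
  ts <- (seq_len(steps) - 0.5) / steps
  for (cl in seq_len(k)) {
    units <- which(fit$labels == cl)
    if (length(units) == 0L) {
      warning(sprintf("cluster %d is empty; no features ranked", cl))
      next
    }
    if (length(units) > units_per_cluster)
      units <- with_seed(seed + cl,
                         sort(sample(units, units_per_cluster)))
    acc <- numeric(m)
    for (u in units) {
      x <- ds$X[u, ]
      d <- x - baseline
      Xpath <- matrix(baseline, steps, m, byrow = TRUE) + outer(ts, d)
      Xnb <- ds$X[fit$graph$neighbor_index[u, ], , drop = FALSE]
      res <- unit_soft_path(fit$params, cfg, Xpath, Xnb, cl)
      acc <- acc + d * colMeans(res$grad)
    }
    ig_matrix[cl, ] <- acc / length(units)
  }
  n_keep <- min(top_n, m)
  top_index <- lapply(seq_len(k), function(cl) {
    if (all(ig_matrix[cl, ] == 0) && !any(fit$labels == cl))
      return(integer(0L))
    order(-ig_matrix[cl, ], seq_len(m))[seq_len(n_keep)]
  })
  structure(list(ig_matrix = ig_matrix,
                 top_index = top_index,
                 top_features = lapply(top_index, function(ix)
                   fit$feature_names[ix]),
                 feature_names = fit$feature_names),
            class = "svg_ranking")
}

#' @export
print.svg_ranking <- function(x, ...) {
  cat(sprintf("svg_ranking: %d clusters x %d features\n",
              nrow(x$ig_matrix), ncol(x$ig_matrix)))
  for (cl in seq_along(x$top_features)) {
    tf <- x$top_features[[cl]]
    cat(sprintf("  cluster %d: %s%s\n", cl,
                paste(utils::head(tf, 5L), collapse = ", "),
                if (length(tf) > 5L) ", ..." else ""))
  }
  invisible(x)
}

#' Export a feature ranking as TSV
#'
#' Columns: cluster, rank, feature, ig_value.
#'
#' @param ranking an `"svg_ranking"`.
#' @param path output file.
#' @export
export_svg_tsv <- function(ranking, path) {
  rows <- do.call(rbind, lapply(seq_along(ranking$top_index), function(cl) {
    ix <- ranking$top_index[[cl]]
    if (length(ix) == 0L) return(NULL)
    data.frame(cluster = cl, rank = seq_along(ix),
               feature = ranking$feature_names[ix],
               ig_value = ranking$ig_matrix[cl, ix])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
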