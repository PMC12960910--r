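## External and internal clustering quality metrics.

choose2 <- function(x) x * (x - 1) / 2

## Contingency table between two labelings plus its margins.
contingency <- function(truth, pred) {
  if (length(truth) != length(pred))
    stopf("label length mismatch: %d vs %d", length(truth), length(pred))
  tab <- table(truth, pred)
  list(counts = tab, a = rowSums(tab), b = colSums(tab), n = length(truth))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance;
#' ranges from -1 to 1 with 1 for identical partitions (up to relabelling)
#' and approximately 0 for independent ones. Computed from the contingency
#' table `c_ij = |a_i intersect b_j|`:
#' `ARI = (S_c - S_a S_b / C) / ((S_a + S_b)/2 - S_a S_b / C)` with
#' `S_c = sum_ij C(c_ij, 2)`, `S_a = sum_i C(a_i, 2)`,
#' `S_b = sum_j C(b_j, 2)`, `C = C(n, 2)`. When both partitions are trivial
#' in the same way (all singletons, or one single cluster) the denominator
#' vanishes and 1.0 is returned by convention.
#'
#' @param truth,pred equal-length label vectors (any types coercible to
#'   factors).
#' @return scalar index.
#' @export
adjusted_rand_index <- function(truth, pred) {
  ct <- contingency(truth, pred)
  if (ct$n < 2L) stopf("need at least 2 units")
  sc <- sum(choose2(as.numeric(ct$counts)))
  sa <- sum(choose2(as.numeric(ct$a)))
  sb <- sum(choose2(as.numeric(ct$b)))
  cn <- choose2(ct$n)
  expected <- sa * sb / cn
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1.0)
  (sc - expected) / denom
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall:
#' `FMI = S_c / sqrt(S_a * S_b)` on the contingency-table pair counts; 0 by
#' convention when either factor is 0.
#'
#' @inheritParams adjusted_rand_index
#' @return scalar in `[0, 1]`.
#' @export
fowlkes_mallows <- function(truth, pred) {
  ct <- contingency(truth, pred)
  sc <- sum(choose2(as.numeric(ct$counts)))
  sa <- sum(choose2(as.numeric(ct$a)))
  sb <- sum(choose2(as.numeric(ct$b)))
  if (sa == 0 || sb == 0) return(0)
  sc / sqrt(sa * sb)
}

#' Mean silhouette score
#'
#' For each unit, `a` is its mean Euclidean distance to the other members of
#' its own cluster and `b` the smallest mean distance to any other cluster;
#' its silhouette is `(b - a)/max(a, b)`. Units in singleton clusters
#' contribute 0. The score is the mean over units; requires at least two
#' non-empty clusters.
#'
#' @param X `n x d` numeric matrix: the space the score is taken in
#'   (preprocessed expression or latent embeddings).
#' @param labels length-`n` cluster labels.
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(labels) != n)
    stopf("label length mismatch: %d vs %d", length(labels), n)
  labs <- as.integer(factor(labels))
  k <- max(labs)
  if (k < 2L) stopf("silhouette undefined for a single cluster")
  sizes <- tabulate(labs, k)
  D <- as.matrix(stats::dist(X))
  sums <- rowsum(D, labs)                     # k x n: col i = sums to cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labs[i]
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sums[own, i] / (sizes[own] - 1L)
    b <- min(sums[-own, i] / sizes[-own])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Evaluate a clustering against ground truth
#'
#' @param truth,pred label vectors.
#' @param X optional matrix for the silhouette (computed on `pred` labels);
#'   skipped when `NULL`.
#' @return named numeric vector with `ari`, `fmi` and (when `X` given) `si`.
#' @export
evaluate_clustering <- function(truth, pred, X = NULL) {
  out <- c(ari = adjusted_rand_index(truth, pred),
           fmi = fowlkes_mallows(truth, pred))
  if (!is.null(X)) out <- c(out, si = silhouette_score(X, pred))
  out
}
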