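## Composite training objective: image-similarity loss on soft labels,
## the GMVAE evidence lower bound standing in for the marginal
## log-likelihood, and a Jensen-Shannon spatial-neighbour consistency term.
## The minimised total is  w_img * image_loss - ELBO + w_js * js_term.

#' Image-similarity loss on soft cluster labels
#'
#' For each unit `i` and each of its in-batch image neighbours `j`,
#' `-log(max(Y_i . Y_j, eps))` is accumulated: the dot product of two
#' row-stochastic soft labels is their probability of agreeing on a cluster,
#' so the loss is zero when a unit and its image neighbours are one-hot on
#' the same cluster, and each term is non-negative. The `eps` clamp removes
#' the singularity when two soft labels are one-hot on different clusters.
#'
#' @param Y `b x k` row-stochastic soft assignment matrix.
#' @param neighbor_idx `b x k_img` integer matrix from [image_neighbors()].
#' @param eps clamp inside the log (default 1e-8).
#' @return length-`b` vector of per-unit losses.
#' @export
image_loss <- function(Y, neighbor_idx, eps = 1e-8) {
  Y <- as.matrix(Y)
  b <- nrow(Y)
  neighbor_idx <- as.matrix(neighbor_idx)
  ii <- rep(seq_len(b), times = ncol(neighbor_idx))
  jj <- as.integer(neighbor_idx)
  dots <- rowSums(Y[ii, , drop = FALSE] * Y[jj, , drop = FALSE])
  terms <- -log(pmax(dots, eps))
  rowsum_vec(terms, ii, b)
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Base-2 entropy form `JS = H(m) - (H(p) + H(q))/2` with `m = (p + q)/2`,
#' bounded in `[0, 1]`.
#'
#' @param p,q non-negative vectors summing to 1.
#' @return scalar divergence.
#' @export
js_divergence <- function(p, q) {
  h2 <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  m <- (p + q) / 2
  h2(m) - (h2(p) + h2(q)) / 2
}

#' Spatial-neighbour label-consistency term
#'
#' For each unit, the mean base-2 Jensen-Shannon divergence between its soft
#' label and those of its spatial graph neighbours. Identical labels give 0;
#' disjoint one-hot labels give the base-2 maximum of 1.
#'
#' @param Y `n x k` soft assignment matrix (rows for every unit referenced).
#' @param neighbor_list either an `n x k_sp` integer matrix of neighbour
#'   indices (e.g. `g$neighbor_index`) or a list of integer vectors.
#' @return per-unit vector of mean divergences.
#' @export
js_neighbor_term <- function(Y, neighbor_list) {
  Y <- as.matrix(Y)
  if (is.matrix(neighbor_list))
    neighbor_list <- split(as.integer(t(neighbor_list)),
                           rep(seq_len(nrow(neighbor_list)),
                               each = ncol(neighbor_list)))
  tiny <- 1e-12
  h2row <- function(P) -rowSums(P * log2(pmax(P, tiny)))
  vapply(seq_along(neighbor_list), function(i) {
    u <- neighbor_list[[i]]
    if (length(u) == 0L) return(0)
    P <- Y[rep(i, length(u)), , drop = FALSE]
    Q <- Y[u, , drop = FALSE]
    mean(h2row((P + Q) / 2) - (h2row(P) + h2row(Q)) / 2)
  }, numeric(1L))
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' `KL(N(mu0, sd0^2) || N(mu1, sd1^2))`, elementwise over conforming arrays,
#' summed over no axis (callers sum as needed):
#' `log(sd1/sd0) + (sd0^2 + (mu0 - mu1)^2) / (2 sd1^2) - 1/2`.
#'
#' @param mu0,sd0 parameters of the first (posterior) Gaussian.
#' @param mu1,sd1 parameters of the second (prior) Gaussian.
#' @return array of elementwise divergences.
#' @export
kl_gaussian <- function(mu0, sd0, mu1, sd1) {
  log(sd1 / sd0) + (sd0^2 + (mu0 - mu1)^2) / (2 * sd1^2) - 0.5
}

#' Evidence-lower-bound terms for a batch
#'
#' The responsibility-weighted GMVAE decomposition:
#' `reconstruction = sum_i sum_j Y_ij log N(x_i; mu_x_ij, sigma_x_ij^2)`,
#' `kl_z = sum_i sum_j Y_ij KL(q(z|x, y=j) || p(z|y=j))` (closed form),
#' `kl_y = sum_i KL(Y_i || uniform)`, and `elbo = reconstruction - kl_z -
#' kl_y`, the surrogate for the marginal log-likelihood `sum_i log p(x_i)`.
#'
#' @param x `n x m` observed matrix.
#' @param Y `n x k` soft assignments.
#' @param mu_post,sigma_post `n x k x d_z` posterior parameter arrays.
#' @param mu_x,sigma_x `n x k x m` output-distribution arrays (component-wise
#'   decodings).
#' @param params,cfg model parameters (for the prior) and configuration.
#' @return list with `reconstruction`, `kl_z`, `kl_y`, `elbo` (scalars).
#' @export
elbo_terms <- function(x, Y, mu_post, sigma_post, mu_x, sigma_x,
                       params, cfg) {
  x <- as.matrix(x); Y <- as.matrix(Y)
  n <- nrow(x); k <- cfg$k
  if (!all(dim(mu_x)[1:2] == c(n, k)))
    stopf("shape mismatch: mu_x is %s, expected %d x %d x m",
          paste(dim(mu_x), collapse = "x"), n, k)
  sp <- prior_sd(params, cfg)
  recon <- matrix(0, n, k); klz <- matrix(0, n, k)
  for (j in seq_len(k)) {
    recon[, j] <- rowSums(stats::dnorm(x, mu_x[, j, ], sigma_x[, j, ],
                                       log = TRUE))
    mp <- matrix(params$mu_prior[j, ], n, cfg$d_z, byrow = TRUE)
    spj <- matrix(sp[j, ], n, cfg$d_z, byrow = TRUE)
    klz[, j] <- rowSums(kl_gaussian(mu_post[, j, ], sigma_post[, j, ],
                                    mp, spj))
  }
  tiny <- 1e-12
  reconstruction <- sum(Y * recon)
  kl_z <- sum(Y * klz)
  kl_y <- sum(Y * log(pmax(Y, tiny) * k))
  list(reconstruction = reconstruction, kl_z = kl_z, kl_y = kl_y,
       elbo = reconstruction - kl_z - kl_y)
}

#' Loss breakdown container
#'
#' @param image_loss total image-similarity loss (>= 0).
#' @param marginal_ll the ELBO surrogate for the summed marginal
#'   log-likelihood.
#' @param js_term total Jensen-Shannon neighbour-consistency term (>= 0).
#' @return a `"loss_breakdown"` list; `total` is filled by [total_loss()].
#' @export
loss_breakdown <- function(image_loss, marginal_ll, js_term) {
  structure(list(image_loss = image_loss, marginal_ll = marginal_ll,
                 js_term = js_term, total = NA_real_),
            class = "loss_breakdown")
}

#' Combine loss parts into the minimised objective
#'
#' `total = w_image * image_loss - marginal_ll + w_js * js_term` (the
#' minimisation form of the training objective; maximising the objective is
#' minimising this total). With `w_image = 0` this reduces exactly to the
#' image-free objective (the expression-only ablation mode).
#'
#' @param parts a [loss_breakdown()].
#' @param weights named numeric vector with entries `image` and `js`
#'   (defaults 1).
#' @return the scalar total.
#' @export
total_loss <- function(parts, weights = c(image = 1, js = 1)) {
  w_img <- if ("image" %in% names(weights)) weights[["image"]] else 1
  w_js <- if ("js" %in% names(weights)) weights[["js"]] else 1
  for (nm in c("image_loss", "marginal_ll", "js_term"))
    if (!is.finite(parts[[nm]]))
      stopf("non-finite loss component: %s", nm)
  w_img * parts$image_loss - parts$marginal_ll + w_js * parts$js_term
}
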