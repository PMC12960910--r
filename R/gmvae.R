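## Gaussian mixture variational autoencoder with a single-hop graph attention
## encoder. The generative side draws a cluster label y ~ Uniform(k), a latent
## z | y = j ~ N(mu_prior_j, diag(sigma_prior_j^2)), and reconstructs the
## (normalised, real-valued) profile x | z ~ N(mu_x, diag(sigma_x^2)) with a
## unit-wise Gaussian output distribution. The inference side encodes a unit
## together with its graph neighbours through one graph-attention hop, then
## reads off a k-way softmax head (the soft cluster label Y-hat) and
## per-component posterior heads (mu_post, sigma_post). Forward and backward
## passes are written explicitly in vectorised base R; the backward pass
## returns exact gradients (verified against finite differences in the test
## suite).

#' Model configuration
#'
#' @param k_cluster number of mixture components (>= 2); taken as the number
#'   of annotated classes when evaluating against a ground truth.
#' @param m number of input features.
#' @param d_z latent dimension (default 16).
#' @param hidden graph-attention encoder width (default 64).
#' @param hidden_dec decoder hidden width (default 64).
#' @param sigma_floor lower bound added to every softplus-activated standard
#'   deviation, preventing posterior/output variance collapse (default 1e-4).
#' @param leaky_slope negative slope of the attention leaky-ReLU (default 0.2).
#' @return a list of class `"gmvae_config"`.
#' @export
gmvae_config <- function(k_cluster, m, d_z = 16L, hidden = 64L,
                         hidden_dec = 64L, sigma_floor = 1e-4,
                         leaky_slope = 0.2) {
  if (k_cluster < 2L) stopf("k_cluster must be >= 2")
  structure(list(k = as.integer(k_cluster), m = as.integer(m),
                 d_z = as.integer(d_z), hidden = as.integer(hidden),
                 hidden_dec = as.integer(hidden_dec),
                 sigma_floor = sigma_floor, leaky_slope = leaky_slope),
            class = "gmvae_config")
}

## Parameter initialisation. Draws from the current RNG stream (callers seed).
## The k per-component posterior-mean heads start as one shared block plus a
## small jitter, so before training every component's posterior mean is
## essentially the same encoder projection; the k-means warm start of the
## prior means then immediately separates components (see the methods
## vignette).
init_gmvae_params <- function(cfg) {
  h <- cfg$hidden; m <- cfg$m; k <- cfg$k; dz <- cfg$d_z; hd <- cfg$hidden_dec
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  shared_mu <- rn(h, dz, 1 / sqrt(h))
  Wm <- do.call(cbind, replicate(k, shared_mu, simplify = FALSE)) +
    rn(h, k * dz, 1e-3)
  list(
    W  = rn(m, h, 1 / sqrt(m)),
    al = stats::rnorm(h, sd = 0.1 / sqrt(h)),
    ar = stats::rnorm(h, sd = 0.1 / sqrt(h)),
    b  = numeric(h),
    Wy = rn(h, k, 1 / sqrt(h)),
    by = numeric(k),
    Wm = Wm,
    bm = numeric(k * dz),
    Ws = rn(h, k * dz, 0.1 / sqrt(h)),
    bs = rep(softplus_inv(0.5), k * dz),
    mu_prior = matrix(0, k, dz),
    rho_prior = matrix(softplus_inv(1), k, dz),
    Wd1 = rn(dz, hd, 1 / sqrt(dz)),
    bd1 = numeric(hd),
    Wd2m = rn(hd, m, 1 / sqrt(hd)),
    bd2m = numeric(m),
    Wd2s = rn(hd, m, 0.1 / sqrt(hd)),
    bd2s = rep(softplus_inv(1), m))
}

## Group-sum of a vector by integer groups 1..n.
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs
  out
}

## Encoder forward over one batch.
##   Xb: members x m, edges: member-local (src, dst) WITHOUT self loops
## Self loops are appended internally so every node attends to itself.
encoder_forward <- function(params, cfg, Xb, edges) {
  nm <- nrow(Xb)
  E <- rbind(edges, cbind(src = seq_len(nm), dst = seq_len(nm)))
  src <- E[, 1L]; dst <- E[, 2L]
  U <- Xb %*% params$W
  sl <- drop(U %*% params$al)
  sr <- drop(U %*% params$ar)
  sc <- sl[dst] + sr[src]
  g <- leaky_relu(sc, cfg$leaky_slope)
  gmax <- group_max_expand(g, dst, nm)
  eg <- exp(g - gmax)
  den <- rowsum_vec(eg, dst, nm)
  alpha <- eg / den[dst]
  A <- rowsum(alpha * U[src, , drop = FALSE], dst)   # rows 1..nm (self loops)
  dimnames(A) <- NULL
  Hpre <- sweep(A, 2L, params$b, "+")
  H <- elu(Hpre)
  logits <- sweep(H %*% params$Wy, 2L, params$by, "+")
  Y <- row_softmax(logits)
  M <- sweep(H %*% params$Wm, 2L, params$bm, "+")
  Spre <- sweep(H %*% params$Ws, 2L, params$bs, "+")
  sigq <- softplus(Spre) + cfg$sigma_floor
  list(nm = nm, src = src, dst = dst, U = U, sc = sc, alpha = alpha,
       Hpre = Hpre, H = H, logits = logits, Y = Y, M = M, Spre = Spre,
       sigq = sigq)
}

## Decoder forward for one component's latent sample.
decoder_forward <- function(params, cfg, z) {
  D1pre <- sweep(z %*% params$Wd1, 2L, params$bd1, "+")
  D1 <- tanh(D1pre)
  mux <- sweep(D1 %*% params$Wd2m, 2L, params$bd2m, "+")
  sxpre <- sweep(D1 %*% params$Wd2s, 2L, params$bd2s, "+")
  sigx <- softplus(sxpre) + cfg$sigma_floor
  list(z = z, D1pre = D1pre, D1 = D1, mux = mux, sxpre = sxpre, sigx = sigx)
}

## Prior standard deviations from their unconstrained parameters.
prior_sd <- function(params, cfg) softplus(params$rho_prior) + cfg$sigma_floor

## Full model forward on a batch: encoder over members, reparameterised
## latents and decoder per component over targets, Gaussian log-likelihoods
## and closed-form KLs. `eps`: nt x d_z standard-normal draws (reparameter-
## isation noise), shared across components.
## `Y_clamp` (optional nt x k) replaces the encoder's soft labels in every
## responsibility-weighted term; used for supervised warm-up where the
## assignment is held at pseudo-label one-hots while decoder, posterior
## heads and priors train.
gmvae_forward <- function(params, cfg, Xb, edges, tpos, eps,
                          Y_clamp = NULL) {
  enc <- encoder_forward(params, cfg, Xb, edges)
  k <- cfg$k; dz <- cfg$d_z
  nt <- length(tpos)
  Xt <- Xb[tpos, , drop = FALSE]
  Yt <- Y_clamp %||% enc$Y[tpos, , drop = FALSE]
  sp <- prior_sd(params, cfg)
  recon <- matrix(0, nt, k); KL <- matrix(0, nt, k)
  dec <- vector("list", k)
  mu_q <- vector("list", k); sd_q <- vector("list", k)
  for (j in seq_len(k)) {
    idx <- ((j - 1L) * dz + 1L):(j * dz)
    mu_q[[j]] <- enc$M[tpos, idx, drop = FALSE]
    sd_q[[j]] <- enc$sigq[tpos, idx, drop = FALSE]
    z <- mu_q[[j]] + sd_q[[j]] * eps
    dec[[j]] <- decoder_forward(params, cfg, z)
    d <- dec[[j]]
    recon[, j] <- -0.5 * (cfg$m * log(2 * pi) +
                            rowSums(2 * log(d$sigx)) +
                            rowSums(((Xt - d$mux) / d$sigx)^2))
    mp <- matrix(params$mu_prior[j, ], nt, dz, byrow = TRUE)
    spj <- matrix(sp[j, ], nt, dz, byrow = TRUE)
    KL[, j] <- rowSums(log(spj) - log(sd_q[[j]]) +
                         (sd_q[[j]]^2 + (mu_q[[j]] - mp)^2) / (2 * spj^2) -
                         0.5)
  }
  tiny <- 1e-12
  recon_term <- sum(Yt * recon)
  kl_z <- sum(Yt * KL)
  kl_y <- sum(Yt * log(pmax(Yt, tiny) * k))
  list(enc = enc, dec = dec, mu_q = mu_q, sd_q = sd_q, eps = eps,
       recon = recon, KL = KL, Xb = Xb, Xt = Xt, Yt = Yt, tpos = tpos,
       Y_clamped = !is.null(Y_clamp),
       reconstruction = recon_term, kl_z = kl_z, kl_y = kl_y,
       elbo = recon_term - kl_z - kl_y)
}

## Exact backward pass for the composite objective on one batch.
##   fw:        output of gmvae_forward
##   img_pairs: list(ii, jj, coef) image-loss pair gradients d(total)/d(dot),
##              in member-local positions (NULL when images unused)
##   js_pairs:  list(ti (member pos of target), u (member pos of neighbour),
##              w (per-pair weight, already including the JS loss weight))
## Returns gradients of the minimised total loss w.r.t. every parameter.
## `dlogits_extra`: additional gradient at the softmax-head logits (member
## rows), e.g. the cross-entropy term of the supervised warm-up. When the
## forward pass clamped Y, the ELBO contributes no gradient through the
## soft labels (they were not a function of the encoder there).
gmvae_backward <- function(params, cfg, fw, img_pairs = NULL,
                           js_pairs = NULL, dlogits_extra = NULL) {
  enc <- fw$enc; k <- cfg$k; dz <- cfg$d_z
  nm <- enc$nm; tpos <- fw$tpos; nt <- length(tpos)
  tiny <- 1e-12
  sp <- prior_sd(params, cfg)

  ## ---- gradient w.r.t. the soft labels Y (members x k)
  dY <- matrix(0, nm, k)
  # -ELBO part (targets only)
  if (!isTRUE(fw$Y_clamped))
    dY[tpos, ] <- -(fw$recon - fw$KL) + (log(pmax(fw$Yt, tiny) * k) + 1)
  # image loss: d/dY_i [-log(Y_i . Y_j)] = -Y_j / dot (clamped pairs excluded)
  if (!is.null(img_pairs) && length(img_pairs$ii)) {
    gi <- tpos[img_pairs$ii]; gj <- tpos[img_pairs$jj]
    dY <- index_add(dY, gi, img_pairs$coef * enc$Y[gj, , drop = FALSE])
    dY <- index_add(dY, gj, img_pairs$coef * enc$Y[gi, , drop = FALSE])
  }
  # JS term: d JS(p, q)/dp_c = (1/2) log2(p_c / m_c)
  if (!is.null(js_pairs) && length(js_pairs$ti)) {
    P <- enc$Y[js_pairs$ti, , drop = FALSE]
    Q <- enc$Y[js_pairs$u, , drop = FALSE]
    Mm <- (P + Q) / 2
    dP <- js_pairs$w * 0.5 * (log2(pmax(P, tiny)) - log2(pmax(Mm, tiny)))
    dQ <- js_pairs$w * 0.5 * (log2(pmax(Q, tiny)) - log2(pmax(Mm, tiny)))
    dY <- index_add(dY, js_pairs$ti, dP)
    dY <- index_add(dY, js_pairs$u, dQ)
  }

  ## ---- per-component decoder + KL backward (targets)
  dM <- matrix(0, nm, k * dz)
  dSigq <- matrix(0, nm, k * dz)
  g <- list(Wd1 = 0 * params$Wd1, bd1 = 0 * params$bd1,
            Wd2m = 0 * params$Wd2m, bd2m = 0 * params$bd2m,
            Wd2s = 0 * params$Wd2s, bd2s = 0 * params$bd2s,
            mu_prior = 0 * params$mu_prior, rho_prior = 0 * params$rho_prior)
  for (j in seq_len(k)) {
    idx <- ((j - 1L) * dz + 1L):(j * dz)
    d <- fw$dec[[j]]
    cY <- fw$Yt[, j]
    R <- (fw$Xt - d$mux) / d$sigx^2
    dmux <- -cY * R
    dsigx <- -cY * (-1 / d$sigx + (fw$Xt - d$mux)^2 / d$sigx^3)
    dsxpre <- dsigx * sigmoid(d$sxpre)
    g$Wd2m <- g$Wd2m + crossprod(d$D1, dmux)
    g$bd2m <- g$bd2m + colSums(dmux)
    g$Wd2s <- g$Wd2s + crossprod(d$D1, dsxpre)
    g$bd2s <- g$bd2s + colSums(dsxpre)
    dD1 <- dmux %*% t(params$Wd2m) + dsxpre %*% t(params$Wd2s)
    dD1pre <- dD1 * (1 - d$D1^2)
    g$Wd1 <- g$Wd1 + crossprod(d$z, dD1pre)
    g$bd1 <- g$bd1 + colSums(dD1pre)
    dz_ <- dD1pre %*% t(params$Wd1)
    # closed-form Gaussian KL gradients, weighted by responsibilities
    mp <- matrix(params$mu_prior[j, ], nt, dz, byrow = TRUE)
    spj <- matrix(sp[j, ], nt, dz, byrow = TRUE)
    dmu_q <- cY * ((fw$mu_q[[j]] - mp) / spj^2) + dz_
    dsd_q <- cY * (-1 / fw$sd_q[[j]] + fw$sd_q[[j]] / spj^2) + dz_ * fw$eps
    g$mu_prior[j, ] <- colSums(cY * (-(fw$mu_q[[j]] - mp) / spj^2))
    dsp <- colSums(cY * (1 / spj -
                           (fw$sd_q[[j]]^2 + (fw$mu_q[[j]] - mp)^2) / spj^3))
    g$rho_prior[j, ] <- dsp * sigmoid(params$rho_prior[j, ])
    dM[tpos, idx] <- dM[tpos, idx] + dmu_q
    dSigq[tpos, idx] <- dSigq[tpos, idx] + dsd_q
  }

  ## ---- heads + encoder backward
  dlogits <- enc$Y * (dY - rowSums(dY * enc$Y))
  if (!is.null(dlogits_extra)) dlogits <- dlogits + dlogits_extra
  dSpre <- dSigq * sigmoid(enc$Spre)
  c(g, encoder_backward(params, cfg, enc, fw$Xb, dlogits, dM, dSpre))
}

## Backward through the heads and the graph-attention encoder, given the
## gradients at the logits and at the posterior-head pre-activations.
encoder_backward <- function(params, cfg, enc, Xb, dlogits,
                             dM = NULL, dSpre = NULL) {
  nm <- enc$nm
  g <- list()
  g$Wy <- crossprod(enc$H, dlogits); g$by <- colSums(dlogits)
  dH <- dlogits %*% t(params$Wy)
  if (!is.null(dM)) {
    g$Wm <- crossprod(enc$H, dM); g$bm <- colSums(dM)
    dH <- dH + dM %*% t(params$Wm)
  }
  if (!is.null(dSpre)) {
    g$Ws <- crossprod(enc$H, dSpre); g$bs <- colSums(dSpre)
    dH <- dH + dSpre %*% t(params$Ws)
  }

  dHpre <- dH * elu_grad(enc$Hpre)
  g$b <- colSums(dHpre)
  dA <- dHpre
  src <- enc$src; dst <- enc$dst
  dU <- matrix(0, nm, cfg$hidden)
  dU <- index_add(dU, src, enc$alpha * dA[dst, , drop = FALSE])
  dalpha <- rowSums(dA[dst, , drop = FALSE] * enc$U[src, , drop = FALSE])
  Sgrp <- rowsum_vec(enc$alpha * dalpha, dst, nm)
  dg_ <- enc$alpha * (dalpha - Sgrp[dst])
  dsc <- dg_ * leaky_relu_grad(enc$sc, cfg$leaky_slope)
  dU <- index_add(dU, dst, tcrossprod(dsc, params$al))
  dU <- index_add(dU, src, tcrossprod(dsc, params$ar))
  g$al <- drop(crossprod(enc$U[dst, , drop = FALSE], dsc))
  g$ar <- drop(crossprod(enc$U[src, , drop = FALSE], dsc))
  g$W <- crossprod(Xb, dU)
  g
}

## ---- exported operation wrappers -------------------------------------------

#' Single-hop graph attention encoding
#'
#' Per-edge attention scores come from a leaky-ReLU of the transformed
#' endpoint features; scores are softmax-normalised over each target's
#' in-neighbourhood (self-loop included), and the output is the
#' attention-weighted sum of transformed source features, passed through an
#' ELU. A node with only its self-loop therefore outputs exactly its own
#' transformed features.
#'
#' @param X `b x m` feature matrix (batch members).
#' @param edges integer matrix (`src`, `dst`) of directed edges in local
#'   positions; self-loops are added internally.
#' @param params list with `W` (`m x h`), `al`, `ar` (length-`h` attention
#'   vectors), `b` (length-`h` bias).
#' @param cfg a [gmvae_config()] (only `leaky_slope` is used here).
#' @return list with `H` (`b x h` encoded features) and `attention`
#'   (per-edge weights, last `b` entries the self-loops).
#' @export
gat_encode <- function(X, edges, params, cfg) {
  enc <- encoder_forward(params, cfg, as.matrix(X), edges)
  list(H = enc$H, attention = enc$alpha, src = enc$src, dst = enc$dst)
}

#' Variational inference for a batch
#'
#' Runs the encoder and reads the soft cluster labels (k-way softmax head)
#' and the per-component Gaussian posterior parameters (softplus-activated
#' standard deviations, floored at `cfg$sigma_floor`).
#'
#' @param X `members x m` matrix; @param edges local edges (see
#'   [gat_encode()]); @param tpos positions of target units within the batch.
#' @param params model parameters; @param cfg a [gmvae_config()].
#' @return list with `soft` (`nt x k`, rows sum to 1), `mu_post` and
#'   `sigma_post` (`nt x k x d_z` arrays).
#' @export
gmvae_infer <- function(X, edges, tpos, params, cfg) {
  enc <- encoder_forward(params, cfg, as.matrix(X), edges)
  nt <- length(tpos); k <- cfg$k; dz <- cfg$d_z
  mu <- array(0, c(nt, k, dz)); sd_ <- array(0, c(nt, k, dz))
  for (j in seq_len(k)) {
    idx <- ((j - 1L) * dz + 1L):(j * dz)
    mu[, j, ] <- enc$M[tpos, idx]
    sd_[, j, ] <- enc$sigq[tpos, idx]
  }
  list(soft = enc$Y[tpos, , drop = FALSE], mu_post = mu, sigma_post = sd_)
}

#' Reparameterised latent sample
#'
#' Draws `z_i = mu + sigma * eps` from each unit's active component (the
#' argmax of its soft label; ties break to the lower component index), with
#' `eps ~ N(0, I)` under the given seed. Passing `eps` explicitly (e.g. all
#' zeros) overrides the draw, which is useful for deterministic checks.
#'
#' @param post list with `mu_post`, `sigma_post` (`n x k x d_z`).
#' @param Y `n x k` soft assignment matrix.
#' @param seed integer seed.
#' @param eps optional `n x d_z` noise matrix overriding the seeded draw.
#' @return `n x d_z` matrix of latent samples.
#' @export
sample_latent <- function(post, Y, seed = 0L, eps = NULL) {
  n <- dim(post$mu_post)[1L]; dz <- dim(post$mu_post)[3L]
  comp <- max.col(Y, ties.method = "first")
  if (is.null(eps))
    eps <- with_seed(seed, matrix(stats::rnorm(n * dz), n, dz))
  mu <- matrix(0, n, dz); sd_ <- matrix(0, n, dz)
  for (i in seq_len(n)) {
    mu[i, ] <- post$mu_post[i, comp[i], ]
    sd_[i, ] <- post$sigma_post[i, comp[i], ]
  }
  mu + sd_ * eps
}

#' Decode latent embeddings to output-distribution parameters
#'
#' @param z `n x d_z` latent matrix.
#' @param params,cfg model parameters and configuration.
#' @return list with `mu_x` (`n x m`) and `sigma_x` (`n x m`, strictly
#'   positive): the per-unit Gaussian output distribution.
#' @export
gmvae_decode <- function(z, params, cfg) {
  d <- decoder_forward(params, cfg, as.matrix(z))
  list(mu_x = d$mux, sigma_x = d$sigx)
}

#' Component-wise prior log-density of latents
#'
#' Entry `(i, j)` is `log N(z_i; mu_prior_j, diag(sigma_prior_j^2))`. The
#' uniform mixture weight `p(y = j) = 1/k` is a separate constant and is not
#' included.
#'
#' @param z `n x d_z` matrix; @param params,cfg model parameters and config.
#' @return `n x k` matrix of log-densities.
#' @export
prior_log_prob <- function(z, params, cfg) {
  z <- as.matrix(z)
  n <- nrow(z); k <- cfg$k; dz <- cfg$d_z
  sp <- prior_sd(params, cfg)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    mp <- matrix(params$mu_prior[j, ], n, dz, byrow = TRUE)
    spj <- matrix(sp[j, ], n, dz, byrow = TRUE)
    out[, j] <- rowSums(stats::dnorm(z, mp, spj, log = TRUE))
  }
  out
}

#' Gaussian log-density of observations under the output distribution
#'
#' @param x,mu_x,sigma_x conforming `n x m` matrices.
#' @return length-`n` vector of per-unit log-densities.
#' @export
output_log_prob <- function(x, mu_x, sigma_x) {
  rowSums(stats::dnorm(as.matrix(x), mu_x, sigma_x, log = TRUE))
}
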