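# Frozen tiny model used across blocks.
tiny_model <- function(seed = 42, k = 3, m = 5, dz = 4, h = 6, hd = 7) {
  set.seed(seed)
  cfg <- gmvae_config(k, m, d_z = dz, hidden = h, hidden_dec = hd)
  params <- stamix:::init_gmvae_params(cfg)
  params$mu_prior <- matrix(rnorm(k * dz), k, dz)
  list(cfg = cfg, params = params)
}

test_that("graph attention reduces to known closed forms", {
  mod <- tiny_model()
  # one node, self-loop only: output is its own transformed features
  x <- matrix(rnorm(5), 1, 5)
  out <- gat_encode(x, cbind(src = integer(0), dst = integer(0)),
                    mod$params, mod$cfg)
  expected <- stamix:::elu(x %*% mod$params$W + rep(mod$params$b, each = 1))
  expect_equal(out$H, expected, tolerance = 1e-12)
  expect_equal(as.numeric(out$attention), 1)

  # attention weights sum to 1 over each target's neighbourhood
  set.seed(1)
  X <- matrix(rnorm(8 * 5), 8, 5)
  edges <- cbind(src = c(2, 3, 4, 1, 1, 5), dst = c(1, 1, 1, 2, 3, 3))
  out2 <- gat_encode(X, edges, mod$params, mod$cfg)
  sums <- tapply(out2$attention, out2$dst, sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  # identical features everywhere: uniform attention 1/(deg+1), output is
  # the shared transformed vector
  Xc <- matrix(rep(rnorm(5), each = 6), 6, 5)
  edges3 <- cbind(src = c(2, 3, 4, 5), dst = c(1, 1, 1, 1))
  out3 <- gat_encode(Xc, edges3, mod$params, mod$cfg)
  att1 <- out3$attention[out3$dst == 1]
  expect_equal(unname(att1), rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(out3$H[1, ], out3$H[2, ], tolerance = 1e-12)
})

test_that("inference produces row-stochastic soft labels and floored sds", {
  mod <- tiny_model()
  set.seed(2)
  X <- matrix(rnorm(10 * 5), 10, 5)
  edges <- cbind(src = sample(10, 20, TRUE), dst = sample(10, 20, TRUE))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  inf <- gmvae_infer(X, edges, 1:10, mod$params, mod$cfg)
  expect_equal(rowSums(inf$soft), rep(1, 10), tolerance = 1e-6)
  expect_true(all(inf$soft >= 0 & inf$soft <= 1))
  expect_true(all(inf$sigma_post >= mod$cfg$sigma_floor))

  # zeroed encoder weights and biases give exactly uniform soft labels
  p0 <- mod$params
  p0$W[] <- 0; p0$al[] <- 0; p0$ar[] <- 0; p0$b[] <- 0
  p0$Wy[] <- 0; p0$by[] <- 0
  inf0 <- gmvae_infer(X, edges, 1:10, p0, mod$cfg)
  expect_equal(inf0$soft, matrix(1 / 3, 10, 3), tolerance = 1e-12)
})

test_that("latent sampling is seeded and honours the zero-noise hook", {
  mod <- tiny_model()
  set.seed(3)
  X <- matrix(rnorm(6 * 5), 6, 5)
  edges <- cbind(src = c(2, 3, 4, 5, 6, 1), dst = c(1, 2, 3, 4, 5, 6))
  inf <- gmvae_infer(X, edges, 1:6, mod$params, mod$cfg)

  # eps = 0 returns the active component's posterior mean exactly
  z0 <- sample_latent(inf, inf$soft, eps = matrix(0, 6, 4))
  comp <- max.col(inf$soft, ties.method = "first")
  for (i in 1:6) expect_equal(z0[i, ], inf$mu_post[i, comp[i], ])

  # same seed, same draw
  expect_identical(sample_latent(inf, inf$soft, seed = 7),
                   sample_latent(inf, inf$soft, seed = 7))
  expect_false(identical(sample_latent(inf, inf$soft, seed = 7),
                         sample_latent(inf, inf$soft, seed = 8)))

  # CLT: mean of many draws approaches mu_post within 3 sd / sqrt(n)
  ndraw <- 10000
  i <- 1
  draws <- sapply(seq_len(ndraw), function(s)
    sample_latent(inf, inf$soft, seed = s)[i, 1])
  mu <- inf$mu_post[i, comp[i], 1]
  sd_ <- inf$sigma_post[i, comp[i], 1]
  expect_lt(abs(mean(draws) - mu), 3 * sd_ / sqrt(ndraw))
})

test_that("decoder outputs positive sds and matches the normal density", {
  mod <- tiny_model()
  set.seed(4)
  z <- matrix(rnorm(3 * 4), 3, 4)
  z[2, ] <- z[1, ]                      # identical latents
  out <- gmvae_decode(z, mod$params, mod$cfg)
  expect_true(all(out$sigma_x > 0))
  expect_equal(out$mu_x[1, ], out$mu_x[2, ])
  expect_equal(out$sigma_x[1, ], out$sigma_x[2, ])

  # log-density agrees with the independently coded normal log-pdf
  x <- matrix(rnorm(3 * 5), 3, 5)
  lp <- output_log_prob(x, out$mu_x, out$sigma_x)
  oracle <- sapply(1:3, function(i)
    sum(-0.5 * log(2 * pi) - log(out$sigma_x[i, ]) -
          (x[i, ] - out$mu_x[i, ])^2 / (2 * out$sigma_x[i, ]^2)))
  expect_equal(lp, oracle, tolerance = 1e-9)
})

test_that("prior log-probabilities follow the closed-form Gaussian", {
  mod <- tiny_model()
  p <- mod$params
  p$rho_prior[] <- stamix:::softplus_inv(1 - mod$cfg$sigma_floor)
  # z at a component mean with unit prior sd: log prob = -(d_z/2) log(2 pi)
  z <- p$mu_prior[2, , drop = FALSE]
  lp <- prior_log_prob(z, p, mod$cfg)
  expect_equal(lp[1, 2], -(4 / 2) * log(2 * pi), tolerance = 1e-9)

  # moving away from the mean strictly decreases the log-probability
  for (step in c(0.1, 0.5, 2)) {
    z2 <- z + step
    expect_lt(prior_log_prob(z2, p, mod$cfg)[1, 2], lp[1, 2])
  }

  # 5 x 3 x 2 fixture against a direct dnorm oracle
  mod2 <- tiny_model(seed = 9, k = 3, m = 4, dz = 2)
  set.seed(5)
  Z <- matrix(rnorm(10), 5, 2)
  lp2 <- prior_log_prob(Z, mod2$params, mod2$cfg)
  sp <- stamix:::prior_sd(mod2$params, mod2$cfg)
  for (i in 1:5) for (j in 1:3)
    expect_equal(lp2[i, j],
                 sum(dnorm(Z[i, ], mod2$params$mu_prior[j, ], sp[j, ],
                           log = TRUE)),
                 tolerance = 1e-9)
})

test_that("the generative joint factorises into its three terms", {
  mod <- tiny_model()
  set.seed(6)
  z <- matrix(rnorm(4 * 4), 4, 4)
  x <- matrix(rnorm(4 * 5), 4, 5)
  dec <- gmvae_decode(z, mod$params, mod$cfg)
  k <- mod$cfg$k
  lp_z <- prior_log_prob(z, mod$params, mod$cfg)
  lp_x <- output_log_prob(x, dec$mu_x, dec$sigma_x)
  joint_terms <- log(1 / k) + lp_z + lp_x     # n x k matrix

  # directly coded joint density, all Gaussian pieces written out
  sp <- stamix:::prior_sd(mod$params, mod$cfg)
  for (i in 1:4) for (j in 1:k) {
    direct <- log(1 / k) +
      sum(-0.5 * log(2 * pi * sp[j, ]^2) -
            (z[i, ] - mod$params$mu_prior[j, ])^2 / (2 * sp[j, ]^2)) +
      sum(-0.5 * log(2 * pi * dec$sigma_x[i, ]^2) -
            (x[i, ] - dec$mu_x[i, ])^2 / (2 * dec$sigma_x[i, ]^2))
    expect_equal(joint_terms[i, j], direct, tolerance = 1e-6)
  }
})

test_that("permuting mixture components permutes outputs consistently", {
  mod <- tiny_model()
  set.seed(7)
  X <- matrix(rnorm(8 * 5), 8, 5)
  edges <- cbind(src = c(2, 3, 5, 6, 8, 1), dst = c(1, 2, 4, 5, 7, 8))
  perm <- c(3, 1, 2)
  pp <- mod$params
  dz <- mod$cfg$d_z
  blk <- function(j) ((j - 1) * dz + 1):(j * dz)
  pp$Wy <- pp$Wy[, perm]; pp$by <- pp$by[perm]
  pp$mu_prior <- pp$mu_prior[perm, ]; pp$rho_prior <- pp$rho_prior[perm, ]
  reorder <- unlist(lapply(perm, blk))
  pp$Wm <- pp$Wm[, reorder]; pp$bm <- pp$bm[reorder]
  pp$Ws <- pp$Ws[, reorder]; pp$bs <- pp$bs[reorder]

  inf <- gmvae_infer(X, edges, 1:8, mod$params, mod$cfg)
  infp <- gmvae_infer(X, edges, 1:8, pp, mod$cfg)
  expect_equal(infp$soft, inf$soft[, perm], tolerance = 1e-12)
  expect_equal(infp$mu_post, inf$mu_post[, perm, ], tolerance = 1e-12)

  z <- matrix(rnorm(8 * dz), 8, dz)
  expect_equal(prior_log_prob(z, pp, mod$cfg),
               prior_log_prob(z, mod$params, mod$cfg)[, perm],
               tolerance = 1e-12)
})

test_that("all model outputs stay finite on finite inputs", {
  mod <- tiny_model()
  set.seed(8)
  X <- matrix(rnorm(20 * 5, sd = 10), 20, 5)   # deliberately large inputs
  edges <- cbind(src = sample(20, 40, TRUE), dst = sample(20, 40, TRUE))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  eps <- matrix(rnorm(20 * 4), 20, 4)
  fw <- stamix:::gmvae_forward(mod$params, mod$cfg, X, edges, 1:20, eps)
  expect_true(all(is.finite(fw$enc$Y)))
  expect_true(all(is.finite(fw$recon)))
  expect_true(all(is.finite(fw$KL)))
  expect_true(is.finite(fw$elbo))
})
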