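test_that("image loss matches closed-form values", {
  # unit and all 8 neighbours one-hot on the same cluster: loss 0
  Y <- matrix(0, 9, 4); Y[, 2] <- 1
  nb <- t(sapply(1:9, function(i) setdiff(1:9, i)))
  L <- image_loss(Y, nb)
  expect_equal(L, rep(0, 9), tolerance = 1e-12)

  # uniform soft labels over K = 4, k = 8 neighbours: L_i = 8 log 4 exactly
  Yu <- matrix(1 / 4, 9, 4)
  Lu <- image_loss(Yu, nb)
  expect_equal(Lu, rep(8 * log(4), 9), tolerance = 1e-9)

  # disjoint one-hot labels clamp at -log(eps)
  Y2 <- rbind(c(1, 0), c(0, 1))
  L2 <- image_loss(Y2, matrix(c(2L, 1L), 2, 1), eps = 1e-8)
  expect_equal(L2, rep(-log(1e-8), 2))

  # permutation equivariance: permuting rows permutes per-unit losses
  set.seed(41)
  Yr <- t(apply(matrix(rexp(9 * 4), 9, 4), 1, function(r) r / sum(r)))
  Lr <- image_loss(Yr, nb)
  perm <- sample(9)
  inv <- integer(9); inv[perm] <- 1:9
  nbp <- matrix(inv[nb[perm, ]], 9, 8)
  expect_equal(image_loss(Yr[perm, ], nbp), Lr[perm], tolerance = 1e-12)
})

test_that("ELBO terms recover closed-form KL values", {
  k <- 4; dz <- 3; n <- 5; m <- 2
  cfg <- gmvae_config(k, m, d_z = dz, hidden = 4, hidden_dec = 4)
  set.seed(42)
  params <- stamix:::init_gmvae_params(cfg)
  params$mu_prior <- matrix(rnorm(k * dz), k, dz)
  sp <- stamix:::prior_sd(params, cfg)

  # posterior identical to prior and uniform responsibilities: both KLs 0
  mu_post <- array(0, c(n, k, dz)); sd_post <- array(0, c(n, k, dz))
  for (j in 1:k) {
    mu_post[, j, ] <- matrix(params$mu_prior[j, ], n, dz, byrow = TRUE)
    sd_post[, j, ] <- matrix(sp[j, ], n, dz, byrow = TRUE)
  }
  Yu <- matrix(1 / k, n, k)
  mu_x <- array(0, c(n, k, m)); sigma_x <- array(1, c(n, k, m))
  x <- matrix(0, n, m)
  et <- elbo_terms(x, Yu, mu_post, sd_post, mu_x, sigma_x, params, cfg)
  expect_equal(et$kl_z, 0, tolerance = 1e-9)
  expect_equal(et$kl_y, 0, tolerance = 1e-9)
  expect_equal(et$reconstruction, n * m * (-0.5 * log(2 * pi)),
               tolerance = 1e-9)

  # one-hot responsibilities: kl_y = n log 4
  Y1 <- matrix(0, n, k); Y1[, 3] <- 1
  et1 <- elbo_terms(x, Y1, mu_post, sd_post, mu_x, sigma_x, params, cfg)
  expect_equal(et1$kl_y, n * log(4), tolerance = 1e-6)

  # 1-D Gaussian KL fixture: N(0,1) vs N(1,2)
  expect_equal(kl_gaussian(0, 1, 1, 2), log(2) + (1 + 1) / 8 - 0.5,
               tolerance = 1e-12)
  # and KL of identical distributions is 0
  expect_equal(kl_gaussian(0.3, 1.7, 0.3, 1.7), 0, tolerance = 1e-12)

  expect_error(elbo_terms(x, Yu, mu_post, sd_post,
                          array(0, c(2, k, m)), sigma_x, params, cfg),
               "shape mismatch")
})

test_that("Jensen-Shannon term matches entropy-form closed values", {
  expect_equal(js_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0,
               tolerance = 1e-12)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1, tolerance = 1e-12)

  # uniform vs one-hot over K = 2 against the entropy-form oracle
  p <- c(0.5, 0.5); q <- c(1, 0)
  h2 <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  m <- (p + q) / 2
  oracle <- h2(m) - (h2(p) + h2(q)) / 2
  expect_equal(js_divergence(p, q), oracle, tolerance = 1e-12)
  expect_equal(oracle, 2 - 0.75 * log2(3) - 0.5, tolerance = 1e-9)

  # per-unit neighbour means, identical labels give 0
  Y <- rbind(c(1, 0), c(1, 0), c(0, 1))
  js <- js_neighbor_term(Y, list(2L, 1L, c(1L, 2L)))
  expect_equal(js[1:2], c(0, 0), tolerance = 1e-9)
  expect_equal(js[3], 1, tolerance = 1e-9)
  expect_true(all(js >= 0 & js <= 1))
})

test_that("total loss combines parts with weights and guards non-finites", {
  expect_equal(total_loss(loss_breakdown(0, 0, 0)), 0)
  expect_equal(total_loss(loss_breakdown(1.5, 2.0, 0.25)), -0.25)
  # zero image weight reduces to the image-free objective
  expect_equal(total_loss(loss_breakdown(99, 2.0, 0.25),
                          weights = c(image = 0, js = 1)), -1.75)
  expect_error(total_loss(loss_breakdown(NaN, 1, 0)), "image_loss")
  expect_error(total_loss(loss_breakdown(0, Inf, 0)), "marginal_ll")
})

test_that("the ELBO lower-bounds an exact marginal likelihood", {
  # tiny model (1 unit, m = 1, d_z = 1, k = 2): log p(x) by 1-D quadrature
  cfg <- gmvae_config(2, 1, d_z = 1, hidden = 3, hidden_dec = 3)
  set.seed(43)
  params <- stamix:::init_gmvae_params(cfg)
  params$mu_prior <- matrix(c(-1, 1), 2, 1)
  X <- matrix(0.4, 1, 1)
  edges <- cbind(src = integer(0), dst = integer(0))
  eps <- matrix(0.3, 1, 1)
  fw <- stamix:::gmvae_forward(params, cfg, X, edges, 1L, eps)

  sp <- stamix:::prior_sd(params, cfg)
  marg <- 0
  for (j in 1:2) {
    dens <- function(z) {
      sapply(z, function(zi) {
        d <- gmvae_decode(matrix(zi, 1, 1), params, cfg)
        dnorm(zi, params$mu_prior[j, ], sp[j, ]) *
          dnorm(X[1, 1], d$mu_x[1, 1], d$sigma_x[1, 1])
      })
    }
    marg <- marg + 0.5 * integrate(dens, -12, 12, rel.tol = 1e-9)$value
  }

  # exact ELBO: the reconstruction expectation is integrated over the
  # posterior (not single-sample), KL terms are closed form already
  recon_exact <- sapply(1:2, function(j) {
    mu_q <- fw$mu_q[[j]][1, 1]; sd_q <- fw$sd_q[[j]][1, 1]
    integrate(function(z) sapply(z, function(zi) {
      d <- gmvae_decode(matrix(zi, 1, 1), params, cfg)
      dnorm(zi, mu_q, sd_q) *
        dnorm(X[1, 1], d$mu_x[1, 1], d$sigma_x[1, 1], log = TRUE)
    }), mu_q - 10 * sd_q, mu_q + 10 * sd_q, rel.tol = 1e-9)$value
  })
  Yt <- fw$Yt[1, ]
  elbo_exact <- sum(Yt * (recon_exact - fw$KL[1, ])) - fw$kl_y
  # a variational lower bound never exceeds the true marginal log-likelihood
  expect_lt(elbo_exact, log(marg) + 1e-8)
})

test_that("analytic gradients of the composite loss match finite
           differences", {
  set.seed(44)
  n <- 10; m <- 4; k <- 3; dz <- 3
  cfg <- gmvae_config(k, m, d_z = dz, hidden = 5, hidden_dec = 5)
  params <- stamix:::init_gmvae_params(cfg)
  params$mu_prior <- matrix(rnorm(k * dz), k, dz)
  Xb <- matrix(rnorm(n * m), n, m)
  edges <- cbind(src = sample(n, 20, TRUE), dst = sample(n, 20, TRUE))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  tpos <- 1:7
  eps <- matrix(rnorm(7 * dz), 7, dz)
  nbi <- t(sapply(1:7, function(i) sample(setdiff(1:7, i), 2)))
  ii <- rep(1:7, 2); jj <- as.integer(nbi)
  js_ti <- rep(1:7, 2); js_u <- sample(n, 14, TRUE)
  w_img <- 0.8; w_js <- 1.3; eps_img <- 1e-8

  loss_fn <- function(p) {
    fw <- stamix:::gmvae_forward(p, cfg, Xb, edges, tpos, eps)
    Y <- fw$enc$Y
    dots <- rowSums(Y[ii, , drop = FALSE] * Y[jj, , drop = FALSE])
    tiny <- 1e-12
    h2 <- function(Z) -rowSums(Z * log2(pmax(Z, tiny)))
    P <- Y[js_ti, , drop = FALSE]; Q <- Y[js_u, , drop = FALSE]
    js_raw <- sum(h2((P + Q) / 2) - (h2(P) + h2(Q)) / 2)
    w_img * sum(-log(pmax(dots, eps_img))) - fw$elbo + w_js * js_raw
  }
  fw <- stamix:::gmvae_forward(params, cfg, Xb, edges, tpos, eps)
  Y <- fw$enc$Y
  dots <- rowSums(Y[ii, , drop = FALSE] * Y[jj, , drop = FALSE])
  ip <- list(ii = ii, jj = jj,
             coef = ifelse(dots > eps_img, -w_img / dots, 0))
  jp <- list(ti = js_ti, u = js_u, w = w_js)
  grads <- stamix:::gmvae_backward(params, cfg, fw, img_pairs = ip,
                                   js_pairs = jp)
  h <- 1e-6
  set.seed(45)
  for (nm in names(params)) {
    for (ix in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      pp <- params; pp[[nm]][ix] <- pp[[nm]][ix] + h
      pm <- params; pm[[nm]][ix] <- pm[[nm]][ix] - h
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      an <- grads[[nm]][ix]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-4)
    }
  }
})
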