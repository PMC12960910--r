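## Seeded mini-batch training of the graph-attention GMVAE, and the
## user-facing fitting function.

## One Adam step over the named parameter list.
adam_update <- function(params, grads, state, lr, t,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Mean profile over each unit's closed neighbourhood (self + graph
## neighbours): the deterministic, structure-preserving statistic the
## warm start clusters.
neighbor_mean <- function(X, g) {
  S <- X
  for (r in seq_len(g$k)) S <- S + X[g$neighbor_index[, r], , drop = FALSE]
  S / (g$k + 1)
}

## Deterministic full-data encoder pass with complete neighbourhoods,
## chunked so memory stays bounded. Returns soft labels and the
## responsibility-weighted posterior-mean embeddings for every unit.
full_encoder_pass <- function(params, cfg, X, g, chunk = 4096L) {
  n <- nrow(X); k <- cfg$k; dz <- cfg$d_z
  Y <- matrix(0, n, k); Z <- matrix(0, n, dz)
  pos <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    targets <- s:min(s + chunk - 1L, n)
    nbrs <- unique(as.integer(g$neighbor_index[targets, , drop = FALSE]))
    members <- c(targets, setdiff(nbrs, targets))
    pos[members] <- seq_along(members)
    dst_all <- rep(members, times = g$k)
    src_all <- as.integer(g$neighbor_index[members, , drop = FALSE])
    keep <- pos[src_all] > 0L
    edges <- cbind(src = pos[src_all[keep]], dst = pos[dst_all[keep]])
    enc <- encoder_forward(params, cfg, X[members, , drop = FALSE], edges)
    tp <- seq_along(targets)
    Y[targets, ] <- enc$Y[tp, , drop = FALSE]
    zbar <- matrix(0, length(targets), dz)
    for (j in seq_len(k)) {
      idx <- ((j - 1L) * dz + 1L):(j * dz)
      zbar <- zbar + enc$Y[tp, j] * enc$M[tp, idx, drop = FALSE]
    }
    Z[targets, ] <- zbar
    pos[members] <- 0L
  }
  list(Y = Y, Z = Z)
}

#' Fit the spatial-omics mixture clustering model
#'
#' Trains a Gaussian mixture variational autoencoder whose encoder is a
#' single-hop graph attention network over the units' spatial (or feature)
#' KNN graph. The minimised objective couples (i) an image-similarity loss
#' pushing units with similar morphology-patch embeddings toward shared soft
#' cluster labels, (ii) the negative evidence lower bound standing in for the
#' marginal log-likelihood of the profiles, and (iii) a Jensen-Shannon term
#' encouraging spatial neighbours to agree. Optimisation is Adam over seeded
#' mini-batches (each batch carries its targets' complete neighbourhoods);
#' the prior component means are warm-started from k-means centroids of a
#' first-pass encoder embedding. Identical data, settings and seed reproduce
#' the result exactly.
#'
#' @param ds a preprocessed [spatial_dataset()] (real-valued, z-scored `X`;
#'   coordinates in image pixel space when `use_image`).
#' @param k_cluster number of clusters (the number of annotated classes when
#'   benchmarking against a ground truth).
#' @param epochs training epochs (default 150).
#' @param batch_size targets per mini-batch (default 1024).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed governing initialisation, batching and
#'   reparameterisation noise.
#' @param k_spatial neighbours in the unit KNN graph (default 8, covering the
#'   8-connected neighbourhood of a grid layout).
#' @param k_image in-batch image neighbours per unit (default 8).
#' @param graph_mode `"spatial"` (coordinates; spatial domains) or
#'   `"feature"` (expression space; cell types).
#' @param use_image couple the morphology image through the image loss;
#'   defaults to `TRUE` when the dataset has an image. `FALSE` is the
#'   expression-only ablation (image loss weight effectively 0).
#' @param weights named loss weights `c(image =, js =)`, default 1 each (the
#'   unweighted sum).
#' @param d_z,hidden,hidden_dec network sizes, see [gmvae_config()].
#' @param patch a [patch_spec()] for image patches.
#' @param extractor image feature extractor, see [feature_extractor()].
#' @param image_embeddings optional precomputed [embed_units()] table
#'   (avoids re-cropping when refitting).
#' @param warm_epochs warm-start epochs: the encoder and assignment head are
#'   pretrained by cross-entropy against seeded k-means pseudo-labels of the
#'   neighbourhood-averaged input, and the prior component means are
#'   initialised at the per-cluster means of the first-pass embeddings
#'   (default 15; 0 disables, leaving a cold random start).
#' @param loss_log optional path; per-epoch loss breakdown appended as TSV.
#' @param verbose print per-epoch losses.
#' @return an object of class `"stamix"` with elements `labels` (hard
#'   assignments, argmax of the soft labels, ties to the lower index),
#'   `soft` (`n x k` row-stochastic), `embeddings` (`n x d_z`
#'   responsibility-weighted posterior means), `loss_history` (per-epoch
#'   data frame), `params`, `config`, `graph`, plus identifiers.
#' @seealso [predict.stamix()], [rank_svgs()], [adjusted_rand_index()]
#' @export
stamix <- function(ds, k_cluster,
                   epochs = 150, batch_size = 1024, learning_rate = 1e-3,
                   seed = 0L, k_spatial = 8L, k_image = 8L,
                   graph_mode = c("spatial", "feature"),
                   use_image = NULL, weights = c(image = 1, js = 1),
                   d_z = 16L, hidden = 64L, hidden_dec = 64L,
                   patch = patch_spec(), extractor = "histogram",
                   image_embeddings = NULL, warm_epochs = 15L,
                   loss_log = NULL, verbose = FALSE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  graph_mode <- match.arg(graph_mode)
  n <- nrow(ds$X); m <- ncol(ds$X)
  if (k_cluster > n) stopf("k_cluster (%d) > number of units (%d)",
                           k_cluster, n)
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (!isTRUE(ds$normalized))
    warning("dataset does not look preprocessed; consider preprocess_dataset()")
  use_image <- use_image %||% !is.null(ds$image)
  if (use_image && is.null(ds$image) && is.null(image_embeddings))
    stopf("use_image = TRUE but the dataset has no image")
  cfg <- gmvae_config(k_cluster, m, d_z = d_z, hidden = hidden,
                      hidden_dec = hidden_dec)
  w_img <- if (use_image) weights[["image"]] else 0
  w_js <- weights[["js"]]
  eps_img <- 1e-8

  E <- NULL
  if (use_image) {
    tab <- image_embeddings %||% embed_units(ds, spec = patch,
                                             extractor = extractor)
    E <- tab$E
    if (nrow(E) != n) stopf("embedding rows (%d) != units (%d)", nrow(E), n)
  }

  g <- build_knn_graph(ds, k_spatial, mode = graph_mode)

  fit <- with_seed(seed, {
    batches <- make_batches(g, batch_size, seed = sample.int(2^31 - 1L, 1L))
    ## per-batch constants: feature block, image-neighbour pairs, JS pairs
    prep <- lapply(batches, function(bt) {
      nt <- length(bt$target_ids)
      Xb <- ds$X[bt$member_ids, , drop = FALSE]
      img_pairs <- NULL
      if (use_image && nt > k_image) {
        nb <- image_neighbors(E[bt$target_ids, , drop = FALSE], k = k_image)
        img_pairs <- list(ii = rep(seq_len(nt), times = k_image),
                          jj = as.integer(nb))
      }
      # spatial pairs: every target with each of its graph neighbours
      pos <- integer(n); pos[bt$member_ids] <- seq_along(bt$member_ids)
      nb_sp <- g$neighbor_index[bt$target_ids, , drop = FALSE]
      js_pairs <- list(ti = rep(seq_len(nt), times = g$k),
                       u = pos[as.integer(nb_sp)],
                       deg = g$k)
      list(bt = bt, nt = nt, Xb = Xb, img_pairs = img_pairs,
           js_pairs = js_pairs)
    })

    params <- init_gmvae_params(cfg)
    ## Warm start. K-means on the neighbourhood-averaged input gives seeded
    ## pseudo-labels (the aggregation mirrors what the attention encoder
    ## sees, and averaging over ~k+1 profiles suppresses unit-level noise);
    ## the encoder and assignment head are briefly pretrained against them
    ## by cross-entropy, and the prior component means are then set to the
    ## per-cluster means of the first-pass embeddings. Without this
    ## anchoring, the label-agreement losses admit spatially smooth but
    ## arbitrary partitions (see the methods vignette).
    pseudo <- stats::kmeans(neighbor_mean(ds$X, g), centers = cfg$k,
                            nstart = 10L, iter.max = 100L)$cluster
    if (warm_epochs > 0L) {
      # supervised warm-up: the full ELBO with responsibilities clamped to
      # the pseudo-label one-hots (training decoder, posterior heads and
      # priors consistently with the pseudo-partition) plus cross-entropy
      # anchoring the assignment head; no image/JS terms yet
      wstate <- list(m = lapply(params, function(p) p * 0),
                     v = lapply(params, function(p) p * 0))
      wt <- 0L
      for (ep in seq_len(warm_epochs)) {
        for (pb in prep) {
          tp <- seq_len(pb$nt)
          eps <- matrix(stats::rnorm(pb$nt * cfg$d_z), pb$nt, cfg$d_z)
          onehot <- matrix(0, pb$nt, cfg$k)
          onehot[cbind(tp, pseudo[pb$bt$target_ids])] <- 1
          fw <- gmvae_forward(params, cfg, pb$Xb, pb$bt$local_edges, tp,
                              eps, Y_clamp = onehot)
          dle <- matrix(0, fw$enc$nm, cfg$k)
          dle[tp, ] <- fw$enc$Y[tp, , drop = FALSE] - onehot
          gr <- gmvae_backward(params, cfg, fw, dlogits_extra = dle)
          wt <- wt + 1L
          upd <- adam_update(params, gr, wstate, learning_rate, wt)
          params <- upd$params; wstate <- upd$state
        }
      }
    }
    fp <- full_encoder_pass(params, cfg, ds$X, g)
    for (j in seq_len(cfg$k)) {
      ix <- which(pseudo == j)
      if (length(ix))
        params$mu_prior[j, ] <- colMeans(fp$Z[ix, , drop = FALSE])
    }

    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    tstep <- 0L
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      acc <- c(image_loss = 0, reconstruction = 0, kl_z = 0, kl_y = 0,
               elbo = 0, js = 0, total = 0)
      for (bi in seq_along(prep)) {
        pb <- prep[[bi]]
        eps <- matrix(stats::rnorm(pb$nt * cfg$d_z), pb$nt, cfg$d_z)
        fw <- gmvae_forward(params, cfg, pb$Xb, pb$bt$local_edges,
                            seq_len(pb$nt), eps)
        Ym <- fw$enc$Y
        img_raw <- 0; ip <- NULL
        if (!is.null(pb$img_pairs)) {
          ii <- pb$img_pairs$ii; jj <- pb$img_pairs$jj
          dots <- rowSums(Ym[ii, , drop = FALSE] * Ym[jj, , drop = FALSE])
          img_raw <- sum(-log(pmax(dots, eps_img)))
          ip <- list(ii = ii, jj = jj,
                     coef = ifelse(dots > eps_img, -w_img / dots, 0))
        }
        jp <- pb$js_pairs
        tiny <- 1e-12
        P <- Ym[jp$ti, , drop = FALSE]; Q <- Ym[jp$u, , drop = FALSE]
        h2 <- function(Z) -rowSums(Z * log2(pmax(Z, tiny)))
        js_vals <- h2((P + Q) / 2) - (h2(P) + h2(Q)) / 2
        js_raw <- sum(js_vals) / jp$deg
        jsb <- list(ti = jp$ti, u = jp$u, w = w_js / jp$deg)

        total <- w_img * img_raw - fw$elbo + w_js * js_raw
        if (!is.finite(total))
          stopf("non-finite loss at epoch %d, batch %d", ep, bi)
        grads <- gmvae_backward(params, cfg, fw, img_pairs = ip,
                                js_pairs = jsb)
        tstep <- tstep + 1L
        upd <- adam_update(params, grads, state, learning_rate, tstep)
        params <- upd$params; state <- upd$state

        acc <- acc + c(img_raw, fw$reconstruction, fw$kl_z, fw$kl_y,
                       fw$elbo, js_raw, total)
      }
      hist[[ep]] <- acc
      if (verbose)
        message(sprintf(
          "epoch %d: total %.2f (image %.2f, elbo %.2f, js %.2f)",
          ep, acc[["total"]], acc[["image_loss"]], acc[["elbo"]],
          acc[["js"]]))
    }
    list(params = params, hist = hist)
  })

  loss_history <- cbind(epoch = seq_len(epochs),
                        as.data.frame(do.call(rbind, fit$hist)))
  if (!is.null(loss_log))
    utils::write.table(loss_history, loss_log, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  final <- full_encoder_pass(fit$params, cfg, ds$X, g)
  labels <- max.col(final$Y, ties.method = "first")
  res <- structure(list(
    labels = labels, soft = final$Y, embeddings = final$Z,
    loss_history = loss_history,
    params = fit$params, config = list(
      cfg = cfg, epochs = epochs, batch_size = batch_size,
      learning_rate = learning_rate, seed = seed, k_spatial = k_spatial,
      k_image = k_image, graph_mode = graph_mode, use_image = use_image,
      weights = weights),
    graph = g, coords = ds$coords, unit_ids = ds$unit_ids,
    feature_names = ds$feature_names, image_embeddings = E,
    call = match.call()),
    class = "stamix")
  res
}

#' Predict cluster assignments for a dataset
#'
#' Inference-only forward pass of a fitted model (no parameter updates):
#' rebuilds the KNN graph on the new coordinates/features with the stored
#' settings and encodes every unit with its complete neighbourhood. Applied
#' to the training data this reproduces the fitted labels exactly, since the
#' soft labels depend only on the (deterministic) encoder.
#'
#' @param object a fitted `"stamix"` model (or a checkpoint loaded with
#'   [stamix_load()]).
#' @param newdata a preprocessed [spatial_dataset()] with the same feature
#'   set as the training data.
#' @param ... unused.
#' @return list with `labels`, `soft`, `embeddings`.
#' @export
predict.stamix <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spatial_dataset"))
  cfg <- object$config$cfg
  if (ncol(newdata$X) != cfg$m)
    stopf("model features (%d) != data features (%d)", cfg$m,
          ncol(newdata$X))
  g <- build_knn_graph(newdata, object$config$k_spatial,
                       mode = object$config$graph_mode)
  out <- full_encoder_pass(object$params, cfg, newdata$X, g)
  list(labels = max.col(out$Y, ties.method = "first"),
       soft = out$Y, embeddings = out$Z)
}

#' Save a fitted model checkpoint
#'
#' A single file holding configuration and weights; [stamix_load()] restores
#' an object usable with [predict.stamix()] and [rank_svgs()].
#'
#' @param fit a `"stamix"` object.
#' @param path output file.
#' @export
stamix_save <- function(fit, path) {
  stopifnot(inherits(fit, "stamix"))
  saveRDS(fit, path)
  invisible(path)
}

#' Load a model checkpoint written by [stamix_save()]
#' @param path checkpoint file.
#' @return the `"stamix"` object.
#' @export
stamix_load <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "stamix")) stopf("not a stamix checkpoint: %s", path)
  obj
}
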