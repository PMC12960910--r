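# Shared fixtures and independent oracles used across test files.

# Small raw-count dataset on a grid with planted structure.
make_counts_ds <- function(n = 50, m = 20, seed = 1, density = 0.3) {
  set.seed(seed)
  X <- matrix(rpois(n * m, lambda = 2) * rbinom(n * m, 1, density), n, m)
  coords <- cbind(x = runif(n, 0, 100), y = runif(n, 0, 100))
  spatial_dataset(X, coords)
}

# O(n^2) pair-counting oracles for external clustering metrics: classify all
# unit pairs as together/apart in each partition and count agreements.
pair_counts <- function(truth, pred) {
  n <- length(truth)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    t_same <- truth[i] == truth[j]
    p_same <- pred[i] == pred[j]
    if (t_same && p_same) s11 <- s11 + 1
    else if (t_same && !p_same) s10 <- s10 + 1
    else if (!t_same && p_same) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  c(s11 = s11, s10 = s10, s01 = s01, s00 = s00)
}

ari_oracle <- function(truth, pred) {
  pc <- pair_counts(truth, pred)
  n <- length(truth)
  total <- n * (n - 1) / 2
  sa <- pc["s11"] + pc["s10"]   # pairs together in truth
  sb <- pc["s11"] + pc["s01"]   # pairs together in pred
  expected <- sa * sb / total
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1.0)
  unname((pc["s11"] - expected) / denom)
}

fmi_oracle <- function(truth, pred) {
  pc <- pair_counts(truth, pred)
  tp <- pc["s11"]; fp <- pc["s01"]; fn <- pc["s10"]
  if (tp + fp == 0 || tp + fn == 0) return(0)
  unname(sqrt(tp / (tp + fp)) * sqrt(tp / (tp + fn)))
}

silhouette_oracle <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    a <- mean(sapply(mates, function(j) d(i, j)))
    b <- min(sapply(setdiff(unique(labels), own), function(cl)
      mean(sapply(which(labels == cl), function(j) d(i, j)))))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Tiny trained model reused by several test files (lazy, computed once).
.fit_cache <- new.env(parent = emptyenv())

small_recovery_fixture <- function() {
  if (!is.null(.fit_cache$small)) return(.fit_cache$small)
  spec <- synthetic_spec(n_units = 400, k_domains = 3, m_features = 30,
                         seed = 7)
  ds <- generate_synthetic(spec)
  dsp <- preprocess_dataset(ds)
  dsp$image <- ds$image
  E <- embed_units(dsp, patch_spec(size = 17))
  fit <- stamix(dsp, k_cluster = 3, epochs = 40, batch_size = 400,
                seed = 1, image_embeddings = E)
  .fit_cache$small <- list(ds = ds, dsp = dsp, E = E, fit = fit,
                           markers = attr(ds, "synthetic")$markers)
  .fit_cache$small
}

# The clustering-recovery study: five seeded fits on the strong-signal
# fixture (2000 units, 4 contiguous domains, 3 markers each, informative
# image). Shared between the recovery and marker-ranking acceptance checks.
recovery_fits <- function() {
  if (!is.null(.fit_cache$recovery)) return(.fit_cache$recovery)
  spec <- synthetic_spec(n_units = 2000, k_domains = 4, m_features = 60,
                         seed = 11)
  ds <- generate_synthetic(spec)
  dsp <- preprocess_dataset(ds)
  dsp$image <- ds$image
  E <- embed_units(dsp, patch_spec(size = 17))
  fits <- lapply(1:5, function(s)
    stamix(dsp, k_cluster = 4, epochs = 60, batch_size = 1024, seed = s,
           image_embeddings = E))
  .fit_cache$recovery <- list(ds = ds, dsp = dsp, E = E, fits = fits,
                              markers = attr(ds, "synthetic")$markers)
  .fit_cache$recovery
}
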