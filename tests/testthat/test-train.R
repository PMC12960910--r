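# Small training fixture shared within this file.
train_fixture <- function(seed = 13, n = 250, k = 3, m = 24) {
  spec <- synthetic_spec(n_units = n, k_domains = k, m_features = m,
                         seed = seed)
  ds <- generate_synthetic(spec)
  dsp <- preprocess_dataset(ds)
  dsp$image <- ds$image
  list(ds = ds, dsp = dsp)
}

test_that("fitting is bitwise reproducible under a fixed seed", {
  fx <- train_fixture()
  f1 <- stamix(fx$dsp, k_cluster = 3, epochs = 8, batch_size = 100,
               seed = 4, warm_epochs = 4)
  f2 <- stamix(fx$dsp, k_cluster = 3, epochs = 8, batch_size = 100,
               seed = 4, warm_epochs = 4)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$soft, f2$soft)
  expect_identical(f1$params, f2$params)
  f3 <- stamix(fx$dsp, k_cluster = 3, epochs = 8, batch_size = 100,
               seed = 5, warm_epochs = 4)
  expect_false(identical(f1$soft, f3$soft))
})

test_that("disabling the image equals a zero image-loss weight", {
  fx <- train_fixture()
  f_off <- stamix(fx$dsp, k_cluster = 3, epochs = 6, batch_size = 250,
                  seed = 2, warm_epochs = 3, use_image = FALSE)
  f_w0 <- stamix(fx$dsp, k_cluster = 3, epochs = 6, batch_size = 250,
                 seed = 2, warm_epochs = 3, use_image = TRUE,
                 weights = c(image = 0, js = 1),
                 patch = patch_spec(size = 9))
  expect_identical(f_off$labels, f_w0$labels)
  expect_equal(f_off$soft, f_w0$soft, tolerance = 1e-12)
  # and the ablation run reports zero image loss throughout
  expect_true(all(f_off$loss_history$image_loss == 0))
})

test_that("prediction reproduces training labels and validates features", {
  fx <- train_fixture()
  fit <- stamix(fx$dsp, k_cluster = 3, epochs = 8, batch_size = 250,
                seed = 3, warm_epochs = 4, patch = patch_spec(size = 9))
  pr <- predict(fit, fx$dsp)
  expect_identical(pr$labels, fit$labels)
  expect_equal(pr$soft, fit$soft, tolerance = 1e-12)
  expect_equal(rowSums(pr$soft), rep(1, nrow(fx$dsp$X)), tolerance = 1e-6)
  expect_equal(max.col(fit$soft, ties.method = "first"), fit$labels)

  # feature-count mismatch errors with both counts
  bad <- fx$dsp
  bad$X <- bad$X[, 1:20]
  bad$feature_names <- bad$feature_names[1:20]
  expect_error(predict(fit, bad), "model features \\(24\\).*\\(20\\)")

  # checkpoint round trip through a single file
  path <- withr::local_tempfile(fileext = ".rds")
  stamix_save(fit, path)
  reloaded <- stamix_load(path)
  pr2 <- predict(reloaded, fx$dsp)
  expect_identical(pr2$labels, fit$labels)
})

test_that("loss history tracks the declared breakdown identity", {
  fx <- train_fixture()
  fit <- stamix(fx$dsp, k_cluster = 3, epochs = 5, batch_size = 250,
                seed = 6, warm_epochs = 3, patch = patch_spec(size = 9))
  h <- fit$loss_history
  expect_equal(nrow(h), 5L)
  # total = w_img * image_loss - elbo + w_js * js with unit weights
  expect_equal(h$total, h$image_loss - h$elbo + h$js, tolerance = 1e-8)
  expect_true(all(h$image_loss >= 0))
  expect_true(all(h$js >= 0))
  # elbo = reconstruction - kl_z - kl_y
  expect_equal(h$elbo, h$reconstruction - h$kl_z - h$kl_y,
               tolerance = 1e-8)
})

test_that("training is stable under unit reordering", {
  fx <- train_fixture(seed = 14, n = 300)
  fit <- stamix(fx$dsp, k_cluster = 3, epochs = 25, batch_size = 300,
                seed = 1, warm_epochs = 8, patch = patch_spec(size = 9))
  set.seed(99)
  perm <- sample(nrow(fx$dsp$X))
  dsp_p <- fx$dsp
  dsp_p$X <- dsp_p$X[perm, ]
  dsp_p$coords <- dsp_p$coords[perm, ]
  dsp_p$unit_ids <- dsp_p$unit_ids[perm]
  dsp_p$labels <- dsp_p$labels[perm]
  fit_p <- stamix(dsp_p, k_cluster = 3, epochs = 25, batch_size = 300,
                  seed = 1, warm_epochs = 8, patch = patch_spec(size = 9))
  # cluster identities may relabel and a few boundary units may flip, but
  # the partitions must agree closely
  expect_gt(adjusted_rand_index(fit$labels[perm], fit_p$labels), 0.8)
})

test_that("a single fit spans multiple slices with one label vocabulary", {
  spec1 <- synthetic_spec(n_units = 150, k_domains = 3, m_features = 24,
                          seed = 15)
  spec2 <- synthetic_spec(n_units = 150, k_domains = 3, m_features = 24,
                          seed = 16)
  d1 <- generate_synthetic(spec1)
  d2 <- generate_synthetic(spec2)
  # same feature space, disjoint coordinate ranges (second slice shifted)
  coords2 <- d2$coords
  coords2[, 1] <- coords2[, 1] + 5000
  both <- spatial_dataset(rbind(d1$X, d2$X), rbind(d1$coords, coords2),
                          labels = c(d1$labels, d2$labels))
  bothp <- preprocess_dataset(both)
  fit <- stamix(bothp, k_cluster = 3, epochs = 40, batch_size = 300,
                seed = 1, warm_epochs = 20, use_image = FALSE)
  slice <- rep(1:2, each = 150)[match(bothp$unit_ids, both$unit_ids)]
  # shared domain types get shared clusters: some clusters contain units
  # from both slices
  spans <- sapply(1:3, function(cl)
    length(unique(slice[fit$labels == cl])) == 2)
  expect_gt(sum(spans), 1)
  # and the joint clustering still recovers the planted domains
  truth <- both$labels[match(bothp$unit_ids, both$unit_ids)]
  expect_gt(adjusted_rand_index(truth, fit$labels), 0.7)
})

test_that("configuration errors are caught early", {
  fx <- train_fixture()
  expect_error(stamix(fx$dsp, k_cluster = 1000), "k_cluster")
  expect_error(stamix(fx$dsp, k_cluster = 3, epochs = 0), "epochs")
  noimg <- fx$dsp; noimg$image <- NULL
  expect_error(stamix(noimg, k_cluster = 3, use_image = TRUE), "no image")
  expect_warning(
    stamix(generate_synthetic(synthetic_spec(n_units = 60, k_domains = 2,
                                             m_features = 10, seed = 1)),
           k_cluster = 2, epochs = 1, warm_epochs = 0, use_image = FALSE),
    "preprocessed")
})
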