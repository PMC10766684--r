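# small labelled patch-set factory: constant-intensity patches per class
constant_patch_sets <- function(n_per_class = 60, p = 16, levels = c(0.2, 0.8),
                                seed = 1) {
  set.seed(seed)
  H <- 64
  imgs <- lapply(seq_along(levels), function(k)
    matrix(levels[k] + rnorm(H * H, sd = 0.01), H, H))
  sets <- lapply(seq_along(levels), function(k) {
    centers <- cbind(sample(20:44, n_per_class, TRUE), sample(20:44, n_per_class, TRUE))
    patch_set(centers, k, p, stats::setNames(imgs[k], as.character(k)),
              labels = rep(k, n_per_class))
  })
  combine_patch_sets(sets)
}

test_that("preprocessing is exact area-averaging plus guarded standardization", {
  cfg <- classifier_config(2, input_downsample_d = 8, architecture = "mlp")
  # p == d: downsampling is the identity (check via raw block means)
  set.seed(4)
  patch <- matrix(runif(64), 8, 8)
  out <- preprocess_patch(patch, cfg)
  expect_equal(out * stats::sd(patch) + mean(patch), patch)

  # constant patch maps to zeros (sd guard)
  expect_true(all(preprocess_patch(matrix(0.7, 24, 24), cfg) == 0))

  # p = 24 -> d = 8: each output pixel is the mean of its 3x3 source block
  p24 <- matrix(runif(24 * 24), 24, 24)
  down <- mobseg:::cpp_downsample_area(p24, 8L)
  oracle <- matrix(0, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    oracle[a, b] <- mean(p24[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)])
  }
  expect_equal(down, oracle, tolerance = 1e-12)

  # the full-scale geometry: 800 -> 100 is exact 8x8 block averaging
  p800 <- matrix(runif(800 * 800), 800, 800)
  d100 <- mobseg:::cpp_downsample_area(p800, 100L)
  i <- 37; j <- 73
  expect_equal(d100[i, j],
               mean(p800[(8 * i - 7):(8 * i), (8 * j - 7):(8 * j)]),
               tolerance = 1e-12)
})

test_that("a linearly separable two-class problem is solved within 5 epochs", {
  ps <- constant_patch_sets()
  sv <- split_train_val(ps, 0.7, seed = 2)
  cfg <- classifier_config(2, input_downsample_d = 8, architecture = "mlp",
                           learning_rate = 1e-2, max_epochs = 5, batch_size = 10,
                           seed = 3)
  model <- train_classifier(sv$train, sv$val, cfg)
  expect_lte(nrow(model$history), 5)
  expect_gte(max(model$history$val_acc), 0.99)
  # history bookkeeping: lr halves every lr_halving_period epochs
  expect_equal(model$history$lr[1], 1e-2)
  if (nrow(model$history) > 5) expect_equal(model$history$lr[6], 5e-3)
})

test_that("the conv backbone also learns the toy problem and stays reproducible", {
  ps <- constant_patch_sets(p = 16)
  sv <- split_train_val(ps, 0.7, seed = 2)
  cfg <- classifier_config(2, input_downsample_d = 8,
                           architecture = "lightweight",
                           learning_rate = 1e-2, max_epochs = 5,
                           batch_size = 10, seed = 3)
  m1 <- train_classifier(sv$train, sv$val, cfg)
  expect_gte(max(m1$history$val_acc), 0.99)
  m2 <- train_classifier(sv$train, sv$val, cfg)
  expect_identical(m1$params, m2$params)  # seed determinism
})

test_that("early stopping halts after patience epochs without improvement and keeps the best weights", {
  # labels are pure noise -> validation loss cannot keep improving
  ps <- constant_patch_sets(n_per_class = 40)
  set.seed(9)
  ps$labels <- sample(1:2, n_patches(ps), TRUE)
  sv <- split_train_val(ps, 0.7, seed = 2)
  cfg <- classifier_config(2, input_downsample_d = 8, architecture = "mlp",
                           learning_rate = 1e-2, max_epochs = 50,
                           early_stop_patience = 3, batch_size = 10, seed = 3)
  model <- train_classifier(sv$train, sv$val, cfg)
  expect_lt(nrow(model$history), 50)
  h <- model$history
  best <- which.min(h$val_loss)
  expect_equal(model$best_epoch, best)
  expect_equal(nrow(h), best + 3L)  # stopped exactly after `patience` stalls
})

test_that("one-hot predictions have exactly one bit, at the argmax with ties low", {
  ps <- constant_patch_sets()
  sv <- split_train_val(ps, 0.7, seed = 2)
  cfg <- classifier_config(2, input_downsample_d = 8, architecture = "mlp",
                           learning_rate = 1e-2, max_epochs = 3, batch_size = 10,
                           seed = 3)
  model <- train_classifier(sv$train, sv$val, cfg)
  for (v in c(0.15, 0.5, 0.85)) {
    oh <- predict_one_hot(model, matrix(v + rnorm(256, sd = 0.01), 16, 16))
    expect_equal(sum(oh), 1L)
  }
  # zeroed network -> all logits equal -> tie broken toward class 1
  model0 <- model
  model0$params <- lapply(model0$params, function(l) list(W = l$W * 0, b = l$b * 0))
  oh0 <- predict_one_hot(model0, matrix(0.5, 16, 16))
  expect_equal(oh0, c(1L, 0L))
})

test_that("batch prediction is order-preserving and batching-invariant", {
  ps <- constant_patch_sets(n_per_class = 50)
  sv <- split_train_val(ps, 0.7, seed = 2)
  cfg <- classifier_config(2, input_downsample_d = 8, architecture = "mlp",
                           learning_rate = 1e-2, max_epochs = 3, batch_size = 10,
                           seed = 3)
  model <- train_classifier(sv$train, sv$val, cfg)
  pred <- predict_batch(model, ps)
  expect_equal(pred$centers, ps$centers)
  expect_length(pred$class_idx, n_patches(ps))
  # element-wise consistency with predict_one_hot
  for (i in c(1L, 25L, n_patches(ps))) {
    oh <- predict_one_hot(model, patch_pixels(ps, i))
    expect_equal(which(oh == 1L), pred$class_idx[i])
  }
  model1 <- model; model1$config$batch_size <- 1L
  pred1 <- predict_batch(model1, ps)
  expect_identical(pred$class_idx, pred1$class_idx)
})

test_that("training rejects labels outside the scheme and empty inputs", {
  ps <- constant_patch_sets()
  sv <- split_train_val(ps, 0.7, seed = 2)
  cfg <- classifier_config(1, input_downsample_d = 8, architecture = "mlp")
  expect_error(train_classifier(sv$train, sv$val, cfg), "exceeds c")
  expect_error(classifier_config(2, input_downsample_d = 4), ">= 8")
  expect_error(classifier_config(2, dropout_rate = 1), "dropout_rate")
})

test_that("models survive a save/load round trip", {
  ps <- constant_patch_sets()
  sv <- split_train_val(ps, 0.7, seed = 2)
  cfg <- classifier_config(2, input_downsample_d = 8, architecture = "mlp",
                           learning_rate = 1e-2, max_epochs = 2, batch_size = 10,
                           seed = 3)
  model <- train_classifier(sv$train, sv$val, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, path)
  back <- load_classifier(path)
  expect_identical(back$params, model$params)
  expect_identical(predict_batch(back, ps)$class_idx,
                   predict_batch(model, ps)$class_idx)
})

test_that("the oracle classifier returns ground-truth center labels", {
  gt <- matrix(0L, 20, 20); gt[5:15, 5:15] <- 1L; gt[8:12, 8:12] <- 2L
  img <- matrix(0.5, 20, 20)
  ps <- sample_prediction_patches(img, gt > 0, 100, 5, seed = 1)
  oc <- oracle_classifier(list("1" = gt), 2)
  pred <- predict_batch(oc, ps)
  expect_equal(pred$class_idx, gt[ps$centers])
  bg <- patch_set(matrix(c(1L, 1L), 1), 1L, 5, list("1" = img))
  expect_error(predict_batch(oc, bg), "unlabelled")
})
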