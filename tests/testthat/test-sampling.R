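reflect_idx <- function(i, n) {
  # mirror-without-edge-repeat fold onto 1..n (i may be any integer)
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * n - 2L
  m <- (i - 1L) %% period
  ifelse(m >= n, period - m, m) + 1L
}

test_that("patch extraction reflects at borders exactly like a padded-copy oracle", {
  set.seed(10)
  img <- matrix(runif(7 * 9), 7, 9)
  for (center in list(c(1L, 1L), c(7L, 9L), c(1L, 5L), c(4L, 4L))) {
    p <- 5L
    patch <- extract_patch(img, center, p)
    rows <- reflect_idx(center[1] + (0:(p - 1)) - p %/% 2, 7)
    cols <- reflect_idx(center[2] + (0:(p - 1)) - p %/% 2, 9)
    expect_equal(patch, img[rows, cols])
  }
  # constant slice -> constant patch; p = 1 -> the center pixel itself
  cimg <- matrix(0.4, 6, 6)
  expect_true(all(extract_patch(cimg, c(2, 2), 5) == 0.4))
  expect_equal(extract_patch(img, c(3, 4), 1), img[3, 4, drop = FALSE])
  expect_error(extract_patch(img, c(0, 1), 3), "outside")
})

test_that("extract_patch matches a naive double-loop copy on random instances", {
  set.seed(77)
  for (i in 1:10) {
    H <- sample(3:12, 1); W <- sample(3:12, 1)
    img <- matrix(runif(H * W), H, W)
    p <- sample(c(2:7), 1)
    cy <- sample(H, 1); cx <- sample(W, 1)
    patch <- extract_patch(img, c(cy, cx), p)
    oracle <- matrix(0, p, p)
    for (a in 1:p) for (b in 1:p) {
      oracle[a, b] <- img[reflect_idx(cy + a - 1 - p %/% 2, H),
                          reflect_idx(cx + b - 1 - p %/% 2, W)]
    }
    expect_equal(patch, oracle)
  }
})

test_that("training patches come from labelled pixels and carry their center labels", {
  set.seed(1)
  img <- matrix(runif(40 * 40), 40, 40)
  ann <- matrix(0L, 40, 40)
  ann[5:30, 5:30] <- 1L
  ann[10:14, 10:14] <- 2L
  ps <- sample_training_patches(img, ann, 500, 9, seed = 3)
  expect_equal(n_patches(ps), 500)
  expect_true(all(ps$labels %in% 1:2))
  expect_true(all(ann[ps$centers] > 0))
  expect_equal(ps$labels, ann[ps$centers])

  # single labelled pixel: every center lands there
  one <- matrix(0L, 10, 10); one[4, 7] <- 3L
  ps1 <- sample_training_patches(img[1:10, 1:10], one, 20, 3, seed = 1)
  expect_true(all(ps1$centers[, 1] == 4 & ps1$centers[, 2] == 7))
  expect_true(all(ps1$labels == 3L))

  expect_error(sample_training_patches(img, matrix(0L, 40, 40), 5, 9),
               "all background")
  # determinism
  ps2 <- sample_training_patches(img, ann, 500, 9, seed = 3)
  expect_identical(ps$centers, ps2$centers)
  expect_identical(ps$labels, ps2$labels)
})

test_that("label proportions of uniform sampling follow the binomial law", {
  img <- matrix(0.5, 100, 100)
  ann <- matrix(0L, 100, 100)
  ann[1:90, 1:100] <- 1L   # 90% of labelled pixels
  ann[91:100, 1:100] <- 2L # 10%
  m <- 10000
  hits <- 0L
  for (s in 1:20) {
    ps <- sample_training_patches(img, ann, m, 5, seed = s)
    frac <- mean(ps$labels == 1L)
    if (abs(frac - 0.9) <= 4 * sqrt(0.9 * 0.1 / m)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("train/validation split partitions the samples at the requested fraction", {
  img <- matrix(0.5, 50, 50)
  ann <- matrix(1L, 50, 50)
  ps <- sample_training_patches(img, ann, 10, 5, seed = 2)
  sv <- split_train_val(ps, 0.7, seed = 4)
  expect_equal(n_patches(sv$train), 7)
  expect_equal(n_patches(sv$val), 3)
  key <- function(x) paste(x$centers[, 1], x$centers[, 2], x$slice_index)
  expect_length(intersect(key(sv$train), key(sv$val)), 0)

  big <- sample_training_patches(img, ann, 220000, 5, seed = 2)
  svb <- split_train_val(big, 0.7, seed = 4)
  expect_equal(n_patches(svb$train), 154000)
  expect_equal(n_patches(svb$val), 66000)

  expect_error(split_train_val(sample_training_patches(img, ann, 1, 5, seed = 1), 0.7),
               "at least 2")
  expect_error(split_train_val(ps, 1.2), "between 0 and 1")
})

test_that("prediction patches stay inside the foreground and are unlabelled", {
  set.seed(9)
  img <- matrix(runif(30 * 30), 30, 30)
  fg <- matrix(FALSE, 30, 30); fg[10:20, 12:25] <- TRUE
  ps <- sample_prediction_patches(img, fg, 300, 7, seed = 8)
  expect_null(ps$labels)
  expect_true(all(fg[ps$centers]))

  single <- matrix(FALSE, 30, 30); single[17, 3] <- TRUE
  ps1 <- sample_prediction_patches(img, single, 10, 7, seed = 8)
  expect_true(all(ps1$centers[, 1] == 17 & ps1$centers[, 2] == 3))

  expect_error(sample_prediction_patches(img, matrix(FALSE, 30, 30), 5, 7,
                                         slice_index = 12),
               "slice 12")
  ps2 <- sample_prediction_patches(img, fg, 300, 7, seed = 8)
  expect_identical(ps$centers, ps2$centers)
})

test_that("patch sets combine and subset consistently across slices", {
  img1 <- matrix(runif(20 * 20), 20, 20)
  img2 <- matrix(runif(20 * 20), 20, 20)
  ann <- matrix(1L, 20, 20)
  a <- sample_training_patches(img1, ann, 5, 5, slice_index = 1, seed = 1)
  b <- sample_training_patches(img2, ann, 7, 5, slice_index = 4, seed = 2)
  both <- combine_patch_sets(list(a, b))
  expect_equal(n_patches(both), 12)
  expect_equal(patch_pixels(both, 1), patch_pixels(a, 1))
  expect_equal(patch_pixels(both, 6), patch_pixels(b, 1))
  expect_error(combine_patch_sets(list(a, sample_training_patches(img2, ann, 3, 7, seed = 1))),
               "different patch sizes")
})
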