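make_predictions <- function(centers, classes, c) {
  structure(list(centers = matrix(as.integer(centers), ncol = 2),
                 slice_index = rep(1L, length(classes)),
                 class_idx = as.integer(classes), c = as.integer(c)),
            class = "patch_predictions")
}

test_that("the sparse map deposits and accumulates one-hot votes at patch centers", {
  empty <- make_predictions(matrix(integer(0), 0, 2), integer(0), 4)
  sm0 <- build_sparse_map(empty, c(6, 7), 4)
  expect_true(all(sm0$counts == 0))
  expect_equal(sm0$n_filled, 0)

  one <- make_predictions(c(3, 5), 3, 4)
  sm1 <- build_sparse_map(one, c(10, 10))
  expect_equal(sm1$counts[3, 5, 3], 1L)
  expect_equal(sum(sm1$counts), 1L)

  # two different classes at one pixel accumulate on their own channels
  two <- make_predictions(rbind(c(2, 2), c(2, 2)), c(1, 2), 3)
  sm2 <- build_sparse_map(two, c(4, 4))
  expect_equal(sm2$counts[2, 2, 1], 1L)
  expect_equal(sm2$counts[2, 2, 2], 1L)
  expect_equal(sm2$n_filled, 2)
  # repeated identical predictions accumulate counts
  rep3 <- make_predictions(rbind(c(1, 1), c(1, 1), c(1, 1)), c(2, 2, 2), 2)
  expect_equal(build_sparse_map(rep3, c(3, 3))$counts[1, 1, 2], 3L)

  expect_error(build_sparse_map(make_predictions(c(11, 1), 1, 2), c(10, 10)),
               "outside")
})

test_that("the density scan equals the naive double-loop window sum", {
  one <- make_predictions(c(30, 40), 1, 1)
  sm <- build_sparse_map(one, c(80, 90))
  cm <- density_scan(sm, 51)
  block <- cm$density[, , 1] == 1
  expect_equal(sum(block), 51 * 51)
  expect_true(all(which(block, arr.ind = TRUE)[, 1] %in% 5:55))

  set.seed(21)
  counts <- array(rpois(40 * 40 * 3, 0.2), c(40, 40, 3))
  sm2 <- structure(list(counts = counts, n_filled = sum(counts)), class = "sparse_map")
  cm2 <- density_scan(sm2, 7)
  for (k in 1:3) expect_identical(cm2$density[, , k], naive_window_sum(counts[, , k], 7))

  expect_error(density_scan(sm2, 0), ">= 1")
  expect_error(density_scan(sm2, 6), "odd")
})

test_that("argmax labelling respects foreground, zero evidence and the tie rule", {
  H <- 12; W <- 12; c <- 3
  zero <- structure(list(density = array(0, c(H, W, c)), window_w = 5),
                    class = "confidence_maps")
  fg <- matrix(TRUE, H, W)
  expect_true(all(assign_labels(zero, fg) == 0L))

  set.seed(31)
  dens <- array(sample(0:5, H * W * c, TRUE), c(H, W, c))
  conf <- structure(list(density = dens, window_w = 5), class = "confidence_maps")
  fg2 <- matrix(runif(H * W) < 0.7, H, W)
  rr <- assign_labels(conf, fg2)
  # brute-force per-pixel oracle with ties to the lowest channel
  for (y in 1:H) for (x in 1:W) {
    v <- dens[y, x, ]
    want <- if (!fg2[y, x] || max(v) == 0) 0L else which.max(v)
    expect_identical(rr[y, x], as.integer(want))
  }
  # dominant channel 3 (0-based channel 2) -> structure id 3
  d3 <- array(0, c(4, 4, 4)); d3[2, 2, 3] <- 7
  conf3 <- structure(list(density = d3, window_w = 5), class = "confidence_maps")
  expect_equal(assign_labels(conf3, matrix(TRUE, 4, 4))[2, 2], 3L)
})

test_that("small components are reassigned to the longest-boundary neighbour", {
  # 30x30: structure 1 dominates; a 5-px island of structure 2 sits inside 1;
  # structure 2 also owns a large block elsewhere
  rr <- matrix(0L, 30, 30)
  rr[3:28, 3:28] <- 1L
  rr[3:28, 20:28] <- 2L
  rr[10, 5:7] <- 2L; rr[11, 5:6] <- 2L   # 5-px island of 2 inside 1
  out <- reassign_small_components(rr, 0.1)
  expect_true(all(out[10, 5:7] == 1L))
  expect_true(all(out[11, 5:6] == 1L))
  # untouched elsewhere
  expect_identical(out[rr == 2L & out != 1L], rr[rr == 2L & out != 1L])

  # nothing below threshold: identity
  expect_identical(reassign_small_components(rr, 0.0001), rr)

  # island whose only neighbour is background becomes background
  lone <- matrix(0L, 20, 20)
  lone[2:3, 2:3] <- 1L
  lone[10:18, 10:18] <- 1L
  out2 <- reassign_small_components(lone, 0.2)
  expect_true(all(out2[2:3, 2:3] == 0L))
  expect_true(all(out2[10:18, 10:18] == 1L))
})

test_that("component reassignment never invents labels nor shrinks the largest component", {
  for (seed in 1:8) {
    rr <- random_label_map(40, 40, 4, seed)
    out <- reassign_small_components(rr, 0.2)
    expect_true(all(out %in% c(0L, sort(unique(rr[rr > 0L])))))
    for (s in sort(unique(rr[rr > 0L]))) {
      comp_in <- mobseg:::cpp_label_components(matrix(as.integer(rr == s), 40))
      comp_out <- mobseg:::cpp_label_components(matrix(as.integer(out == s), 40))
      max_in <- if (max(comp_in) > 0) max(tabulate(comp_in[comp_in > 0])) else 0
      max_out <- if (max(comp_out) > 0) max(tabulate(comp_out[comp_out > 0])) else 0
      expect_gte(max_out, max_in)
      # every sub-threshold input component was relabelled
      if (max(comp_in) > 1) {
        areas <- tabulate(comp_in[comp_in > 0])
        for (ci in which(areas < 0.2 * max(areas))) {
          expect_true(all(out[comp_in == ci] != s))
        }
      }
    }
  }
})

test_that("reconstruct_slice handles m = 0 and is seed-deterministic", {
  spec <- tiny_phantom_spec(n_slices = 1)
  ph <- generate_phantom(spec)
  slice <- ph$stack$voxels[, , 1]
  gt <- ph$labels$labels[, , 1]
  fg <- gt > 0
  oracle <- oracle_classifier(list("1" = gt), 2)
  expect_warning(r0 <- reconstruct_slice(slice, fg, oracle, 0, 9, 11), "m = 0")
  expect_true(all(r0 == 0L))
  r1 <- reconstruct_slice(slice, fg, oracle, 2000, 9, 11, seed = 5)
  r2 <- reconstruct_slice(slice, fg, oracle, 2000, 9, 11, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1[!fg] == 0L))
})

test_that("exhaustive one-vote-per-pixel stub predictions recover the easy phantom almost exactly", {
  spec <- phantom_preset("easy", n_slices = 1)
  ph <- generate_phantom(spec)
  gt <- ph$labels$labels[, , 1]
  fg_idx <- which(gt > 0)
  centers <- cbind(((fg_idx - 1L) %% 512L) + 1L, ((fg_idx - 1L) %/% 512L) + 1L)
  ps <- patch_set(centers, 1L, 65L, list("1" = ph$stack$voxels[, , 1]))
  pred <- predict_batch(oracle_classifier(list("1" = gt), 5), ps)
  rr <- assign_labels(density_scan(build_sparse_map(pred, c(512, 512)), 51), gt > 0)
  lab <- reassign_small_components(rr, 0.05)
  for (s in 1:5) {
    expect_gte(score_structure(lab == s, gt == s)$dsc, 0.95)
  }
})

test_that("assembled volumes interleave training and predicted slices in z order", {
  scheme <- label_scheme(c("a", "b"))
  sp <- split_slices(3, 2)  # TC = {1, 3}, PC = {2}
  ta1 <- matrix(1L, 4, 4); ta3 <- matrix(2L, 4, 4)
  pr2 <- matrix(0L, 4, 4); pr2[2, 2] <- 1L
  vol <- assemble_volume(sp, list("1" = ta1, "3" = ta3), list("2" = pr2), scheme)
  expect_identical(vol$labels[, , 1], ta1)
  expect_identical(vol$labels[, , 2], pr2)
  expect_identical(vol$labels[, , 3], ta3)

  # all-training: output equals the annotations verbatim
  sp1 <- split_slices(2, 1)
  vol2 <- assemble_volume(sp1, list("1" = ta1, "2" = ta3), list(), scheme)
  expect_identical(vol2$labels[, , 1], ta1)
  expect_identical(vol2$labels[, , 2], ta3)

  expect_error(assemble_volume(sp, list("1" = ta1, "3" = ta3), list(), scheme),
               "no annotation")
  expect_error(assemble_volume(sp, list("1" = ta1, "3" = ta3),
                               list("2" = pr2, "3" = ta3), scheme),
               "both")
})
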