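test_that("two concentric layers partition a slice into ring, disc and background", {
  spec <- phantom_spec(100, 100, 1,
                      list(layer_spec(1, 0.9, 50), layer_spec(2, 0.5, 50)))
  m <- layer_masks(spec, 1)
  expect_equal(sort(unique(as.vector(m))), c(0L, 1L, 2L))
  expect_equal(length(m), 10000L)
  # the disc sits strictly inside the ring: every label-2 pixel is closer to
  # the center than any label-1 pixel along the same normalized radius
  e <- sqrt(outer(((1:100 - 50.5) / 50)^2, ((1:100 - 50.5) / 50)^2, `+`))
  expect_true(all(e[m == 2] <= 0.5 + 1e-12))
  expect_true(all(e[m == 1] > 0.5 & e[m == 1] <= 0.9 + 1e-12))
  expect_true(all(e[m == 0] > 0.9))
})

test_that("annulus pixel membership matches an exhaustive per-pixel test on 200x200", {
  spec <- phantom_spec(200, 200, 1,
                      list(layer_spec(1, 0.9, 0), layer_spec(2, 0.5, 0)))
  m <- layer_masks(spec, 1)
  # brute-force oracle over all pixels
  oracle <- matrix(0L, 200, 200)
  for (y in 1:200) {
    for (x in 1:200) {
      e <- sqrt(((y - 100.5) / 100)^2 + ((x - 100.5) / 100)^2)
      oracle[y, x] <- if (e <= 0.5) 2L else if (e <= 0.9) 1L else 0L
    }
  }
  expect_identical(m, oracle)
})

test_that("constant radius profiles give identical masks on every slice", {
  spec <- tiny_phantom_spec(n_slices = 4)
  masks <- lapply(1:4, function(z) layer_masks(spec, z))
  for (z in 2:4) expect_identical(masks[[z]], masks[[1]])
})

test_that("crossing radius profiles are rejected", {
  expect_error(
    phantom_spec(64, 64, 2, list(layer_spec(1, c(0.8, 0.4), 10),
                                 layer_spec(2, c(0.5, 0.5), 10))),
    "strictly decreasing")
})

test_that("rendering is deterministic and texture-free layers are piecewise constant", {
  spec <- phantom_spec(48, 48, 1,
                      list(layer_spec(1, 0.8, 0, background_intensity = 0.7, noise_sd = 0),
                           layer_spec(2, 0.4, 0, background_intensity = 0.3, noise_sd = 0)),
                      background_intensity = 0.9, background_noise_sd = 0)
  m <- layer_masks(spec, 1)
  img <- render_slice(m, spec, seed = 5)
  expect_equal(unique(img[m == 0]), 0.9)
  expect_equal(unique(img[m == 1]), 0.7)
  expect_equal(unique(img[m == 2]), 0.3)
  spec2 <- tiny_phantom_spec()
  m2 <- layer_masks(spec2, 1)
  expect_identical(render_slice(m2, spec2, seed = 11),
                   render_slice(m2, spec2, seed = 11))
})

test_that("realized dot counts follow the Poisson mean of the layer density", {
  # single-pixel dots (radius 0.5) in the inner disc allow exact counting
  spec <- phantom_spec(100, 100, 1,
                      list(layer_spec(1, 0.95, 0, noise_sd = 0),
                           layer_spec(2, 0.60, 50, dot_radius_px = 0.5,
                                      dot_intensity = 0.1, noise_sd = 0)),
                      background_noise_sd = 0)
  m <- layer_masks(spec, 1)
  A <- sum(m == 2)
  lambda <- 50 * A / 1e4
  tol <- 4 * sqrt(lambda)
  hits <- 0L
  for (s in 1:100) {
    img <- render_slice(m, spec, seed = s)
    n_dots <- sum(img[m == 2] < 0.5)
    if (abs(n_dots - lambda) <= tol) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("generate_phantom aligns stack and labels and is seed-deterministic", {
  spec <- tiny_phantom_spec(n_slices = 10)
  ph <- generate_phantom(spec)
  expect_equal(n_slices(ph$stack), 10)
  expect_equal(dim(ph$labels$labels), dim(ph$stack$voxels))
  ph2 <- generate_phantom(tiny_phantom_spec(n_slices = 10))
  expect_identical(ph$stack$voxels, ph2$stack$voxels)
  expect_identical(ph$labels$labels, ph2$labels$labels)
  # labels partition every slice
  expect_true(all(ph$labels$labels %in% 0:2))
})

test_that("a linearly shrinking radius profile gives strictly decreasing foreground", {
  shrink <- seq(0.9, 0.5, length.out = 6)
  spec <- phantom_spec(80, 80, 6,
                      list(layer_spec(1, shrink, 10),
                           layer_spec(2, shrink * 0.5, 10)))
  ph <- generate_phantom(spec)
  areas <- apply(ph$labels$labels > 0, 3, sum)
  expect_true(all(diff(areas) < 0))
})

test_that("phantom presets build valid five-structure worlds and write to disk", {
  for (nm in c("easy", "hard")) {
    spec <- phantom_preset(nm, height = 64, width = 64, n_slices = 2)
    expect_equal(spec$scheme$c, 5L)
    ph <- generate_phantom(spec)
    expect_equal(sort(unique(as.vector(ph$labels$labels))), 0:5)
  }
  dir <- file.path(withr::local_tempdir(), "ph")
  ph <- write_phantom(phantom_preset("easy", height = 48, width = 48, n_slices = 2), dir)
  expect_true(file.exists(file.path(dir, "image.tif")))
  expect_true(file.exists(file.path(dir, "labels.tif")))
  side <- jsonlite::read_json(file.path(dir, "phantom.json"))
  expect_equal(side$n_slices, 2L)
  back <- read_slice_stack(file.path(dir, "image.tif"))
  expect_equal(back$voxels, round(ph$stack$voxels * 255) / 255, tolerance = 1e-12)
})
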