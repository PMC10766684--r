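# Shared fixtures: tiny phantoms and random label maps, all generated in code.

tiny_phantom_spec <- function(height = 64, width = 64, n_slices = 3,
                              seed = 42, densities = c(150, 10),
                              radii = c(0.8, 0.4)) {
  layers <- lapply(seq_along(radii), function(k)
    layer_spec(k, radii[k], densities[k], dot_radius_px = 1.5,
               dot_intensity = 0.1, background_intensity = 0.9,
               noise_sd = 0.02))
  phantom_spec(height, width, n_slices, layers, seed = seed,
               background_intensity = 0.9, background_noise_sd = 0.02)
}

# random blobby label map: a few seeded rectangles over background
random_label_map <- function(H, W, c, seed) {
  set.seed(seed)
  m <- matrix(0L, H, W)
  for (i in seq_len(c + 3)) {
    s <- sample.int(c, 1)
    y <- sort(sample.int(H, 2)); x <- sort(sample.int(W, 2))
    m[y[1]:y[2], x[1]:x[2]] <- s
  }
  m
}

# naive O(H*W*w^2) double-loop window sum oracle
naive_window_sum <- function(M, w) {
  h <- (w - 1) %/% 2
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      ys <- max(1, y - h):min(H, y + h)
      xs <- max(1, x - h):min(W, x + h)
      out[y, x] <- sum(M[ys, xs])
    }
  }
  out
}
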