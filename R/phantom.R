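#' Synthetic layered-cytoarchitecture phantom
#'
#' Builds a stand-in for Nissl-stained laminar brain volumes: concentric
#' elliptical layers whose cross-sections morph smoothly along z, each layer
#' textured by its own Poisson point process of soma-like dots (layer-specific
#' density, size and contrast) on a common background, plus clipped Gaussian
#' noise. Texture — not raw intensity alone — is what separates the layers,
#' which is exactly the regime the patch classifier is built for.
#'
#' `layer_spec()` describes one layer (outermost first); `phantom_spec()`
#' assembles the volume description; [generate_phantom()] renders it.
#'
#' @param label structure label in `1..c` carried by the layer.
#' @param radius_profile outer boundary of the layer per slice, as a fraction
#'   of the half-image size (scalar = constant in z, or one value per slice).
#'   Layer k occupies the elliptical annulus between its own fraction and the
#'   next layer's; the last layer is a full disc.
#' @param dot_density expected dots per 100 x 100 px of layer area.
#' @param dot_radius_px dot (soma) radius, px.
#' @param dot_intensity,background_intensity intensities in `[0, 1]`; dots are
#'   stamped over the background (and may cross layer boundaries, as real
#'   somata do).
#' @param noise_sd additive Gaussian noise sd inside the layer.
#' @return `layer_spec()`: a `layer_spec` object.
#' @export
layer_spec <- function(label, radius_profile, dot_density, dot_radius_px = 1.5,
                       dot_intensity = 0.15, background_intensity = 0.85,
                       noise_sd = 0.03) {
  stopifnot(label >= 1, all(radius_profile > 0), all(radius_profile <= 1),
            dot_density >= 0, dot_radius_px > 0,
            dot_intensity >= 0, dot_intensity <= 1,
            background_intensity >= 0, background_intensity <= 1,
            noise_sd >= 0)
  structure(list(label = as.integer(label), radius_profile = radius_profile,
                 dot_density = dot_density, dot_radius_px = dot_radius_px,
                 dot_intensity = dot_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @param height,width slice size, px.
#' @param n_slices number of z slices.
#' @param layers list of `layer_spec`s, outermost first, with strictly
#'   decreasing radius profiles on every slice.
#' @param seed integer seed; (spec, seed) fully determines the volume.
#' @param background_intensity,background_noise_sd appearance of the label-0
#'   region outside all layers.
#' @param label_names optional structure names for the ground-truth scheme.
#' @export
phantom_spec <- function(height, width, n_slices, layers, seed = 1L,
                         background_intensity = 0.85,
                         background_noise_sd = 0.03,
                         label_names = NULL) {
  stopifnot(height >= 8, width >= 8, n_slices >= 1, length(layers) >= 2)
  layers <- lapply(layers, function(l) {
    if (!inherits(l, "layer_spec")) stop("`layers` must be a list of layer_spec objects")
    if (length(l$radius_profile) == 1L)
      l$radius_profile <- rep(l$radius_profile, n_slices)
    if (length(l$radius_profile) != n_slices)
      stop("radius_profile must have length 1 or n_slices")
    l
  })
  prof <- vapply(layers, `[[`, numeric(n_slices), "radius_profile")
  prof <- matrix(prof, nrow = n_slices)
  if (any(apply(prof, 1, function(r) any(diff(r) >= 0))))
    stop("layer radius profiles must be strictly decreasing from outermost to innermost on every slice")
  labs <- vapply(layers, `[[`, integer(1), "label")
  if (anyDuplicated(labs)) stop("layer labels must be unique")
  if (is.null(label_names)) label_names <- sprintf("S%d", seq_len(max(labs)))
  if (length(label_names) < max(labs))
    stop("`label_names` must cover every layer label")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_slices = as.integer(n_slices), layers = layers,
                 seed = as.integer(seed),
                 background_intensity = background_intensity,
                 background_noise_sd = background_noise_sd,
                 scheme = label_scheme(label_names)),
            class = "phantom_spec")
}

#' Ground-truth layer masks of a phantom slice
#'
#' Partitions slice `z` into concentric elliptical annuli following each
#' layer's radius profile; every pixel receives exactly one label in
#' `0..c` (0 outside the outermost layer).
#'
#' @param spec a [phantom_spec()].
#' @param z slice index in `1..n_slices`.
#' @return integer `height x width` label matrix.
#' @export
layer_masks <- function(spec, z) {
  stopifnot(inherits(spec, "phantom_spec"), z >= 1, z <= spec$n_slices)
  H <- spec$height; W <- spec$width
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ry <- H / 2; rx <- W / 2
  ey <- ((seq_len(H) - cy) / ry)^2
  ex <- ((seq_len(W) - cx) / rx)^2
  e <- sqrt(outer(ey, ex, `+`))
  mask <- matrix(0L, H, W)
  fr <- vapply(spec$layers, function(l) l$radius_profile[z], numeric(1))
  labs <- vapply(spec$layers, `[[`, integer(1), "label")
  L <- length(fr)
  for (k in seq_len(L)) {
    inside <- if (k < L) e <= fr[k] & e > fr[k + 1] else e <= fr[k]
    mask[inside] <- labs[k]
  }
  mask
}

stamp_dots <- function(img, centers_y, centers_x, radius, intensity) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
  H <- nrow(img); W <- ncol(img)
  for (i in seq_along(centers_y)) {
    yy <- centers_y[i] + off$dy
    xx <- centers_x[i] + off$dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    img[cbind(yy[ok], xx[ok])] <- intensity
  }
  img
}

#' Render one phantom slice
#'
#' Draws each layer's Poisson dot process over the layer backgrounds, adds
#' per-layer Gaussian noise and clips to `[0, 1]`. Deterministic given `seed`.
#'
#' @param mask label matrix from [layer_masks()].
#' @param spec the [phantom_spec()].
#' @param seed integer seed for this slice (`NULL` = use the current RNG state).
#' @return numeric `height x width` grayscale matrix in `[0, 1]`.
#' @export
render_slice <- function(mask, spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  H <- nrow(mask); W <- ncol(mask)
  img <- matrix(spec$background_intensity, H, W)
  sd_map <- matrix(spec$background_noise_sd, H, W)
  for (l in spec$layers) {
    inside <- mask == l$label
    img[inside] <- l$background_intensity
    sd_map[inside] <- l$noise_sd
  }
  for (l in spec$layers) {
    idx <- which(mask == l$label)
    if (length(idx) == 0L) next
    lambda <- l$dot_density * length(idx) / 1e4
    n_dots <- stats::rpois(1L, lambda)
    if (n_dots > 0L) {
      pick <- idx[sample.int(length(idx), n_dots, replace = TRUE)]
      img <- stamp_dots(img, ((pick - 1L) %% H) + 1L, ((pick - 1L) %/% H) + 1L,
                        l$dot_radius_px, l$dot_intensity)
    }
  }
  if (any(sd_map > 0)) {
    img <- img + stats::rnorm(H * W) * sd_map
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a phantom volume with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `stack` (a [slice_stack()]) and `labels`
#'   (the ground-truth [label_volume()]), aligned slice by slice.
#' @examples
#' spec <- phantom_preset("easy", height = 96, width = 96, n_slices = 3)
#' ph <- generate_phantom(spec)
#' n_slices(ph$stack)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vox <- array(0, c(spec$height, spec$width, spec$n_slices))
  lab <- array(0L, c(spec$height, spec$width, spec$n_slices))
  for (z in seq_len(spec$n_slices)) {
    m <- layer_masks(spec, z)
    vox[, , z] <- render_slice(m, spec, seed = derive_seed(spec$seed, "phantom", z))
    lab[, , z] <- m
  }
  list(stack = slice_stack(vox, pixel_size_um = 1, bit_depth = 8L),
       labels = label_volume(lab, spec$scheme))
}

#' Preset phantoms
#'
#' Two fixed five-layer worlds used throughout the tests. `"easy"`: thick
#' layers whose dot density x size combinations are pairwise well separated
#' (in local dot coverage), alternating high/low the way MOB laminae do
#' (GL dense, EPL sparse, ML dense small somata, IPL sparse large somata,
#' GCL dense).
#' `"hard"`: closer densities, more noise, and one thin ML-like layer (~3% of
#' the half-image, i.e. ~15 px at 512) that challenges the patch classifier.
#' Cross-sections swell towards mid-z and shrink at the ends (smooth dome
#' profile), so annotating every few slices leaves real interpolation work.
#'
#' @param name `"easy"` or `"hard"`.
#' @param height,width,n_slices volume size.
#' @param seed phantom seed.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(name = c("easy", "hard"), height = 512L,
                           width = 512L, n_slices = 30L, seed = 1L) {
  name <- match.arg(name)
  t <- (seq_len(n_slices) - 0.5) / n_slices
  dome <- 0.85 + 0.15 * sin(pi * t)
  mk <- function(fracs, dens, radii, dot_int, bg, noise) {
    layers <- lapply(seq_along(fracs), function(k)
      layer_spec(label = k, radius_profile = fracs[k] * dome,
                 dot_density = dens[k], dot_radius_px = radii[k],
                 dot_intensity = dot_int, background_intensity = bg,
                 noise_sd = noise))
    phantom_spec(height, width, n_slices, layers, seed = seed,
                 background_intensity = bg, background_noise_sd = noise,
                 label_names = c("GL", "EPL", "ML", "IPL", "GCL"))
  }
  if (name == "easy") {
    mk(fracs = c(0.92, 0.78, 0.64, 0.50, 0.36),
       dens = c(160, 12, 220, 20, 200),
       radii = c(2, 2, 1.2, 3, 1.5),
       dot_int = 0.12, bg = 0.88, noise = 0.03)
  } else {
    mk(fracs = c(0.92, 0.74, 0.68, 0.48, 0.30),
       dens = c(155, 44, 330, 60, 57),
       radii = c(1.5, 2, 1.2, 2, 1.5),
       dot_int = 0.2, bg = 0.80, noise = 0.06)
  }
}

#' Write a phantom to disk
#'
#' Writes the image stack, the ground-truth labels, and a JSON sidecar
#' recording the generating parameters.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed). Writes `image.tif`,
#'   `labels.tif` and `phantom.json`.
#' @return the generated phantom, invisibly.
#' @export
write_phantom <- function(spec, dir) {
  ph <- generate_phantom(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_slice_stack(ph$stack, file.path(dir, "image.tif"))
  write_label_volume(ph$labels, file.path(dir, "labels.tif"))
  side <- list(height = spec$height, width = spec$width,
               n_slices = spec$n_slices, seed = spec$seed,
               background_intensity = spec$background_intensity,
               background_noise_sd = spec$background_noise_sd,
               label_names = spec$scheme$names,
               layers = lapply(spec$layers, function(l) l[names(l) != "class"]))
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ph)
}
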