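#' Slice stacks, label volumes and label schemes
#'
#' `slice_stack()` wraps a z-ordered stack of 2D grayscale slices (e.g. coronal
#' Nissl-stained sections) as a 3D array. `label_volume()` wraps an aligned
#' integer segmentation (0 = background, 1..c = structures) together with the
#' [label_scheme()] naming the structures.
#'
#' Arrays are indexed `[y, x, z]`, 1-based (R convention): `voxels[, , z]` is
#' the z-th coronal slice as a `height x width` matrix with rows running down
#' the image. Intensities are stored in `[0, 1]`; `bit_depth` (8 or 16) fixes
#' the integer encoding used on disk, so write/read round-trips are bit exact.
#'
#' @param voxels numeric array `height x width x n_slices` with values in
#'   `[0, 1]`; a single matrix is promoted to a one-slice stack.
#' @param pixel_size_um positive pixel size in micrometres (isotropic).
#' @param bit_depth integer file encoding, 8 or 16.
#' @return `slice_stack()`: an object of class `slice_stack` with elements
#'   `voxels`, `pixel_size_um`, `bit_depth`.
#' @examples
#' s <- slice_stack(array(runif(4 * 4 * 3), c(4, 4, 3)))
#' n_slices(s)
#' @export
slice_stack <- function(voxels, pixel_size_um = 1, bit_depth = 8L) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a height x width x n_slices array")
  if (dim(voxels)[3] < 1L) stop("a slice stack needs at least one slice")
  if (anyNA(voxels) || min(voxels) < 0 || max(voxels) > 1)
    stop("voxel intensities must lie in [0, 1] with no NA")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth)),
            class = "slice_stack")
}

#' @rdname slice_stack
#' @param x a `slice_stack` or `label_volume`.
#' @export
n_slices <- function(x) {
  if (inherits(x, "slice_stack")) dim(x$voxels)[3]
  else if (inherits(x, "label_volume")) dim(x$labels)[3]
  else stop("`x` must be a slice_stack or label_volume")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<slice_stack> %d x %d px, %d slices, %g um/px, %d-bit\n",
              d[1], d[2], d[3], x$pixel_size_um, x$bit_depth))
  invisible(x)
}

#' Label scheme for the segmented structures
#'
#' Names the `c` anatomical structures encoded as labels `1..c` (0 is always
#' background). [mob_label_scheme()] is the default 10-structure scheme for the
#' mouse main olfactory bulb region: the five concentric laminae (GL, EPL, ML,
#' IPL, GCL) plus AOB, AON, SEZ, aco and lotg.
#'
#' @param names character vector of unique, non-empty structure names
#'   (outer label 1 first).
#' @return an object of class `label_scheme` with elements `c` and `names`.
#' @examples
#' label_scheme(c("ring", "core"))
#' mob_label_scheme()
#' @export
label_scheme <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("a label scheme needs at least one structure")
  if (anyNA(names) || any(!nzchar(names))) stop("structure names must be non-empty")
  if (anyDuplicated(names)) stop("structure names must be unique")
  structure(list(c = length(names), names = names), class = "label_scheme")
}

#' @rdname label_scheme
#' @export
mob_label_scheme <- function() {
  label_scheme(c("GL", "EPL", "ML", "IPL", "GCL",
                 "AOB", "AON", "SEZ", "aco", "lotg"))
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme> c = %d: %s\n", x$c, paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @rdname slice_stack
#' @param labels integer array (or matrix) of the same orientation as
#'   `voxels`, values in `0..scheme$c`.
#' @param scheme a [label_scheme()].
#' @export
label_volume <- function(labels, scheme) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a height x width x n_slices array")
  if (!inherits(scheme, "label_scheme")) stop("`scheme` must be a label_scheme")
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA")
  bad <- labels < 0L | labels > scheme$c
  if (any(bad)) {
    z <- which(apply(bad, 3, any))[1]
    v <- labels[, , z][bad[, , z]][1]
    stop("label value ", v, " on slice ", z, " is outside 0..", scheme$c)
  }
  structure(list(labels = labels, scheme = scheme), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d px, %d slices, c = %d\n",
              d[1], d[2], d[3], x$scheme$c))
  invisible(x)
}

# --- file IO ---------------------------------------------------------------

png_header_info <- function(path) {
  r <- readBin(path, "raw", n = 26L)
  if (length(r) < 26L || any(r[1:4] != as.raw(c(0x89, 0x50, 0x4e, 0x47))))
    stop("not a PNG file: ", path)
  list(bits = as.integer(r[25]), color_type = as.integer(r[26]))
}

read_one_slice_raw <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tf <- read_tiff(path)
    if (length(tf$pages) != 1L)
      stop("expected a single-page TIFF inside a slice directory: ", path)
    list(data = tf$pages[[1]], bits = tf$bits)
  } else if (ext == "png") {
    info <- png_header_info(path)
    if (info$color_type != 0L)
      stop("PNG slice is not single-channel grayscale (RGB/palette/alpha rejected): ", path)
    if (!info$bits %in% c(8L, 16L))
      stop("unsupported PNG bit depth ", info$bits, ": ", path)
    v <- png::readPNG(path)
    if (length(dim(v)) > 2L) stop("multi-channel PNG rejected: ", path)
    list(data = matrix(as.integer(round(v * (2^info$bits - 1))), nrow(v), ncol(v)),
         bits = info$bits)
  } else {
    stop("unsupported slice file type '.", ext, "': ", path)
  }
}

# shared by image and label readers: integer array + bit depth
read_raw_stack <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    if (length(files) == 0L) stop("no PNG/TIFF slices found in directory: ", path)
    files <- files[order(files)]  # lexicographic z order
    slices <- lapply(file.path(path, files), read_one_slice_raw)
    bits <- unique(vapply(slices, `[[`, integer(1), "bits"))
    if (length(bits) != 1L) stop("slices mix bit depths in: ", path)
    shp <- vapply(slices, function(s) dim(s$data), integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
      k <- which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])[1]
      stop("slice '", files[k], "' has shape ", shp[1, k], "x", shp[2, k],
           " but '", files[1], "' has ", shp[1, 1], "x", shp[2, 1])
    }
    arr <- array(0L, c(shp[1, 1], shp[2, 1], length(slices)))
    for (z in seq_along(slices)) arr[, , z] <- slices[[z]]$data
    list(data = arr, bits = bits)
  } else {
    tf <- read_tiff(path)
    shp <- vapply(tf$pages, dim, integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
      k <- which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])[1]
      stop("TIFF page ", k, " has shape ", shp[1, k], "x", shp[2, k],
           " but page 1 has ", shp[1, 1], "x", shp[2, 1])
    }
    arr <- array(0L, c(shp[1, 1], shp[2, 1], length(tf$pages)))
    for (z in seq_along(tf$pages)) arr[, , z] <- tf$pages[[z]]
    list(data = arr, bits = tf$bits)
  }
}

#' Read and write slice stacks
#'
#' A stack lives either in one multi-page TIFF (`.tif`/`.tiff`) or in a
#' directory of single-page TIFF/PNG files, one per slice, ordered
#' lexicographically by filename. Only uncompressed single-channel grayscale
#' data at 8 or 16 bits is supported; RGB input is rejected. Intensities are
#' preserved bit-exactly through a write/read round trip.
#'
#' @param path a `.tif`/`.tiff` file or a slice directory. For
#'   `write_slice_stack()`, a `.tif`/`.tiff` path writes one multi-page TIFF;
#'   any other path is created as a directory of 8-bit PNGs
#'   (`slice_0000.png`, ...).
#' @param pixel_size_um pixel size to record on the returned stack.
#' @return `read_slice_stack()`: a [slice_stack()].
#' @export
read_slice_stack <- function(path, pixel_size_um = 1) {
  rs <- read_raw_stack(path)
  slice_stack(rs$data / (2^rs$bits - 1), pixel_size_um = pixel_size_um,
              bit_depth = rs$bits)
}

#' @rdname read_slice_stack
#' @param stack a [slice_stack()].
#' @export
write_slice_stack <- function(stack, path) {
  if (!inherits(stack, "slice_stack")) stop("`stack` must be a slice_stack")
  maxval <- 2^stack$bit_depth - 1
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[3]), function(z)
    matrix(as.integer(round(stack$voxels[, , z] * maxval)), d[1], d[2]))
  write_pages(pages, path, stack$bit_depth)
  invisible(path)
}

write_pages <- function(pages, path, bits) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write_tiff(pages, path, bits)
  } else {
    if (bits != 8L)
      stop("PNG slice directories support 8-bit data only; use a .tif path")
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (z in seq_along(pages)) {
      png::writePNG(pages[[z]] / 255,
                    file.path(path, sprintf("slice_%04d.png", z - 1L)))
    }
  }
  invisible(path)
}

#' Read and write label volumes
#'
#' Label maps are stored as raw integer values (not intensity-scaled): an
#' 8-bit TIFF stack or PNG directory whose pixel values are the structure
#' labels `0..c` directly.
#'
#' @inheritParams read_slice_stack
#' @param scheme a [label_scheme()]; values above `scheme$c` are an error.
#' @return `read_label_volume()`: a [label_volume()].
#' @export
read_label_volume <- function(path, scheme) {
  rs <- read_raw_stack(path)
  bad <- rs$data > scheme$c
  if (any(bad)) {
    z <- which(apply(bad, 3, any))[1]
    v <- rs$data[, , z][bad[, , z]][1]
    stop("label value ", v, " on slice ", z, " exceeds scheme c = ", scheme$c)
  }
  label_volume(rs$data, scheme)
}

#' @rdname read_label_volume
#' @param labels a [label_volume()].
#' @export
write_label_volume <- function(labels, path) {
  if (!inherits(labels, "label_volume")) stop("`labels` must be a label_volume")
  if (labels$scheme$c > 255L) stop("label schemes with c > 255 are not storable as 8-bit")
  d <- dim(labels$labels)
  pages <- lapply(seq_len(d[3]), function(z) labels$labels[, , z])
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff(pages, path, 8L)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (z in seq_along(pages)) {
      png::writePNG(pages[[z]] / 255,
                    file.path(path, sprintf("slice_%04d.png", z - 1L)))
    }
  }
  invisible(path)
}
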