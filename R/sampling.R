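#' Patch sets
#'
#' A `patch_set` is the in-memory collection of square patch samples used for
#' training or prediction: per-sample center coordinates, source slice index,
#' optional center labels, and references to the source slice images. Patch
#' pixels are materialized lazily ([patch_pixels()], or in bulk during
#' classifier preprocessing), so a hundred thousand 800 x 800 patches never
#' exist at once.
#'
#' @param centers integer `n x 2` matrix of (row, col) patch centers, 1-based.
#' @param slice_index integer vector (length 1 or n) of source slice indices.
#' @param p patch side, px. The center pixel sits at patch position
#'   `(p %/% 2, p %/% 2)` (0-based), so even `p` is well defined.
#' @param images named list mapping slice index (as character) to its
#'   grayscale matrix.
#' @param labels optional integer center labels in `1..c` (training patches).
#' @return an object of class `patch_set`.
#' @export
patch_set <- function(centers, slice_index, p, images, labels = NULL) {
  centers <- matrix(as.integer(centers), ncol = 2)
  n <- nrow(centers)
  slice_index <- as.integer(slice_index)
  if (length(slice_index) == 1L) slice_index <- rep(slice_index, n)
  if (length(slice_index) != n) stop("`slice_index` must have length 1 or n")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("`labels` must have one entry per sample")
    if (any(labels < 1L)) stop("training patch labels must be >= 1 (no background class)")
  }
  structure(list(centers = centers, slice_index = slice_index,
                 labels = labels, p = as.integer(p), images = images),
            class = "patch_set")
}

#' @rdname patch_set
#' @param ps a `patch_set`.
#' @export
n_patches <- function(ps) nrow(ps$centers)

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d px from %d slice(s)%s\n",
              n_patches(x), x$p, x$p, length(x$images),
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

#' @rdname patch_set
#' @param i sample index.
#' @return `patch_pixels()`: the `p x p` pixel matrix of sample `i`.
#' @export
patch_pixels <- function(ps, i) {
  img <- ps$images[[as.character(ps$slice_index[i])]]
  extract_patch(img, ps$centers[i, ], ps$p)
}

subset_patch_set <- function(ps, idx) {
  keep <- unique(as.character(ps$slice_index[idx]))
  patch_set(ps$centers[idx, , drop = FALSE], ps$slice_index[idx], ps$p,
            ps$images[keep], labels = ps$labels[idx])
}

#' @rdname patch_set
#' @param sets list of `patch_set`s sharing one patch size.
#' @export
combine_patch_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  p <- unique(vapply(sets, `[[`, integer(1), "p"))
  if (length(p) != 1L) stop("patch sets have different patch sizes")
  has_lab <- vapply(sets, function(s) !is.null(s$labels), logical(1))
  if (!all(has_lab) && any(has_lab)) stop("cannot mix labelled and unlabelled patch sets")
  images <- do.call(c, lapply(sets, `[[`, "images"))
  images <- images[!duplicated(names(images))]
  patch_set(do.call(rbind, lapply(sets, `[[`, "centers")),
            do.call(c, lapply(sets, `[[`, "slice_index")),
            p, images,
            labels = if (all(has_lab)) do.call(c, lapply(sets, `[[`, "labels")))
}

#' Extract one patch
#'
#' Cuts the `p x p` window centered at `center_yx` from a slice;
#' out-of-bounds pixels are filled by reflect padding (mirror without
#' repeating the edge pixel), so patches near the border stay valid and thin
#' peripheral layers are not under-sampled.
#'
#' @param slice grayscale matrix.
#' @param center_yx integer (row, col), 1-based, inside the slice.
#' @param p patch side.
#' @return `p x p` numeric matrix.
#' @export
extract_patch <- function(slice, center_yx, p) {
  cy <- as.integer(center_yx[1]); cx <- as.integer(center_yx[2])
  if (cy < 1L || cy > nrow(slice) || cx < 1L || cx > ncol(slice))
    stop("patch center (", cy, ", ", cx, ") lies outside the slice")
  if (p < 1L) stop("`p` must be >= 1")
  cpp_extract_patch(slice, cy, cx, as.integer(p))
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Sample labelled training patches from an annotated slice
#'
#' Draws `m` patch centers uniformly with replacement from the labelled
#' (undilated) pixels of the annotation; each sample carries the annotation
#' value at its center. Centers are restricted to labelled pixels because the
#' classifier has one output per structure and no background class.
#'
#' @param slice grayscale matrix.
#' @param annotation integer label matrix aligned with `slice`.
#' @param m number of patches.
#' @param p patch side.
#' @param slice_index slice z-index recorded on the samples.
#' @param seed optional integer seed (NULL = current RNG state).
#' @return a labelled [patch_set()].
#' @export
sample_training_patches <- function(slice, annotation, m, p, slice_index = 1L,
                                    seed = NULL) {
  eligible <- which(annotation > 0L)
  if (length(eligible) == 0L)
    stop("annotation of slice ", slice_index, " is all background; cannot sample training patches")
  idx <- with_seed(seed, eligible[sample.int(length(eligible), m, replace = TRUE)])
  H <- nrow(annotation)
  centers <- cbind(((idx - 1L) %% H) + 1L, ((idx - 1L) %/% H) + 1L)
  images <- stats::setNames(list(slice), as.character(slice_index))
  patch_set(centers, slice_index, p, images, labels = annotation[idx])
}

#' Random train/validation split of a patch set
#'
#' @param ps a [patch_set()].
#' @param train_fraction fraction assigned to training,
#'   `round(train_fraction * n)` samples (70/30 by default downstream).
#' @param seed optional integer seed.
#' @return list with labelled patch sets `train` and `val` partitioning `ps`.
#' @export
split_train_val <- function(ps, train_fraction, seed = NULL) {
  n <- n_patches(ps)
  if (n < 2L) stop("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly between 0 and 1")
  n_train <- round(train_fraction * n)
  if (n_train < 1L || n_train >= n)
    stop("split leaves an empty partition (n = ", n, ", fraction = ", train_fraction, ")")
  perm <- with_seed(seed, sample.int(n))
  list(train = subset_patch_set(ps, sort(perm[seq_len(n_train)])),
       val = subset_patch_set(ps, sort(perm[(n_train + 1L):n])))
}

#' Sample unlabelled prediction patches inside a foreground mask
#'
#' Draws `m` centers uniformly with replacement over the slice's initial
#' foreground (the dilated/interpolated localization mask).
#'
#' @param slice grayscale matrix.
#' @param foreground logical mask aligned with `slice`.
#' @inheritParams sample_training_patches
#' @return an unlabelled [patch_set()].
#' @export
sample_prediction_patches <- function(slice, foreground, m, p, slice_index = 1L,
                                      seed = NULL) {
  eligible <- which(foreground)
  if (length(eligible) == 0L)
    stop("initial foreground of slice ", slice_index, " is empty; cannot sample prediction patches")
  idx <- with_seed(seed,
                   if (m > 0) eligible[sample.int(length(eligible), m, replace = TRUE)]
                   else integer(0))
  H <- nrow(slice)
  centers <- cbind(((idx - 1L) %% H) + 1L, ((idx - 1L) %/% H) + 1L)
  images <- stats::setNames(list(slice), as.character(slice_index))
  patch_set(centers, slice_index, p, images)
}
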