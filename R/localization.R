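#' Split slices into training and predicting sets
#'
#' Picks every `interval_n`-th slice (starting at slice 1) as a training
#' slice to be annotated manually; all remaining slices are predicting slices.
#' With 2900 slices and an interval of 100 this yields 29 training slices.
#'
#' @param n_slices total slice count.
#' @param interval_n annotation interval, `1 <= interval_n < n_slices`.
#' @return object of class `slice_split`: list with `training_indices`,
#'   `predicting_indices` (1-based, disjoint, covering all slices) and
#'   `interval_n`.
#' @examples
#' split_slices(7, 3)
#' @export
split_slices <- function(n_slices, interval_n) {
  n_slices <- as.integer(n_slices); interval_n <- as.integer(interval_n)
  if (n_slices < 1L) stop("`n_slices` must be >= 1")
  if (interval_n < 1L || interval_n >= n_slices)
    stop("`interval_n` must satisfy 1 <= interval_n < n_slices (got ",
         interval_n, " for ", n_slices, " slices)")
  tc <- seq.int(1L, n_slices, by = interval_n)
  if (length(tc) > 100L)
    warning("more than 100 training slices (", length(tc),
            "); the workflow is designed for sparse annotation")
  structure(list(training_indices = tc,
                 predicting_indices = setdiff(seq_len(n_slices), tc),
                 interval_n = interval_n),
            class = "slice_split")
}

#' @export
print.slice_split <- function(x, ...) {
  cat(sprintf("<slice_split> interval %d: %d training, %d predicting slices\n",
              x$interval_n, length(x$training_indices), length(x$predicting_indices)))
  invisible(x)
}

#' Initial foreground of an annotated slice
#'
#' Binarizes an annotation (any structure label vs background) and applies a
#' morphological dilation with a disc structuring element, producing the
#' margin inside which prediction patches will later be sampled. The dilation
#' uses the exact Euclidean distance transform, so a pixel is foreground iff
#' its distance to a labelled pixel is `<= dilation_radius`.
#'
#' @param annotation integer label matrix (0 background).
#' @param dilation_radius disc radius in px; 0 returns the plain binarization.
#' @return logical matrix.
#' @export
annotation_foreground <- function(annotation, dilation_radius) {
  if (dilation_radius < 0) stop("`dilation_radius` must be non-negative")
  bin <- annotation > 0
  if (dilation_radius == 0 || !any(bin)) return(bin)
  d2 <- cpp_edt_sq(matrix(as.integer(bin), nrow(bin), ncol(bin)))
  d2 <= dilation_radius^2
}

#' Nearest-neighbour interpolation of foreground masks
#'
#' Produces the initial foreground for the slices strictly between two
#' annotated slices that are `interval_n` apart: intermediate slice `k`
#' (1-based, `k` in `1..interval_n - 1`) copies the earlier mask when
#' `k <= interval_n / 2` (midpoint ties go to the earlier slice) and the later
#' mask otherwise. Nearest-neighbour never blends: every output equals one of
#' the two inputs.
#'
#' @param fg_a,fg_b logical masks of the two annotated slices (same shape).
#' @param interval_n slice interval between the annotated pair.
#' @return list of `interval_n - 1` logical masks.
#' @export
interpolate_foreground <- function(fg_a, fg_b, interval_n) {
  if (!all(dim(fg_a) == dim(fg_b))) stop("foreground masks differ in shape")
  interval_n <- as.integer(interval_n)
  if (interval_n < 1L) stop("`interval_n` must be >= 1")
  if (interval_n == 1L) return(list())
  lapply(seq_len(interval_n - 1L), function(k)
    if (k <= interval_n / 2) fg_a else fg_b)
}

#' Initial foreground volume from sparse annotations
#'
#' Training slices receive the dilated foreground of their own annotation;
#' every predicting slice copies the foreground of its nearest training slice
#' (midpoint ties go to the earlier slice; slices after the last training
#' slice reuse the last training foreground).
#'
#' @param split a [split_slices()] result.
#' @param annotations named list mapping training slice index (as character)
#'   to its integer annotation matrix.
#' @param dilation_radius disc radius passed to [annotation_foreground()].
#' @return logical array `height x width x n_slices`.
#' @export
build_initial_foreground <- function(split, annotations, dilation_radius) {
  tc <- split$training_indices
  missing_tc <- tc[!as.character(tc) %in% names(annotations)]
  if (length(missing_tc) > 0L)
    stop("missing annotation for training slice(s): ",
         paste(missing_tc, collapse = ", "))
  fgs <- lapply(tc, function(z)
    annotation_foreground(annotations[[as.character(z)]], dilation_radius))
  shp <- dim(fgs[[1]])
  nz <- max(c(tc, split$predicting_indices))
  out <- array(FALSE, c(shp, nz))
  for (z in seq_len(nz)) {
    dist <- abs(tc - z)
    nearest <- which(dist == min(dist))[1]  # tie -> earlier training slice
    out[, , z] <- fgs[[nearest]]
  }
  out
}
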