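#' Sparse map of one-hot patch predictions
#'
#' Deposits each prediction's one-hot vote at its center pixel of a c-channel
#' per-slice accumulator (the sparse map SM): channel k is incremented at the
#' center of every patch classified as structure k. Repeated centers
#' accumulate, so the map holds local vote mass, not just presence.
#'
#' @param predictions a `patch_predictions` object (see [predict_batch()]).
#' @param shape integer (height, width) of the slice.
#' @param c number of structures (channels).
#' @return object of class `sparse_map`: list with `counts`
#'   (`height x width x c` integer array) and `n_filled`.
#' @export
build_sparse_map <- function(predictions, shape, c = predictions$c) {
  stopifnot(inherits(predictions, "patch_predictions"))
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  ctr <- predictions$centers
  if (nrow(ctr) > 0L &&
      (min(ctr[, 1]) < 1L || max(ctr[, 1]) > H ||
       min(ctr[, 2]) < 1L || max(ctr[, 2]) > W))
    stop("prediction center outside the slice (", H, " x ", W, ")")
  counts <- array(0L, c(H, W, c))
  for (k in seq_len(c)) {
    sel <- predictions$class_idx == k
    if (!any(sel)) next
    lin <- (ctr[sel, 2] - 1L) * H + ctr[sel, 1]
    counts[, , k] <- matrix(tabulate(lin, nbins = H * W), H, W)
  }
  structure(list(counts = counts, n_filled = nrow(ctr)), class = "sparse_map")
}

# Exact zero-padded w x w window sum of a single-channel count matrix via a
# padded integral image; integer-valued inputs make the cumulative sums exact.
window_sum <- function(M, w) {
  H <- nrow(M); W <- ncol(M)
  h <- (w - 1L) %/% 2L
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(M, 2L, cumsum), 1L, cumsum) |> t()
  y1 <- pmax(seq_len(H) - h - 1L, 0L); y2 <- pmin(seq_len(H) + h, H)
  x1 <- pmax(seq_len(W) - h - 1L, 0L); x2 <- pmin(seq_len(W) + h, W)
  S[y2 + 1L, x2 + 1L, drop = FALSE] - S[y1 + 1L, x2 + 1L, drop = FALSE] -
    S[y2 + 1L, x1 + 1L, drop = FALSE] + S[y1 + 1L, x1 + 1L, drop = FALSE]
}

#' Signal-density scan of a sparse map
#'
#' Slides a `w x w` window (default 51, i.e. offsets -25..25 around each
#' pixel) over every channel of the sparse map and records the window sum of
#' votes, zero-padded at the borders. The sum is used directly as the
#' per-pixel class confidence: it differs from the window's average only by
#' the constant factor w^2, which cannot change any argmax.
#'
#' @param sm a [build_sparse_map()] result.
#' @param w odd window side.
#' @return object of class `confidence_maps`: list with `density`
#'   (`height x width x c` numeric array) and `window_w`.
#' @export
density_scan <- function(sm, w) {
  stopifnot(inherits(sm, "sparse_map"))
  w <- as.integer(w)
  if (w < 1L) stop("`w` must be >= 1")
  if (w %% 2L == 0L) stop("`w` must be odd so the window has a unique center")
  d <- dim(sm$counts)
  density <- array(0, d)
  for (k in seq_len(d[3])) density[, , k] <- window_sum(sm$counts[, , k], w)
  structure(list(density = density, window_w = w), class = "confidence_maps")
}

#' Per-pixel argmax labelling of the confidence maps
#'
#' Inside the foreground, each pixel takes `1 +` the channel with the highest
#' confidence (ties toward the lowest channel, i.e. the lowest structure id).
#' Pixels outside the foreground, or whose confidence is zero on every
#' channel (no evidence), become background.
#'
#' @param conf a [density_scan()] result.
#' @param foreground logical mask matching the slice shape.
#' @return integer label matrix (the rough segmentation result).
#' @export
assign_labels <- function(conf, foreground) {
  stopifnot(inherits(conf, "confidence_maps"))
  d <- dim(conf$density)
  if (!all(dim(foreground) == d[1:2]))
    stop("foreground shape does not match the confidence maps")
  flat <- matrix(conf$density, d[1] * d[2], d[3])
  best <- max.col(flat, ties.method = "first")
  mx <- flat[cbind(seq_len(nrow(flat)), best)]
  lab <- ifelse(as.vector(foreground) & mx > 0, best, 0L)
  matrix(as.integer(lab), d[1], d[2])
}

component_neighbor_label <- function(labels, pix_y, pix_x, own) {
  H <- nrow(labels); W <- ncol(labels)
  cnt <- integer(max(labels) + 1L)  # index = label + 1
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    yy <- pix_y + dy; xx <- pix_x + dx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    if (!any(ok)) next
    nb <- labels[cbind(yy[ok], xx[ok])]
    nb <- nb[nb != own]
    if (length(nb) > 0L) {
      t <- tabulate(nb + 1L, nbins = length(cnt))
      cnt <- cnt + t
    }
  }
  structure_cnt <- cnt[-1L]  # labels 1..c
  if (any(structure_cnt > 0L)) {
    which.max(structure_cnt)  # ties -> lowest structure id
  } else {
    0L  # background is the only neighbour
  }
}

#' Reassign small connected components
#'
#' For every structure, 8-connected components whose area falls below
#' `min_fraction` of that structure's largest component are treated as false
#' positives and relabelled to the neighbouring structure sharing the longest
#' 8-connected boundary with the component (ties toward the lowest structure
#' id; background only if it is the only neighbour). Component statistics are
#' taken on the input and all reassignments applied in one pass.
#'
#' @param rr integer label matrix (rough result).
#' @param min_fraction threshold in `[0, 1)`.
#' @return integer label matrix.
#' @export
reassign_small_components <- function(rr, min_fraction) {
  if (min_fraction < 0 || min_fraction >= 1) stop("`min_fraction` must lie in [0, 1)")
  out <- rr
  H <- nrow(rr)
  for (s in sort(unique(rr[rr > 0L]))) {
    comp <- cpp_label_components(matrix(as.integer(rr == s), H, ncol(rr)))
    ncomp <- max(comp)
    if (ncomp <= 1L) next
    areas <- tabulate(comp[comp > 0L], nbins = ncomp)
    cutoff <- min_fraction * max(areas)
    for (ci in which(areas < cutoff)) {
      idx <- which(comp == ci)
      pix_y <- ((idx - 1L) %% H) + 1L
      pix_x <- ((idx - 1L) %/% H) + 1L
      out[idx] <- component_neighbor_label(rr, pix_y, pix_x, s)
    }
  }
  out
}

#' Reconstruct a dense annotation for one predicting slice
#'
#' The full sparse-to-dense chain: sample `m` prediction patches inside the
#' slice's initial foreground, classify them, accumulate the one-hot votes
#' into the sparse map, run the `w x w` signal-density scan, take the
#' per-pixel argmax, and clean up small components.
#'
#' @param slice grayscale matrix.
#' @param foreground logical initial-foreground mask.
#' @param model classifier (`classifier_model` or [oracle_classifier()]).
#' @param m number of prediction patches.
#' @param p patch side.
#' @param w density window side (odd).
#' @param min_fraction small-component threshold (see
#'   [reassign_small_components()]).
#' @param slice_index slice z-index (for sampling records and error messages).
#' @param seed optional integer seed for the patch sampling.
#' @return integer label matrix.
#' @export
reconstruct_slice <- function(slice, foreground, model, m, p, w,
                              min_fraction = 0.05, slice_index = 1L,
                              seed = NULL) {
  if (m == 0L) {
    warning("m = 0 prediction patches for slice ", slice_index,
            "; returning an all-background annotation")
    return(matrix(0L, nrow(slice), ncol(slice)))
  }
  ps <- sample_prediction_patches(slice, foreground, m, p,
                                  slice_index = slice_index, seed = seed)
  pred <- predict_batch(model, ps)
  sm <- build_sparse_map(pred, dim(slice))
  conf <- density_scan(sm, w)
  rr <- assign_labels(conf, foreground)
  reassign_small_components(rr, min_fraction)
}

#' Assemble the final label volume
#'
#' Interleaves the manual training annotations (carried over verbatim) with
#' the reconstructed predicting annotations in slice order.
#'
#' @param split a [split_slices()] result.
#' @param training_annotations named list (slice index as character ->
#'   integer label matrix) covering every training slice.
#' @param predicted same, covering every predicting slice.
#' @param scheme the [label_scheme()] of the output volume.
#' @return a [label_volume()].
#' @export
assemble_volume <- function(split, training_annotations, predicted, scheme) {
  all_idx <- sort(c(split$training_indices, split$predicting_indices))
  have <- c(stats::setNames(training_annotations, names(training_annotations)),
            stats::setNames(predicted, names(predicted)))
  missing_z <- all_idx[!as.character(all_idx) %in% names(have)]
  if (length(missing_z) > 0L)
    stop("no annotation provided for slice(s): ", paste(missing_z, collapse = ", "))
  dup <- intersect(names(training_annotations), names(predicted))
  if (length(dup) > 0L)
    stop("slice(s) provided both as training and predicted: ",
         paste(dup, collapse = ", "))
  shp <- dim(have[[1]])
  out <- array(0L, c(shp, length(all_idx)))
  for (z in all_idx) out[, , z] <- have[[as.character(z)]]
  label_volume(out, scheme)
}
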