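#' Overlap scores for one structure
#'
#' Dice similarity coefficient, precision and recall of a predicted binary
#' mask A against a ground-truth mask B:
#' DSC = 2|A∩B| / (|A| + |B|), precision = |A∩B| / |A|,
#' recall = |A∩B| / |B|.
#'
#' Empty-mask conventions (so structures absent from a slice do not poison
#' aggregates): both masks empty — all three scores are 1; prediction empty
#' but truth nonempty — DSC 0, precision 1, recall 0; prediction nonempty but
#' truth empty — DSC 0, precision 0, recall 1.
#'
#' @param pred_mask,gt_mask logical (or 0/1) matrices of equal shape.
#' @return a one-row tibble with `dsc`, `precision`, `recall`, `n_pred_px`,
#'   `n_gt_px`, `n_overlap_px`.
#' @examples
#' a <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2)
#' b <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0), 2)
#' score_structure(a, b)  # dsc 2*2/6, precision 0.5, recall 1
#' @export
score_structure <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask)))
    stop("prediction and ground-truth masks differ in shape")
  a <- pred_mask > 0; b <- gt_mask > 0
  na <- sum(a); nb <- sum(b); nab <- sum(a & b)
  if (na == 0 && nb == 0) {
    dsc <- 1; prec <- 1; rec <- 1
  } else {
    dsc <- 2 * nab / (na + nb)
    prec <- if (na > 0) nab / na else 1
    rec <- if (nb > 0) nab / nb else 1
  }
  tibble::tibble(dsc = dsc, precision = prec, recall = rec,
                 n_pred_px = na, n_gt_px = nb, n_overlap_px = nab)
}

#' Evaluate a segmentation volume against ground truth
#'
#' Binarizes each structure on each listed slice and scores it with
#' [score_structure()]. Aggregation mirrors the usual reporting layout:
#' per-structure mean and sample sd over the listed slices, then a grand mean
#' (and sd) over the structure means. Structures empty in the ground truth on
#' every listed slice are scored under the empty-mask conventions and flagged.
#'
#' @param pred,gt aligned [label_volume()]s sharing one label scheme size.
#' @param slices slice indices to evaluate (e.g. the predicted slices).
#' @return object of class `segmentation_eval`: list of tibbles `detail`
#'   (one row per structure x slice), `by_structure` (mean/sd per metric,
#'   plus `flag` for degenerate cases) and `overall` (grand mean/sd over
#'   structure means).
#' @export
evaluate_volume <- function(pred, gt, slices) {
  stopifnot(inherits(pred, "label_volume"), inherits(gt, "label_volume"))
  if (!all(dim(pred$labels) == dim(gt$labels)))
    stop("prediction and ground-truth volumes differ in shape")
  if (length(slices) == 0L) stop("`slices` must list at least one slice")
  scheme <- gt$scheme
  rows <- list()
  for (s in seq_len(scheme$c)) {
    for (z in slices) {
      sc <- score_structure(pred$labels[, , z] == s, gt$labels[, , z] == s)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(structure_id = s, structure = scheme$names[s],
                       slice = as.integer(z), sc)
    }
  }
  detail <- do.call(rbind, rows)
  single <- length(slices) == 1L
  by_structure <- do.call(rbind, lapply(seq_len(scheme$c), function(s) {
    d <- detail[detail$structure_id == s, ]
    gt_absent <- all(d$n_gt_px == 0)
    tibble::tibble(
      structure_id = s, structure = scheme$names[s],
      mean_dsc = mean(d$dsc), sd_dsc = if (single) 0 else stats::sd(d$dsc),
      mean_precision = mean(d$precision),
      sd_precision = if (single) 0 else stats::sd(d$precision),
      mean_recall = mean(d$recall),
      sd_recall = if (single) 0 else stats::sd(d$recall),
      flag = paste(c(if (gt_absent) "absent_in_gt",
                     if (single) "single_slice"), collapse = ";"))
  }))
  overall <- tibble::tibble(
    mean_dsc = mean(by_structure$mean_dsc),
    sd_dsc = if (scheme$c == 1L) 0 else stats::sd(by_structure$mean_dsc),
    mean_precision = mean(by_structure$mean_precision),
    sd_precision = if (scheme$c == 1L) 0 else stats::sd(by_structure$mean_precision),
    mean_recall = mean(by_structure$mean_recall),
    sd_recall = if (scheme$c == 1L) 0 else stats::sd(by_structure$mean_recall))
  structure(list(detail = detail, by_structure = by_structure, overall = overall),
            class = "segmentation_eval")
}

#' @export
print.segmentation_eval <- function(x, ...) {
  cat("<segmentation_eval>\n")
  o <- x$overall
  cat(sprintf("  mean DSC %.3f +/- %.3f | precision %.3f +/- %.3f | recall %.3f +/- %.3f\n",
              o$mean_dsc, o$sd_dsc, o$mean_precision, o$sd_precision,
              o$mean_recall, o$sd_recall))
  b <- x$by_structure
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-6s DSC %.3f +/- %.3f%s\n", b$structure[i], b$mean_dsc[i],
                b$sd_dsc[i], if (nzchar(b$flag[i])) paste0("  [", b$flag[i], "]") else ""))
  invisible(x)
}

#' Export an evaluation report as CSV
#'
#' One file holding the detail rows (one per structure x slice) followed by
#' the per-structure summary and the grand mean, distinguished by a `kind`
#' column (`detail`, `structure_mean`, `grand_mean`).
#'
#' @param eval a [evaluate_volume()] result.
#' @param path output CSV path.
#' @export
export_report <- function(eval, path) {
  stopifnot(inherits(eval, "segmentation_eval"))
  d <- eval$detail
  detail <- data.frame(kind = "detail", structure = d$structure,
                       slice = d$slice, dsc = d$dsc, precision = d$precision,
                       recall = d$recall, sd_dsc = NA_real_,
                       sd_precision = NA_real_, sd_recall = NA_real_,
                       flag = "")
  b <- eval$by_structure
  bs <- data.frame(kind = "structure_mean", structure = b$structure,
                   slice = NA_integer_, dsc = b$mean_dsc,
                   precision = b$mean_precision, recall = b$mean_recall,
                   sd_dsc = b$sd_dsc, sd_precision = b$sd_precision,
                   sd_recall = b$sd_recall, flag = b$flag)
  o <- eval$overall
  gr <- data.frame(kind = "grand_mean", structure = "all", slice = NA_integer_,
                   dsc = o$mean_dsc, precision = o$mean_precision,
                   recall = o$mean_recall, sd_dsc = o$sd_dsc,
                   sd_precision = o$sd_precision, sd_recall = o$sd_recall,
                   flag = "")
  utils::write.csv(rbind(detail, bs, gr), path, row.names = FALSE)
  invisible(path)
}
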