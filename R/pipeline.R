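# Orchestration of the two-phase workflow: train (sparse annotation ->
# patch sampling -> classifier) and predict (initial foreground ->
# per-slice reconstruction -> assembled volume), plus the parameter sweeps.

as_annotation_list <- function(annotations, split) {
  tc <- split$training_indices
  if (inherits(annotations, "label_volume")) {
    out <- stats::setNames(
      lapply(tc, function(z) annotations$labels[, , z]), as.character(tc))
    return(out)
  }
  if (!is.list(annotations) || is.null(names(annotations)))
    stop("`annotations` must be a label_volume or a named list keyed by slice index")
  missing_tc <- tc[!as.character(tc) %in% names(annotations)]
  if (length(missing_tc) > 0L)
    stop("missing annotation for training slice(s): ",
         paste(missing_tc, collapse = ", "))
  annotations[as.character(tc)]
}

merge_classifier_config <- function(config, n_train_override = NULL) {
  defaults <- list(c = config$scheme$c,
                   input_downsample_d = config$input_downsample_d,
                   seed = derive_seed(config$seed, "train_init"))
  do.call(classifier_config, utils::modifyList(defaults, config$classifier))
}

#' Run the training phase
#'
#' Splits the stack into training/predicting slices, samples
#' `train_patches_total` labelled patches across the training slices
#' (uniformly with replacement from each slice's labelled pixels), performs
#' the 70/30 train/validation split, and trains the patch classifier.
#'
#' @param config a [pipeline_config()].
#' @param stack a [slice_stack()].
#' @param annotations a [label_volume()] (only training slices are read) or a
#'   named list mapping training slice index to its label matrix.
#' @return a `classifier_model`; attribute `"manifest"` records the split and
#'   per-slice sample counts.
#' @export
run_train <- function(config, stack, annotations) {
  stopifnot(inherits(config, "pipeline_config"), inherits(stack, "slice_stack"))
  split <- split_slices(n_slices(stack), config$slice_interval_n)
  ann <- as_annotation_list(annotations, split)
  tc <- split$training_indices
  ntc <- length(tc)
  m_per <- rep(config$train_patches_total %/% ntc, ntc)
  extra <- config$train_patches_total %% ntc
  if (extra > 0L) m_per[seq_len(extra)] <- m_per[seq_len(extra)] + 1L
  sets <- vector("list", ntc)
  for (i in seq_len(ntc)) {
    z <- tc[i]
    a <- ann[[as.character(z)]]
    if (!any(a > 0L))
      stop("run_train: annotation of training slice ", z, " is all background")
    sets[[i]] <- sample_training_patches(
      stack$voxels[, , z], a, m_per[i], config$patch_size_p,
      slice_index = z, seed = derive_seed(config$seed, "train_sample", z))
  }
  all_ps <- combine_patch_sets(sets)
  sv <- split_train_val(all_ps, 0.7, seed = derive_seed(config$seed, "train_val"))
  model <- train_classifier(sv$train, sv$val, merge_classifier_config(config))
  attr(model, "manifest") <- list(
    split = split,
    samples_per_slice = stats::setNames(m_per, as.character(tc)),
    n_train = n_patches(sv$train), n_val = n_patches(sv$val),
    seed = config$seed)
  model
}

#' Run the predicting phase
#'
#' Builds the initial foreground volume from the dilated training annotations
#' (nearest-neighbour interpolated onto the predicting slices), reconstructs
#' every predicting slice with [reconstruct_slice()], and assembles the final
#' volume in which training slices carry their manual annotations verbatim.
#' Per-slice RNG streams derive from the master seed by slice index, so
#' slices can be processed in any order with identical results.
#'
#' @inheritParams run_train
#' @param model classifier from [run_train()] (or an [oracle_classifier()]).
#' @return a [label_volume()]; attribute `"run_log"` holds the config
#'   snapshot and per-slice sampling records.
#' @export
run_predict <- function(config, stack, annotations, model) {
  stopifnot(inherits(config, "pipeline_config"), inherits(stack, "slice_stack"))
  if (inherits(model, "classifier_model") && model$config$c != config$scheme$c)
    stop("model has ", model$config$c, " outputs but the label scheme has ",
         config$scheme$c, " structures")
  split <- split_slices(n_slices(stack), config$slice_interval_n)
  ann <- as_annotation_list(annotations, split)
  fg <- build_initial_foreground(split, ann, config$dilation_radius)
  predicted <- list()
  log_rows <- list()
  for (z in split$predicting_indices) {
    seed_z <- derive_seed(config$seed, "predict_sample", z)
    lab <- reconstruct_slice(stack$voxels[, , z], fg[, , z], model,
                             m = config$predict_patches_per_slice,
                             p = config$patch_size_p,
                             w = config$density_window_w,
                             min_fraction = config$min_component_fraction,
                             slice_index = z, seed = seed_z)
    predicted[[as.character(z)]] <- lab
    log_rows[[as.character(z)]] <- list(
      slice = z, seed = seed_z,
      n_sampled = config$predict_patches_per_slice,
      n_per_class = as.list(stats::setNames(
        tabulate(lab[lab > 0L], nbins = config$scheme$c), config$scheme$names)))
  }
  vol <- assemble_volume(split, ann, predicted, config$scheme)
  attr(vol, "run_log") <- list(
    config = unclass(config)[setdiff(names(config), "scheme")],
    slices = log_rows)
  vol
}

#' Sweep a pipeline parameter
#'
#' Reproduces the receptive-field and patch-number experiments at any scale:
#' for `patch_size_p` the classifier is retrained per value (the receptive
#' field changes its input); for `predict_patches_per_slice` one model is
#' trained and reused across values. Each run shares the master seed; the
#' predicted slices are scored against ground truth.
#'
#' @inheritParams run_train
#' @param gt ground-truth [label_volume()] for scoring.
#' @param param `"patch_size_p"` or `"predict_patches_per_slice"`.
#' @param values at least two parameter values.
#' @return tibble with one row per value: `value`, `mean_dsc`,
#'   `predict_time_s`.
#' @export
run_sweep <- function(config, stack, annotations, gt, param, values) {
  param <- match.arg(param, c("patch_size_p", "predict_patches_per_slice"))
  if (length(values) < 2L) stop("a sweep needs at least 2 values")
  split <- split_slices(n_slices(stack), config$slice_interval_n)
  shared_model <- NULL
  if (param == "predict_patches_per_slice")
    shared_model <- run_train(config, stack, annotations)
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg[[param]] <- as.integer(v)
    model <- if (is.null(shared_model)) run_train(cfg, stack, annotations) else shared_model
    t0 <- proc.time()[["elapsed"]]
    vol <- run_predict(cfg, stack, annotations, model)
    dt <- proc.time()[["elapsed"]] - t0
    ev <- evaluate_volume(vol, gt, split$predicting_indices)
    tibble::tibble(value = as.integer(v), mean_dsc = ev$overall$mean_dsc,
                   predict_time_s = dt)
  })
  do.call(rbind, rows)
}
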