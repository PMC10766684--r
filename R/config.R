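#' Pipeline configuration
#'
#' Collects every tunable of the train/predict workflow. Defaults are the
#' full-scale operating point used on 1 um/px Nissl-stained coronal stacks:
#' annotate every 100th slice, 800 x 800 px patches downsampled to 100 x 100
#' for the classifier, 220,000 training patches in total, 100,000 prediction
#' patches per slice, a 51 x 51 px density window, and a 50 px dilation margin
#' around the annotated structures. Desk-scale runs (tests, phantoms) override
#' these; see the methods vignette.
#'
#' @param slice_interval_n annotate every n-th slice (training slices).
#' @param patch_size_p side of the square patch fed to the classifier, px
#'   (the classifier's receptive field in the raw image).
#' @param input_downsample_d classifier input resolution after area
#'   downsampling, px.
#' @param train_patches_total total number of labelled training patches,
#'   spread over the training slices.
#' @param predict_patches_per_slice random patches classified per predicted
#'   slice.
#' @param density_window_w odd side of the signal-density scan window, px.
#' @param dilation_radius disc radius (px) for the morphological expansion of
#'   the annotated foreground.
#' @param min_component_fraction connected components of a structure smaller
#'   than this fraction of its largest component are reassigned.
#' @param seed master seed; every random draw in a run derives from it.
#' @param label_names structure names (defines the label scheme).
#' @param classifier list of [classifier_config()] overrides (e.g.
#'   `list(learning_rate = 1e-3)`).
#' @return an object of class `pipeline_config`.
#' @examples
#' pipeline_config(slice_interval_n = 5, patch_size_p = 64)
#' @export
pipeline_config <- function(slice_interval_n = 100L,
                            patch_size_p = 800L,
                            input_downsample_d = 100L,
                            train_patches_total = 220000L,
                            predict_patches_per_slice = 100000L,
                            density_window_w = 51L,
                            dilation_radius = 50L,
                            min_component_fraction = 0.05,
                            seed = 1L,
                            label_names = mob_label_scheme()$names,
                            classifier = list()) {
  cfg <- list(slice_interval_n = as.integer(slice_interval_n),
              patch_size_p = as.integer(patch_size_p),
              input_downsample_d = as.integer(input_downsample_d),
              train_patches_total = as.integer(train_patches_total),
              predict_patches_per_slice = as.integer(predict_patches_per_slice),
              density_window_w = as.integer(density_window_w),
              dilation_radius = as.integer(dilation_radius),
              min_component_fraction = as.numeric(min_component_fraction),
              seed = as.integer(seed),
              label_names = as.character(label_names),
              classifier = classifier)
  errs <- character(0)
  pos <- c("slice_interval_n", "patch_size_p", "input_downsample_d",
           "train_patches_total", "predict_patches_per_slice", "density_window_w")
  for (k in pos) {
    if (is.na(cfg[[k]]) || cfg[[k]] < 1L)
      errs <- c(errs, paste0("`", k, "` must be a positive integer"))
  }
  if (!is.na(cfg$density_window_w) && cfg$density_window_w >= 1L &&
      cfg$density_window_w %% 2L == 0L)
    errs <- c(errs, "`density_window_w` must be odd")
  if (is.na(cfg$dilation_radius) || cfg$dilation_radius < 0L)
    errs <- c(errs, "`dilation_radius` must be a non-negative integer")
  if (is.na(cfg$min_component_fraction) || cfg$min_component_fraction < 0 ||
      cfg$min_component_fraction >= 1)
    errs <- c(errs, "`min_component_fraction` must lie in [0, 1)")
  if (length(cfg$label_names) < 1L)
    errs <- c(errs, "`label_names` must name at least one structure")
  if (!is.list(cfg$classifier))
    errs <- c(errs, "`classifier` must be a list of classifier_config overrides")
  if (length(errs) > 0L)
    stop("invalid pipeline configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$scheme <- label_scheme(cfg$label_names)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in setdiff(names(x), c("scheme", "classifier", "label_names")))
    cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  cat(sprintf("  %-26s %s\n", "label_names", paste(x$label_names, collapse = ", ")))
  if (length(x$classifier) > 0L)
    cat(sprintf("  %-26s %s\n", "classifier overrides",
                paste(names(x$classifier), collapse = ", ")))
  invisible(x)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys are the arguments of [pipeline_config()];
#' missing keys take their defaults, unknown keys and invalid values are
#' reported together.
#'
#' @param path YAML file path. An empty file yields the full default
#'   configuration.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain a YAML mapping: ", path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# One deterministic 31-bit stream seed per (master seed, stage, index), so
# slices can be processed in any order with identical draws.
derive_seed <- function(master, stage, index = 0L) {
  h <- (as.numeric(master) * 2654435761 + match(stage, c(
    "phantom", "split", "train_sample", "train_val", "train_init",
    "predict_sample", "sweep")) * 97003 + as.numeric(index) * 7919) %% 2147483647
  as.integer(h)
}
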