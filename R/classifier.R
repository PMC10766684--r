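#' Classifier configuration
#'
#' Configuration of the patch classifier M that maps a downsampled,
#' normalized `p x p` patch to a c-way prediction. The training recipe follows
#' the reference protocol: Adam, cross-entropy on softmax outputs, batch size
#' 100, at most 50 epochs, learning rate 1e-4 halved every 5 epochs, and early
#' stopping (with weight restore) when the validation loss fails to improve
#' for 5 epochs.
#'
#' Three backbones sit behind one interface (the surrounding pipeline is
#' classifier-agnostic):
#' \describe{
#'   \item{`"lightweight"`}{a small convolutional network (3x3 conv + ReLU +
#'     2x2 max-pool blocks with 8/16/32 channels, dropout, dense softmax
#'     head). Its input has two registered `d x d` channels: the whole patch
#'     area-downsampled to `d`, and the central `p/2` crop at finer scale —
#'     a foveated view that preserves texture detail near the patch center,
#'     where the label lives.}
#'   \item{`"inception_v3_like"`}{a deeper/wider conv variant (16/32/64/96
#'     channels, three input scales p, p/2, p/4), echoing the multi-scale
#'     design of the original InceptionV3-based model at desk scale. An
#'     option, not the default.}
#'   \item{`"mlp"`}{a single-hidden-layer perceptron on the `d x d` input;
#'     cheap, used in fast tests of the training machinery.}
#' }
#' Dropout sits in front of the output layer in all backbones.
#'
#' @param c number of structures (output classes; there is no background
#'   class).
#' @param input_downsample_d classifier input side after area downsampling
#'   (>= 8; the full-scale reference model uses 100).
#' @param dropout_rate dropout in `[0, 1)` applied to the last hidden
#'   activation.
#' @param architecture `"lightweight"`, `"inception_v3_like"` or `"mlp"`.
#' @param hidden_units hidden-layer sizes for the `"mlp"` backbone
#'   (default 64); ignored by the conv backbones.
#' @param batch_size,max_epochs,learning_rate,early_stop_patience,lr_halving_period
#'   optimization settings (see above).
#' @param seed seed controlling init, shuffling and dropout.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(c, input_downsample_d = 100L, dropout_rate = 0.5,
                              architecture = c("lightweight", "inception_v3_like", "mlp"),
                              hidden_units = NULL, batch_size = 100L,
                              max_epochs = 50L, learning_rate = 1e-4,
                              early_stop_patience = 5L, lr_halving_period = 5L,
                              seed = 1L) {
  architecture <- match.arg(architecture)
  c <- as.integer(c); input_downsample_d <- as.integer(input_downsample_d)
  if (c < 1L) stop("`c` must be >= 1")
  if (input_downsample_d < 8L) stop("`input_downsample_d` must be >= 8")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("`dropout_rate` must lie in [0, 1)")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (max_epochs < 1L) stop("`max_epochs` must be >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (is.null(hidden_units)) hidden_units <- 64L
  structure(list(c = c, input_downsample_d = input_downsample_d,
                 dropout_rate = dropout_rate, architecture = architecture,
                 hidden_units = as.integer(hidden_units),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_halving_period = as.integer(lr_halving_period),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# backbone geometry: input view fractions of p, conv channels (NULL = mlp)
arch_spec <- function(config) {
  switch(config$architecture,
         lightweight = list(type = "conv", views = c(1, 0.5),
                            channels = c(8L, 16L, 32L)),
         inception_v3_like = list(type = "conv", views = c(1, 0.5, 0.25),
                                  channels = c(16L, 32L, 64L, 96L)),
         mlp = list(type = "mlp", views = 1))
}

conv_flat_dim <- function(d, channels) {
  H <- d
  for (k in channels) H <- H %/% 2L
  H * H * channels[length(channels)]
}

#' Preprocess a patch for the classifier
#'
#' Area-downsamples a square patch to `d x d` (each output pixel is the exact
#' area-weighted mean of its source block; identity when `p == d`), then
#' standardizes with the model's stored intensity statistics. A constant patch
#' (zero spread) maps to all zeros. This is the canonical single-view
#' preprocessing; conv backbones additionally receive center-crop views
#' preprocessed the same way.
#'
#' @param patch square numeric matrix.
#' @param config a [classifier_config()].
#' @param stats list with `mean` and `sd` (a trained model's frozen training
#'   statistics); `NULL` standardizes by the patch's own moments.
#' @return `d x d` numeric matrix, finite everywhere.
#' @export
preprocess_patch <- function(patch, config, stats = NULL) {
  if (nrow(patch) != ncol(patch)) stop("`patch` must be square")
  down <- cpp_downsample_area(patch, config$input_downsample_d)
  if (is.null(stats)) stats <- list(mean = mean(down), sd = stats::sd(down))
  if (!is.finite(stats$sd) || stats$sd < 1e-12) return(down * 0)
  (down - stats$mean) / stats$sd
}

# n x d^2 raw (unnormalized) downsampled features for one view size
patch_features_raw <- function(ps, d, p = ps$p) {
  n <- n_patches(ps)
  X <- matrix(0, n, d * d)
  for (key in names(ps$images)) {
    idx <- which(ps$slice_index == as.integer(key))
    if (length(idx) == 0L) next
    X[idx, ] <- cpp_extract_features(ps$images[[key]],
                                     ps$centers[idx, 1], ps$centers[idx, 2],
                                     as.integer(p), as.integer(d))
  }
  X
}

# multi-view raw features: one d x d channel per view fraction
patch_features_views <- function(ps, config) {
  spec <- arch_spec(config)
  d <- config$input_downsample_d
  do.call(cbind, lapply(spec$views, function(f)
    patch_features_raw(ps, d, p = max(2L, as.integer(round(ps$p * f))))))
}

onehot_matrix <- function(labels, c) {
  Y <- matrix(0, length(labels), c)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

init_params <- function(config, n_features) {
  spec <- arch_spec(config)
  d <- config$input_downsample_d
  he <- function(fan_in, nr, nc) matrix(stats::rnorm(nr * nc) * sqrt(2 / fan_in), nr, nc)
  if (spec$type == "mlp") {
    mlp_init(c(n_features, config$hidden_units, config$c))
  } else {
    chans <- c(length(spec$views), spec$channels)
    layers <- lapply(seq_along(spec$channels), function(l)
      list(W = he(chans[l] * 9L, chans[l] * 9L, chans[l + 1L]),
           b = rep(0, chans[l + 1L])))
    flat <- conv_flat_dim(d, spec$channels)
    c(layers, list(list(W = he(flat, flat, config$c), b = rep(0, config$c))))
  }
}

# unified loss+grad and logits across backbones; params is a list of
# (W, b) layers (conv layers first, dense head last for conv backbones)
backbone_grad <- function(params, X, Y, config) {
  spec <- arch_spec(config)
  if (spec$type == "mlp")
    return(mlp_loss_grad(params, X, Y, config$dropout_rate))
  L <- length(params)
  g <- cpp_convnet_grad(params[-L], params[[L]]$W, params[[L]]$b, X, Y,
                        config$input_downsample_d, length(spec$views),
                        config$dropout_rate)
  list(loss = g$loss, grads = c(g$conv, list(g$dense)))
}

backbone_logits <- function(params, X, config) {
  spec <- arch_spec(config)
  if (spec$type == "mlp") return(mlp_logits(params, X))
  L <- length(params)
  cpp_convnet_logits(params[-L], params[[L]]$W, params[[L]]$b, X,
                     config$input_downsample_d, length(spec$views))
}

backbone_eval <- function(params, X, labels, config, batch = 2000L) {
  n <- nrow(X)
  loss <- 0; correct <- 0L
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    lg <- backbone_logits(params, X[idx, , drop = FALSE], config)
    P <- mlp_softmax(lg)
    loss <- loss - sum(log(pmax(P[cbind(seq_along(idx), labels[idx])], 1e-12)))
    correct <- correct + sum(max.col(lg, ties.method = "first") == labels[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the patch classifier
#'
#' Optimizes the configured backbone with Adam and softmax cross-entropy.
#' The learning rate is halved every `lr_halving_period` epochs; training
#' stops early once the validation loss has not improved for
#' `early_stop_patience` consecutive epochs, and the weights of the best
#' validation epoch are kept. Normalization statistics (global intensity
#' mean/sd of the downsampled training patches) are computed here and frozen
#' into the model. Fully reproducible under `config$seed`.
#'
#' @param train,val labelled [patch_set()]s (labels in `1..c`).
#' @param config a [classifier_config()].
#' @return object of class `classifier_model`: trained weights, the config,
#'   the frozen normalization stats and a per-epoch `history` tibble
#'   (epoch, lr, train_loss, train_acc, val_loss, val_acc).
#' @export
train_classifier <- function(train, val, config) {
  stopifnot(inherits(train, "patch_set"), inherits(val, "patch_set"),
            inherits(config, "classifier_config"))
  if (n_patches(train) == 0L || n_patches(val) == 0L)
    stop("training and validation patch sets must be nonempty")
  for (ps in list(train, val)) {
    if (is.null(ps$labels)) stop("patch sets must carry center labels")
    if (any(ps$labels > config$c))
      stop("patch label ", max(ps$labels), " exceeds c = ", config$c)
  }
  Xtr <- patch_features_views(train, config)
  Xva <- patch_features_views(val, config)
  stats <- list(mean = mean(Xtr), sd = max(stats::sd(Xtr), 1e-8))
  Xtr <- (Xtr - stats$mean) / stats$sd
  Xva <- (Xva - stats$mean) / stats$sd
  Ytr <- onehot_matrix(train$labels, config$c)

  n <- nrow(Xtr)
  history <- list()
  best <- list(loss = Inf, params = NULL, epoch = 0L)
  stall <- 0L
  with_seed(config$seed, {
    params <- init_params(config, ncol(Xtr))
    state <- adam_init(params)
    t <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$learning_rate * 0.5^((epoch - 1L) %/% config$lr_halving_period)
      perm <- sample.int(n)
      run_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        lg <- backbone_grad(params, Xtr[idx, , drop = FALSE],
                            Ytr[idx, , drop = FALSE], config)
        t <- t + 1L
        upd <- adam_step(params, lg$grads, state, lr, t)
        params <- upd$params; state <- upd$state
        run_loss <- run_loss + lg$loss * length(idx)
      }
      # train metrics: running minibatch loss plus accuracy on a fixed
      # subsample (a full training-set pass per epoch would dominate runtime)
      tr_idx <- seq_len(min(n, 5000L))
      tr <- backbone_eval(params, Xtr[tr_idx, , drop = FALSE],
                          train$labels[tr_idx], config)
      va <- backbone_eval(params, Xva, val$labels, config)
      history[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = run_loss / n, train_acc = tr$acc,
                                     val_loss = va$loss, val_acc = va$acc)
      if (va$loss < best$loss - 1e-9) {
        best <- list(loss = va$loss, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
  })
  structure(list(params = best$params, config = config, stats = stats,
                 history = tibble::as_tibble(do.call(rbind, history)),
                 best_epoch = best$epoch),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<classifier_model> %s, c = %d, d = %d; %d epoch(s), best val loss %.4f (epoch %d)\n",
              x$config$architecture, x$config$c, x$config$input_downsample_d,
              nrow(h), min(h$val_loss), x$best_epoch))
  invisible(x)
}

#' One-hot prediction for a single patch
#'
#' Runs the trained model on one raw `p x p` patch and converts the class
#' probabilities to a c-bit one-hot vector: exactly one bit set, at the argmax
#' (ties broken toward the lowest class index).
#'
#' @param model a trained [train_classifier()] model.
#' @param patch square numeric matrix.
#' @return integer vector of length `c` with a single 1.
#' @export
predict_one_hot <- function(model, patch) {
  UseMethod("predict_one_hot")
}

#' @export
predict_one_hot.classifier_model <- function(model, patch) {
  p <- nrow(patch)
  center <- matrix(c(p %/% 2L + 1L, p %/% 2L + 1L), 1)
  ps <- patch_set(center, 1L, p, list("1" = patch))
  pred <- predict_batch(model, ps)
  oh <- integer(model$config$c)
  oh[pred$class_idx] <- 1L
  oh
}

#' Batch prediction over a patch set
#'
#' Order-preserving one-hot classification of every sample; results carry the
#' center coordinates and slice index needed to fill the sparse map.
#' Predictions are independent of how the batch is partitioned internally.
#'
#' @param model a `classifier_model`, or any object with a `predict_batch`
#'   method (e.g. [oracle_classifier()] for pipeline tests).
#' @param patches a [patch_set()].
#' @return object of class `patch_predictions`: list with `centers`
#'   (n x 2), `slice_index`, `class_idx` (argmax labels in `1..c`) and `c`.
#' @export
predict_batch <- function(model, patches) {
  UseMethod("predict_batch")
}

#' @export
predict_batch.classifier_model <- function(model, patches) {
  stopifnot(inherits(patches, "patch_set"))
  n <- n_patches(patches)
  if (n == 0L) {
    return(structure(list(centers = patches$centers,
                          slice_index = patches$slice_index,
                          class_idx = integer(0), c = model$config$c),
                     class = "patch_predictions"))
  }
  # extract features and classify in chunks so very large patch sets never
  # materialize their full feature matrix at once
  cls <- integer(n)
  chunk <- 4096L   # feature-extraction block (memory bound)
  fwd <- 128L      # forward block (cache bound)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    sub <- subset_patch_set(patches, idx)
    X <- (patch_features_views(sub, model$config) - model$stats$mean) / model$stats$sd
    for (s2 in seq(1L, nrow(X), by = fwd)) {
      j <- s2:min(s2 + fwd - 1L, nrow(X))
      cls[idx[j]] <- max.col(backbone_logits(model$params, X[j, , drop = FALSE],
                                             model$config),
                             ties.method = "first")
    }
  }
  structure(list(centers = patches$centers, slice_index = patches$slice_index,
                 class_idx = cls, c = model$config$c),
            class = "patch_predictions")
}

#' Perfect-classifier stub for pipeline tests
#'
#' A drop-in for [predict_batch()] that returns the ground-truth label at each
#' patch center, isolating the reconstruction stage from classifier error.
#' Centers on unlabelled (background) pixels are an error: the classifier
#' interface has no background class, so a perfect stub is only defined on
#' structure pixels.
#'
#' @param gt_labels named list mapping slice index (as character) to the
#'   ground-truth label matrix, or a [label_volume()].
#' @param c number of structures.
#' @return object of class `oracle_classifier`.
#' @export
oracle_classifier <- function(gt_labels, c) {
  if (inherits(gt_labels, "label_volume")) {
    c <- gt_labels$scheme$c
    vol <- gt_labels$labels
    gt_labels <- stats::setNames(
      lapply(seq_len(dim(vol)[3]), function(z) vol[, , z]),
      as.character(seq_len(dim(vol)[3])))
  }
  structure(list(gt = gt_labels, c = as.integer(c)), class = "oracle_classifier")
}

#' @export
predict_batch.oracle_classifier <- function(model, patches) {
  stopifnot(inherits(patches, "patch_set"))
  n <- n_patches(patches)
  cls <- integer(n)
  for (key in unique(as.character(patches$slice_index))) {
    gt <- model$gt[[key]]
    if (is.null(gt)) stop("oracle classifier has no ground truth for slice ", key)
    idx <- which(patches$slice_index == as.integer(key))
    cls[idx] <- gt[patches$centers[idx, , drop = FALSE]]
  }
  if (any(cls == 0L))
    stop("oracle classifier hit an unlabelled (background) center; use dilation_radius = 0")
  structure(list(centers = patches$centers, slice_index = patches$slice_index,
                 class_idx = cls, c = model$c),
            class = "patch_predictions")
}

#' Save or load a trained classifier
#'
#' The model is stored as a single archive holding the weights together with
#' its metadata (configuration, normalization statistics, training history).
#'
#' @param model a `classifier_model`.
#' @param path file path (`.rds`).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "classifier_model")) stop("not a saved classifier_model: ", path)
  model
}
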