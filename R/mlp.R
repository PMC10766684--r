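# Internal multilayer-perceptron machinery: He init, ReLU hidden layers with
# inverted dropout, softmax cross-entropy, Adam. Written against base matrix
# algebra because no deep-learning backend exists in the target library; the
# classifier module keeps the backbone swappable behind its interface.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  params <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    params[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1L]) * sqrt(2 / fan_in),
                 fan_in, sizes[l + 1L]),
      b = rep(0, sizes[l + 1L]))
  }
  params
}

mlp_logits <- function(params, X) {
  L <- length(params)
  A <- X
  for (l in seq_len(L - 1L)) {
    A <- A %*% params[[l]]$W
    A <- sweep(A, 2L, params[[l]]$b, `+`)
    A[A < 0] <- 0
  }
  A <- A %*% params[[L]]$W
  sweep(A, 2L, params[[L]]$b, `+`)
}

mlp_softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# One forward+backward pass on a minibatch. Y is an n x c one-hot matrix.
# Inverted dropout is applied to every hidden activation at `dropout_rate`.
mlp_loss_grad <- function(params, X, Y, dropout_rate = 0) {
  L <- length(params)
  acts <- vector("list", L)  # inputs to each layer
  masks <- vector("list", L)
  A <- X
  for (l in seq_len(L - 1L)) {
    acts[[l]] <- A
    A <- sweep(A %*% params[[l]]$W, 2L, params[[l]]$b, `+`)
    A[A < 0] <- 0
    if (dropout_rate > 0) {
      m <- matrix(stats::runif(length(A)) >= dropout_rate, nrow(A), ncol(A)) /
        (1 - dropout_rate)
      A <- A * m
      masks[[l]] <- m
    }
  }
  acts[[L]] <- A
  logits <- sweep(A %*% params[[L]]$W, 2L, params[[L]]$b, `+`)
  P <- mlp_softmax(logits)
  n <- nrow(X)
  loss <- -sum(Y * log(pmax(P, 1e-12))) / n
  grads <- vector("list", L)
  delta <- (P - Y) / n
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(params[[l]]$W)
      if (!is.null(masks[[l - 1L]])) delta <- delta * masks[[l - 1L]]
      delta[acts[[l]] <= 0] <- 0  # ReLU gate (post-activation input stored)
    }
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(params)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[l]]$W <- params[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[l]]$b <- params[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}
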