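# Minimal feed-forward network engine: dense layers with selu/elu/relu
# activations, inverted dropout, ADAM updates on a mean-squared-error loss,
# validation split with early stopping.  Written with plain matrix algebra;
# gradient correctness is guarded by finite-difference tests.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

act_fun <- function(name) {
  switch(name,
    selu = list(
      f = function(z) SELU_LAMBDA * ifelse(z > 0, z, SELU_ALPHA * (exp(z) - 1)),
      df = function(z) SELU_LAMBDA * ifelse(z > 0, 1, SELU_ALPHA * exp(z))),
    elu = list(
      f = function(z) ifelse(z > 0, z, exp(z) - 1),
      df = function(z) ifelse(z > 0, 1, exp(z))),
    relu = list(
      f = function(z) pmax(z, 0),
      df = function(z) as.numeric(z > 0)),
    linear = list(f = identity, df = function(z) rep(1, length(z))),
    stop("unknown activation '", name, "'"))
}

#' Multilayer-perceptron configuration
#'
#' @param widths Hidden layer widths (default 256, 64, 16: three dense
#'   layers).  The scalar output layer is appended automatically.
#' @param activation `"selu"` (default), `"elu"` or `"relu"`.
#' @param dropout Dropout rate applied after each hidden layer (default 0.2).
#' @param learning_rate ADAM learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param epochs Epoch cap (default 200).
#' @param patience Early-stopping patience on the validation loss
#'   (default 10).
#' @param validation_split Fraction of the training pool held out for
#'   validation (default 0.2).
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(widths = c(256L, 64L, 16L), activation = "selu",
                       dropout = 0.2, learning_rate = 1e-3,
                       batch_size = 32L, epochs = 200L, patience = 10L,
                       validation_split = 0.2) {
  stopifnot(length(widths) >= 1, all(widths >= 1),
            dropout >= 0, dropout < 1,
            validation_split >= 0, validation_split < 1)
  structure(list(widths = as.integer(widths), activation = activation,
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 validation_split = validation_split),
            class = "mlp_config")
}

mlp_init <- function(n_in, widths, activation) {
  dims <- c(n_in, widths, 1L)
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    sd <- if (activation == "selu") 1 / sqrt(fan_in) else sqrt(2 / fan_in)
    list(W = matrix(stats::rnorm(fan_in * dims[l + 1L], 0, sd),
                    fan_in, dims[l + 1L]),
         b = rep(0, dims[l + 1L]))
  })
}

# Forward pass; returns activations and pre-activations per layer.
# drop_masks NULL for inference (no dropout).
mlp_forward <- function(layers, X, act, drop_masks = NULL) {
  L <- length(layers)
  zs <- vector("list", L); as_ <- vector("list", L + 1L)
  as_[[1L]] <- X
  for (l in seq_len(L)) {
    z <- sweep(as_[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    zs[[l]] <- z
    a <- if (l < L) {
      h <- act$f(z)
      if (!is.null(drop_masks)) h * drop_masks[[l]] else h
    } else {
      z  # linear output
    }
    as_[[l + 1L]] <- a
  }
  list(zs = zs, as_ = as_)
}

# Backward pass for 0.5 * mean squared error; returns per-layer gradients.
mlp_backward <- function(layers, fw, y, act, drop_masks = NULL) {
  L <- length(layers)
  n <- length(y)
  grads <- vector("list", L)
  delta <- (fw$as_[[L + 1L]] - y) / n          # n x 1
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(fw$as_[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(layers[[l]]$W)) * act$df(fw$zs[[l - 1L]])
      if (!is.null(drop_masks)) delta <- delta * drop_masks[[l - 1L]]
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    st <- state[[l]]; g <- grads[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
    mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}

#' Fit a multilayer perceptron regressor
#'
#' Standardizes inputs and targets internally, trains with ADAM on the MSE
#' loss using minibatches, a validation split and early stopping (the best
#' validation-loss weights are restored).  Fully seeded.
#'
#' @param X Numeric matrix (n x p) of inputs.
#' @param y Numeric response vector.
#' @param config An [mlp_config].
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return An `mlp_model` with `predict()` support and a `history`
#'   data.frame (epoch, train_loss, val_loss).
#' @export
mlp_fit <- function(X, y, config = mlp_config(), seed = 1L,
                    verbose = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  set.seed(seed)
  act <- act_fun(config$activation)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd); x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, x_center), 2L, x_scale, `/`)
  y_center <- mean(y); y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1
  ys <- matrix((y - y_center) / y_scale, ncol = 1L)

  n <- nrow(Xs)
  n_val <- floor(n * config$validation_split)
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- if (n_val > 0) idx[-seq_len(n_val)] else idx
  Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx, , drop = FALSE]
  Xva <- Xs[val_idx, , drop = FALSE]; yva <- ys[val_idx, , drop = FALSE]

  layers <- mlp_init(ncol(Xs), config$widths, config$activation)
  state <- adam_state(layers)
  t_step <- 0L
  best <- list(loss = Inf, layers = layers)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  n_tr <- nrow(Xtr)
  monitor_val <- n_val > 0
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (s in starts) {
      rows <- ord[s:min(s + config$batch_size - 1L, n_tr)]
      Xb <- Xtr[rows, , drop = FALSE]; yb <- ytr[rows, , drop = FALSE]
      masks <- if (config$dropout > 0) {
        lapply(seq_along(config$widths), function(l) {
          matrix(stats::rbinom(length(rows) * config$widths[l], 1L,
                               1 - config$dropout) / (1 - config$dropout),
                 length(rows), config$widths[l])
        })
      } else NULL
      fw <- mlp_forward(layers, Xb, act, masks)
      if (any(!is.finite(fw$as_[[length(layers) + 1L]]))) {
        stop("NaN loss during MLP training; lower the learning rate")
      }
      grads <- mlp_backward(layers, fw, yb, act, masks)
      t_step <- t_step + 1L
      upd <- adam_update(layers, grads, state, config$learning_rate, t_step)
      layers <- upd$layers; state <- upd$state
    }
    tr_loss <- mean((mlp_forward(layers, Xtr, act)$as_[[length(layers) + 1L]]
                     - ytr)^2)
    va_loss <- if (monitor_val) {
      mean((mlp_forward(layers, Xva, act)$as_[[length(layers) + 1L]] - yva)^2)
    } else tr_loss
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = va_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tr_loss,
                      va_loss))
    }
    if (va_loss < best$loss - 1e-7) {
      best <- list(loss = va_loss, layers = layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(layers = best$layers, config = config,
                 n_train = n_tr, n_val = n_val,
                 activation = config$activation,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 history = history, seed = seed),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  Xs <- sweep(sweep(newdata, 2L, object$x_center), 2L, object$x_scale, `/`)
  act <- act_fun(object$activation)
  out <- mlp_forward(object$layers, Xs, act)$as_[[length(object$layers) + 1L]]
  as.numeric(out) * object$y_scale + object$y_center
}
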