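# Separable-convolution network for peptide pI prediction.
#
# Fixed layer sequence over the (60, 22, 4) peptide tensor:
#   separable conv (depthwise 22 x 5 spanning all symbol columns with a
#   window of five residues, then 1x1 pointwise mixing) -> average pooling
#   -> separable conv (depthwise length-5 along the sequence axis, then
#   pointwise) -> average pooling -> flatten -> three dense layers -> scalar.
# Forward and backward passes are written as matrix algebra (im2col for the
# first depthwise stage); gradients are verified against finite differences
# in the test suite.

#' Configuration of the separable-convolution peptide model
#'
#' @param filters Pointwise filter counts of the two separable-convolution
#'   blocks (default 8 and 16).
#' @param kernel Window length along the sequence axis (default 5; the first
#'   depthwise kernel is 22 x `kernel`, spanning every symbol column).
#' @param dense_widths Widths of the first two dense head layers (default
#'   64, 16); the third dense layer is the scalar output.
#' @param activation `"selu"` (default) or `"elu"`.
#' @param dropout Dropout rate in the dense head (default 0.2).
#' @param learning_rate ADAM learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 8; small batches give the
#'   optimizer enough updates per epoch on modest training sets).
#' @param epochs Epoch cap (default 100).
#' @param patience Early-stopping patience (default 15; validation losses
#'   on small held-out splits are noisy).
#' @param validation_split Validation fraction of the training pool
#'   (default 0.2).
#' @param input_shape Tensor shape, fixed at c(60, 22, 4).
#' @return A `convnet_config` list.
#' @export
convnet_config <- function(filters = c(8L, 16L), kernel = 5L,
                           dense_widths = c(64L, 16L),
                           activation = c("selu", "elu"),
                           dropout = 0.2, learning_rate = 1e-3,
                           batch_size = 8L, epochs = 100L, patience = 15L,
                           validation_split = 0.2,
                           input_shape = c(60L, 22L, 4L)) {
  activation <- match.arg(activation)
  stopifnot(length(filters) == 2L, all(filters >= 1),
            kernel >= 2, kernel <= input_shape[1],
            length(dense_widths) == 2L,
            length(input_shape) == 3L)
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 dense_widths = as.integer(dense_widths),
                 activation = activation, dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 validation_split = validation_split,
                 input_shape = as.integer(input_shape)),
            class = "convnet_config")
}

convnet_dims <- function(cfg) {
  L <- cfg$input_shape[1]; A <- cfg$input_shape[2]; C <- cfg$input_shape[3]
  l1 <- L - cfg$kernel + 1L           # positions after depthwise 1
  p1 <- l1 %/% 2L                     # after average pooling 1
  l2 <- p1 - cfg$kernel + 1L          # after depthwise 2
  p2 <- l2 %/% 2L                     # after average pooling 2
  list(L = L, A = A, C = C, l1 = l1, p1 = p1, l2 = l2, p2 = p2,
       flat = p2 * cfg$filters[2])
}

#' Build an untrained separable-convolution peptide model
#'
#' Weight initialization is fully determined by the configuration and seed:
#' two builds with the same seed have identical weights.
#'
#' @param cfg A [convnet_config].
#' @param seed Integer seed for the initial weights.
#' @return A `peptide_convnet` with fields `weights`, `cfg`, `dims`,
#'   `n_parameters`, `layer_sequence`.
#' @export
build_peptide_convnet <- function(cfg = convnet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "convnet_config"))
  set.seed(seed)
  d <- convnet_dims(cfg)
  F1 <- cfg$filters[1]; F2 <- cfg$filters[2]
  k <- cfg$kernel
  lecun <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(fan_in)), nr, nc)
  }
  w <- list(
    kd1 = lecun(k * d$A, d$C, k * d$A),       # depthwise 22 x k per channel
    pw1 = lecun(d$C, F1, d$C), b1 = rep(0, F1),
    kd2 = lecun(k, F1, k),                    # depthwise length-k per filter
    pw2 = lecun(F1, F2, F1), b2 = rep(0, F2),
    d1W = lecun(d$flat, cfg$dense_widths[1], d$flat),
    d1b = rep(0, cfg$dense_widths[1]),
    d2W = lecun(cfg$dense_widths[1], cfg$dense_widths[2],
                cfg$dense_widths[1]),
    d2b = rep(0, cfg$dense_widths[2]),
    d3W = lecun(cfg$dense_widths[2], 1L, cfg$dense_widths[2]),
    d3b = 0)
  structure(list(
    weights = w, cfg = cfg, dims = d, seed = seed,
    n_parameters = sum(vapply(w, length, integer(1))),
    layer_sequence = c("sepconv", "avgpool", "sepconv", "avgpool",
                       "flatten", "dense", "dense", "dense"),
    y_center = 0, y_scale = 1, trained = FALSE, history = NULL),
    class = "peptide_convnet")
}

#' @export
print.peptide_convnet <- function(x, ...) {
  cat(sprintf("<peptide_convnet> %s, %d parameters, %s\n",
              paste(x$layer_sequence, collapse = " -> "),
              x$n_parameters,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# im2col for the first depthwise stage: one (n * l1) x (k * A) matrix per
# input channel; row r = example + (position - 1) * n.
convnet_im2col <- function(tensors, cfg) {
  d <- convnet_dims(cfg)
  n <- dim(tensors)[1]
  k <- cfg$kernel
  lapply(seq_len(d$C), function(cc) {
    M <- matrix(0, n * d$l1, k * d$A)
    q <- 0L
    for (a in seq_len(d$A)) {
      for (j in seq_len(k)) {
        q <- q + 1L
        M[, q] <- as.vector(tensors[, j:(j + d$l1 - 1L), a, cc])
      }
    }
    M
  })
}

pool2 <- function(arr) {  # average pooling, pool width 2, over dim 2
  l <- dim(arr)[2] %/% 2L
  (arr[, seq(1L, 2L * l, 2L), , drop = FALSE] +
   arr[, seq(2L, 2L * l, 2L), , drop = FALSE]) / 2
}

unpool2 <- function(darr, l_out) {  # adjoint of pool2
  n <- dim(darr)[1]; f <- dim(darr)[3]
  out <- array(0, c(n, l_out, f))
  l <- dim(darr)[2]
  out[, seq(1L, 2L * l, 2L), ] <- darr / 2
  out[, seq(2L, 2L * l, 2L), ] <- darr / 2
  out
}

# Forward pass from precomputed im2col matrices (rows already subset to the
# minibatch).  Returns every intermediate needed by the backward pass.
convnet_forward <- function(w, cols, n, cfg, act, masks = NULL) {
  d <- convnet_dims(cfg)
  F1 <- cfg$filters[1]; F2 <- cfg$filters[2]; k <- cfg$kernel
  D1 <- vapply(seq_len(d$C), function(cc) cols[[cc]] %*% w$kd1[, cc],
               numeric(n * d$l1))
  Z1 <- sweep(D1 %*% w$pw1, 2L, w$b1, `+`)
  A1 <- array(act$f(Z1), c(n, d$l1, F1))
  P1 <- pool2(A1)
  D2 <- array(0, c(n, d$l2, F1))
  for (j in seq_len(k)) {
    D2 <- D2 + sweep(P1[, j:(j + d$l2 - 1L), , drop = FALSE], 3L,
                     w$kd2[j, ], `*`)
  }
  D2m <- matrix(D2, n * d$l2, F1)
  Z2 <- sweep(D2m %*% w$pw2, 2L, w$b2, `+`)
  A2 <- array(act$f(Z2), c(n, d$l2, F2))
  P2 <- pool2(A2)
  Fl <- matrix(P2, n, d$flat)
  Zd1 <- sweep(Fl %*% w$d1W, 2L, w$d1b, `+`)
  Ad1 <- act$f(Zd1); if (!is.null(masks)) Ad1 <- Ad1 * masks[[1L]]
  Zd2 <- sweep(Ad1 %*% w$d2W, 2L, w$d2b, `+`)
  Ad2 <- act$f(Zd2); if (!is.null(masks)) Ad2 <- Ad2 * masks[[2L]]
  out <- sweep(Ad2 %*% w$d3W, 2L, w$d3b, `+`)
  list(D1 = D1, Z1 = Z1, P1 = P1, D2m = D2m, Z2 = Z2, P2 = P2, Fl = Fl,
       Zd1 = Zd1, Ad1 = Ad1, Zd2 = Zd2, Ad2 = Ad2, out = out)
}

convnet_backward <- function(w, fw, cols, y, n, cfg, act, masks = NULL) {
  d <- convnet_dims(cfg)
  F1 <- cfg$filters[1]; F2 <- cfg$filters[2]; k <- cfg$kernel
  g <- list()
  delta <- (fw$out - y) / n                      # n x 1
  g$d3W <- crossprod(fw$Ad2, delta); g$d3b <- colSums(delta)
  dAd2 <- delta %*% t(w$d3W)
  if (!is.null(masks)) dAd2 <- dAd2 * masks[[2L]]
  dZd2 <- dAd2 * act$df(fw$Zd2)
  g$d2W <- crossprod(fw$Ad1, dZd2); g$d2b <- colSums(dZd2)
  dAd1 <- dZd2 %*% t(w$d2W)
  if (!is.null(masks)) dAd1 <- dAd1 * masks[[1L]]
  dZd1 <- dAd1 * act$df(fw$Zd1)
  g$d1W <- crossprod(fw$Fl, dZd1); g$d1b <- colSums(dZd1)
  dFl <- dZd1 %*% t(w$d1W)
  dP2 <- array(dFl, c(n, d$p2, F2))
  dA2 <- unpool2(dP2, d$l2)
  dZ2 <- matrix(dA2, n * d$l2, F2) * act$df(fw$Z2)
  g$pw2 <- crossprod(fw$D2m, dZ2); g$b2 <- colSums(dZ2)
  dD2 <- array(dZ2 %*% t(w$pw2), c(n, d$l2, F1))
  g$kd2 <- matrix(0, k, F1)
  dP1 <- array(0, c(n, d$p1, F1))
  D2arr <- dD2
  P1 <- fw$P1
  for (j in seq_len(k)) {
    slice <- P1[, j:(j + d$l2 - 1L), , drop = FALSE]
    g$kd2[j, ] <- colSums(matrix(slice * D2arr, n * d$l2, F1))
    dP1[, j:(j + d$l2 - 1L), ] <- dP1[, j:(j + d$l2 - 1L), , drop = FALSE] +
      sweep(D2arr, 3L, w$kd2[j, ], `*`)
  }
  dA1 <- unpool2(dP1, d$l1)
  dZ1 <- matrix(dA1, n * d$l1, F1) * act$df(fw$Z1)
  g$pw1 <- crossprod(fw$D1, dZ1); g$b1 <- colSums(dZ1)
  dD1 <- dZ1 %*% t(w$pw1)                        # (n*l1) x C
  g$kd1 <- vapply(seq_len(d$C),
                  function(cc) as.numeric(crossprod(cols[[cc]], dD1[, cc])),
                  numeric(k * d$A))
  g
}

# rows of the full im2col matrices belonging to a minibatch, in batch order
col_rows <- function(batch, n, l1) {
  as.vector(outer(batch, (seq_len(l1) - 1L) * n, `+`))
}

#' Train the peptide model on tensors and labels
#'
#' ADAM on the mean-squared-error loss with minibatches, a validation split
#' and early stopping; aborts with a diagnostic on a NaN loss.  Labels are
#' standardized internally.
#'
#' @param model An untrained (or previously trained) [build_peptide_convnet]
#'   result.
#' @param tensors n x 60 x 22 x 4 array (see [build_peptide_tensor]).
#' @param labels Numeric pI labels, length n (n >= 100 recommended for a
#'   meaningful early-stopping split).
#' @param seed Seed for the shuffling/dropout stream (default: model seed).
#' @param verbose Print per-epoch losses.
#' @return The trained model, with a `history` data.frame (epoch,
#'   train_loss, val_loss).
#' @export
train_regressor <- function(model, tensors, labels, seed = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "peptide_convnet"),
            length(dim(tensors)) == 4L,
            dim(tensors)[1] == length(labels))
  if (length(labels) < 100) {
    warning("fewer than 100 examples; early stopping will be noisy")
  }
  cfg <- model$cfg
  if (is.null(seed)) seed <- model$seed
  set.seed(seed)
  act <- act_fun(cfg$activation)
  d <- model$dims
  n_all <- length(labels)
  y_center <- mean(labels); y_scale <- stats::sd(labels)
  if (y_scale == 0) y_scale <- 1
  ys <- (labels - y_center) / y_scale

  idx <- sample.int(n_all)
  n_val <- floor(n_all * cfg$validation_split)
  val <- idx[seq_len(n_val)]
  tr <- if (n_val > 0) idx[-seq_len(n_val)] else idx
  cols_all <- convnet_im2col(tensors, cfg)
  subcols <- function(batch) {
    rows <- col_rows(batch, n_all, d$l1)
    lapply(cols_all, function(M) M[rows, , drop = FALSE])
  }
  cols_tr <- subcols(tr); cols_va <- if (n_val > 0) subcols(val) else NULL

  w <- model$weights
  state <- adam_state_flat(w)
  t_step <- 0L
  best <- list(loss = Inf, w = w)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  n_tr <- length(tr)
  eval_loss <- function(w, cols, rows_y, n) {
    fw <- convnet_forward(w, cols, n, cfg, act)
    mean((as.numeric(fw$out) - rows_y)^2)
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = cfg$batch_size)
    for (s in starts) {
      b_local <- ord[s:min(s + cfg$batch_size - 1L, n_tr)]
      batch <- tr[b_local]
      nb <- length(batch)
      rows <- col_rows(batch, n_all, d$l1)
      cols_b <- lapply(cols_all, function(M) M[rows, , drop = FALSE])
      masks <- if (cfg$dropout > 0) {
        lapply(cfg$dense_widths, function(wd) {
          matrix(stats::rbinom(nb * wd, 1L, 1 - cfg$dropout) /
                   (1 - cfg$dropout), nb, wd)
        })
      } else NULL
      fw <- convnet_forward(w, cols_b, nb, cfg, act, masks)
      if (any(!is.finite(fw$out))) {
        stop("NaN loss during training; lower the learning rate")
      }
      grads <- convnet_backward(w, fw, cols_b, matrix(ys[batch], ncol = 1L),
                                nb, cfg, act, masks)
      t_step <- t_step + 1L
      upd <- adam_update_flat(w, grads, state, cfg$learning_rate, t_step)
      w <- upd$w; state <- upd$state
    }
    tr_loss <- eval_loss(w, cols_tr, ys[tr], n_tr)
    va_loss <- if (n_val > 0) eval_loss(w, cols_va, ys[val], n_val) else
      tr_loss
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tr_loss,
                                val_loss = va_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f",
                      epoch, tr_loss, va_loss))
    }
    if (va_loss < best$loss - 1e-7) {
      best <- list(loss = va_loss, w = w)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$weights <- best$w
  model$n_train <- n_tr
  model$n_val <- n_val
  model$y_center <- y_center
  model$y_scale <- y_scale
  model$history <- history
  model$trained <- TRUE
  model
}

# ADAM over an arbitrary named list of weight arrays.
adam_state_flat <- function(w) {
  lapply(w, function(x) list(m = x * 0, v = x * 0))
}

adam_update_flat <- function(w, g, state, lr, t,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(w)) {
    gn <- g[[nm]]
    dim(gn) <- dim(w[[nm]])
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * gn
    st$v <- beta2 * st$v + (1 - beta2) * gn^2
    mh <- st$m / (1 - beta1^t); vh <- st$v / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  list(w = w, state = state)
}

#' @export
predict.peptide_convnet <- function(object, newdata, ...) {
  stopifnot(length(dim(newdata)) == 4L)
  cfg <- object$cfg
  act <- act_fun(cfg$activation)
  n <- dim(newdata)[1]
  cols <- convnet_im2col(newdata, cfg)
  fw <- convnet_forward(object$weights, cols, n, cfg, act)
  raw <- as.numeric(fw$out) * object$y_scale + object$y_center
  clip_ph(raw)
}

# Clip predictions into the physical pH range, counting clip events.
clip_ph <- function(x) {
  n_clip <- sum(x < 0 | x > 14)
  if (n_clip > 0) {
    message(n_clip, " prediction(s) clipped into [0, 14]")
  }
  pmin(pmax(x, 0), 14)
}
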