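#' 1-D CNN architecture and training specification
#'
#' The network is the compact spectral regressor used throughout this
#' package: three convolution blocks (1-D convolution with
#' `filters_per_layer` kernels, batch normalization, ReLU, max-pool of 2),
#' a flatten, one hidden fully connected ReLU layer, and a scalar linear
#' output. Training minimizes mean-squared error with the Adam optimizer
#' at the stated learning rate for the stated number of epochs, with
#' seeded initialization and shuffling so runs are exactly reproducible.
#'
#' @param n_conv_layers number of conv-BN-ReLU-pool blocks (default 3).
#' @param filters_per_layer convolution kernels per layer (default 16).
#' @param kernel_size odd convolution kernel length (default 5), stride 1,
#'   same-padding.
#' @param fc_width width of the hidden fully connected layer (default 64).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed for initialization and shuffling.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(n_conv_layers = 3L, filters_per_layer = 16L,
                     kernel_size = 5L, fc_width = 64L,
                     learning_rate = 0.001, epochs = 100L,
                     batch_size = 32L, seed = 1L) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd (same-padding)")
  stopifnot(n_conv_layers >= 1, filters_per_layer >= 1, fc_width >= 1,
            learning_rate > 0, epochs >= 1, batch_size >= 2)
  structure(
    list(n_conv_layers = as.integer(n_conv_layers),
         filters_per_layer = as.integer(filters_per_layer),
         kernel_size = kernel_size, fc_width = as.integer(fc_width),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "cnn_spec"
  )
}

# ---- layer primitives ------------------------------------------------------
# Activations are 3-D arrays (batch, length, channels); flattening to
# (batch*length, channels) matrices is a free dim<- because batch is the
# fastest-varying index.

im2col <- function(A, k, pad) {
  d <- dim(A)
  cpp_im2col(A, d[1], d[2], d[3], k, pad)
}

conv1d_forward <- function(A, W, b, pad) {
  d <- dim(A)
  k <- nrow(W) / d[3]
  M <- im2col(A, k, pad)
  Z <- M %*% W
  Z <- Z + rep(b, each = nrow(Z))
  dim(Z) <- c(d[1], d[2], ncol(W))
  list(out = Z, M = M)
}

conv1d_backward <- function(dOut, M, W, dims, pad, need_dA = TRUE) {
  n <- dims[1]; L <- dims[2]; Cin <- dims[3]
  k <- nrow(W) / Cin
  Cout <- ncol(W)
  dZ <- dOut; dim(dZ) <- c(n * L, Cout)
  dW <- crossprod(M, dZ)
  db <- colSums(dZ)
  if (!need_dA) return(list(dA = NULL, dW = dW, db = db))
  # input gradient = convolution of dOut with the kernel flipped along the
  # window axis and transposed in channels (stride 1, same padding)
  Wt <- matrix(0, k * Cout, Cin)
  Wm <- W; dim(Wm) <- c(Cin, k, Cout)
  for (j in seq_len(k)) {
    Wt[((j - 1) * Cout + 1):(j * Cout), ] <- t(Wm[, k - j + 1, ])
  }
  dim(dOut) <- c(n, L, Cout)
  Md <- im2col(dOut, k, pad)
  dA <- Md %*% Wt
  dim(dA) <- c(n, L, Cin)
  list(dA = dA, dW = dW, db = db)
}

bn_forward <- function(A, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(A); m <- d[1] * d[2]; C <- d[3]
  X <- A; dim(X) <- c(m, C)
  if (training) {
    r <- cpp_bn_forward(X, gamma, beta, eps)
    state$mean <- (1 - momentum) * state$mean + momentum * r$mu
    state$var <- (1 - momentum) * state$var + momentum * r$var * m / max(m - 1, 1)
    out <- r$out; dim(out) <- d
    list(out = out, xhat = r$xhat, inv_sd = r$inv_sd, state = state)
  } else {
    out <- cpp_bn_infer(X, gamma, beta, state$mean, state$var, eps)
    dim(out) <- d
    list(out = out, xhat = NULL, inv_sd = NULL, state = state)
  }
}

bn_backward <- function(dOut, xhat, inv_sd, gamma, dims) {
  m <- dims[1] * dims[2]; C <- dims[3]
  dY <- dOut; dim(dY) <- c(m, C)
  r <- cpp_bn_backward(dY, xhat, inv_sd, gamma)
  dX <- r$dX; dim(dX) <- dims
  list(dA = dX, dgamma = r$dgamma, dbeta = r$dbeta)
}

# pooling is the identity once the signal is down to a single position,
# so the architecture also accepts short selected-band inputs
maxpool2_forward <- function(A) {
  d <- dim(A)
  if (d[2] < 2) return(list(out = A, take_first = NULL, in_dim = d))
  r <- cpp_maxpool2_forward(A, d[1], d[2], d[3])
  list(out = r$out, take_first = r$take_first, in_dim = d)
}

maxpool2_backward <- function(dOut, take_first, in_dim) {
  if (is.null(take_first)) return(dOut)
  cpp_maxpool2_backward(dOut, take_first, in_dim[1], in_dim[2], in_dim[3])
}

cnn_init_params <- function(spec, p) {
  k <- spec$kernel_size; Fc <- spec$filters_per_layer
  params <- list(conv = list(), bn = list())
  L <- p; Cin <- 1L
  for (l in seq_len(spec$n_conv_layers)) {
    fan_in <- k * Cin
    params$conv[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * Fc, 0, sqrt(2 / fan_in)), fan_in, Fc),
      b = numeric(Fc)
    )
    params$bn[[l]] <- list(gamma = rep(1, Fc), beta = numeric(Fc),
                           mean = numeric(Fc), var = rep(1, Fc))
    Cin <- Fc
    if (L >= 2) L <- L %/% 2
  }
  D <- L * Fc
  params$fc1 <- list(W = matrix(stats::rnorm(D * spec$fc_width, 0, sqrt(2 / D)),
                                D, spec$fc_width),
                     b = numeric(spec$fc_width))
  params$fc2 <- list(W = matrix(stats::rnorm(spec$fc_width, 0, sqrt(2 / spec$fc_width)),
                                spec$fc_width, 1),
                     b = 0)
  params$flat_dim <- D
  params
}

cnn_forward <- function(params, Xb, spec, training = FALSE) {
  n <- nrow(Xb)
  pad <- (spec$kernel_size - 1L) %/% 2L
  A <- array(Xb, c(n, ncol(Xb), 1L))
  cache <- list(blocks = vector("list", spec$n_conv_layers))
  for (l in seq_len(spec$n_conv_layers)) {
    cv <- conv1d_forward(A, params$conv[[l]]$W, params$conv[[l]]$b, pad)
    bn <- bn_forward(cv$out, params$bn[[l]]$gamma, params$bn[[l]]$beta,
                     params$bn[[l]], training)
    if (training) {
      params$bn[[l]]$mean <- bn$state$mean
      params$bn[[l]]$var <- bn$state$var
    }
    relu_mask <- bn$out > 0
    R <- bn$out * relu_mask
    pl <- maxpool2_forward(R)
    cache$blocks[[l]] <- list(M = cv$M, conv_dims = dim(A),
                              bn_xhat = bn$xhat, bn_inv_sd = bn$inv_sd,
                              bn_dims = dim(cv$out), relu_mask = relu_mask,
                              pool_take = pl$take_first, pool_in = pl$in_dim)
    A <- pl$out
  }
  Fl <- A; dim(Fl) <- c(n, params$flat_dim)
  Z1 <- Fl %*% params$fc1$W
  Z1 <- Z1 + rep(params$fc1$b, each = nrow(Z1))
  H <- Z1 * (Z1 > 0)
  yhat <- drop(H %*% params$fc2$W) + params$fc2$b
  cache$Fl <- Fl; cache$Z1 <- Z1; cache$H <- H
  cache$pool_out_dim <- dim(A)
  list(yhat = yhat, cache = cache, params = params)
}

cnn_backward <- function(params, cache, dyhat, spec) {
  n <- length(dyhat)
  grads <- list(conv = list(), bn = list())
  dH <- matrix(dyhat, n, 1) %*% t(params$fc2$W)
  grads$fc2 <- list(W = crossprod(cache$H, matrix(dyhat, n, 1)), b = sum(dyhat))
  dZ1 <- dH * (cache$Z1 > 0)
  grads$fc1 <- list(W = crossprod(cache$Fl, dZ1), b = colSums(dZ1))
  dFl <- dZ1 %*% t(params$fc1$W)
  dA <- dFl; dim(dA) <- cache$pool_out_dim
  pad <- (spec$kernel_size - 1L) %/% 2L
  for (l in rev(seq_len(spec$n_conv_layers))) {
    blk <- cache$blocks[[l]]
    dR <- maxpool2_backward(dA, blk$pool_take, blk$pool_in)
    dBn <- dR * blk$relu_mask
    bnb <- bn_backward(dBn, blk$bn_xhat, blk$bn_inv_sd,
                       params$bn[[l]]$gamma, blk$bn_dims)
    grads$bn[[l]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cvb <- conv1d_backward(bnb$dA, blk$M, params$conv[[l]]$W, blk$conv_dims, pad,
                           need_dA = l > 1)
    grads$conv[[l]] <- list(W = cvb$dW, b = cvb$db)
    dA <- cvb$dA
  }
  grads
}

# Adam, applied in-place over the nested parameter list
adam_update <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  upd <- function(par, gr, st) {
    st$m <- beta1 * st$m + (1 - beta1) * gr
    st$v <- beta2 * st$v + (1 - beta2) * gr^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    list(par = par - lr * mhat / (sqrt(vhat) + eps), st = st)
  }
  # explicit traversal: conv/bn lists, then fc layers
  for (l in seq_along(grads$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[l]][[nm]], grads$conv[[l]][[nm]], state$conv[[l]][[nm]])
      params$conv[[l]][[nm]] <- r$par; state$conv[[l]][[nm]] <- r$st
    }
    for (nm in c("gamma", "beta")) {
      r <- upd(params$bn[[l]][[nm]], grads$bn[[l]][[nm]], state$bn[[l]][[nm]])
      params$bn[[l]][[nm]] <- r$par; state$bn[[l]][[nm]] <- r$st
    }
  }
  for (fc in c("fc1", "fc2")) {
    for (nm in c("W", "b")) {
      r <- upd(params[[fc]][[nm]], grads[[fc]][[nm]], state[[fc]][[nm]])
      params[[fc]][[nm]] <- r$par; state[[fc]][[nm]] <- r$st
    }
  }
  list(params = params, state = state)
}

adam_init <- function(params, n_conv) {
  zero_like <- function(x) list(m = x * 0, v = x * 0)
  st <- list(conv = list(), bn = list())
  for (l in seq_len(n_conv)) {
    st$conv[[l]] <- list(W = zero_like(params$conv[[l]]$W),
                         b = zero_like(params$conv[[l]]$b))
    st$bn[[l]] <- list(gamma = zero_like(params$bn[[l]]$gamma),
                       beta = zero_like(params$bn[[l]]$beta))
  }
  st$fc1 <- list(W = zero_like(params$fc1$W), b = zero_like(params$fc1$b))
  st$fc2 <- list(W = zero_like(params$fc2$W), b = zero_like(params$fc2$b))
  st
}

#' Train the 1-D CNN spectral regressor
#'
#' Spectra are standardized per band and the target is standardized, both
#' with training-set statistics only (stored in the model and inverted at
#' prediction time); batch normalization keeps running statistics for
#' inference. Training is plain minibatch Adam on the mean-squared error
#' for `spec$epochs` epochs. A non-finite loss aborts with the epoch index.
#'
#' @param X training spectra: matrix or [spectrum_matrix()]; at least
#'   `spec$batch_size` rows.
#' @param y numeric target vector (% units).
#' @param spec a [cnn_spec()].
#' @return A `cnn_model` with trained `params`, the standardization
#'   vectors, and `history` (per-epoch training RMSE, original units,
#'   length `spec$epochs`).
#' @export
cnn_fit <- function(X, y, spec = cnn_spec()) {
  if (inherits(X, "spectrum_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) does not match nrow(X)")
  if (n < spec$batch_size) stop("need n >= batch_size training samples")
  if (p < 2) stop("need at least 2 spectral bands")
  if (stats::sd(y) == 0) stop("`y` has zero variance; no calibration is possible")

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd); x_sd[x_sd == 0] <- 1
  y_mean <- mean(y); y_sd <- stats::sd(y)
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, `/`)
  ys <- (y - y_mean) / y_sd

  set.seed(spec$seed)
  params <- cnn_init_params(spec, p)
  state <- adam_init(params, spec$n_conv_layers)
  history <- numeric(spec$epochs)
  t_step <- 0L
  for (epoch in seq_len(spec$epochs)) {
    idx <- sample(n)
    ep_sse <- 0; ep_n <- 0L
    for (b0 in seq(1, n, by = spec$batch_size)) {
      bi <- idx[b0:min(b0 + spec$batch_size - 1L, n)]
      if (length(bi) < 2L) next  # batch norm needs >= 2 samples
      fw <- cnn_forward(params, Xs[bi, , drop = FALSE], spec, training = TRUE)
      params <- fw$params  # running BN stats advanced
      resid <- fw$yhat - ys[bi]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      }
      grads <- cnn_backward(params, fw$cache, 2 * resid / length(bi), spec)
      t_step <- t_step + 1L
      au <- adam_update(params, grads, state, spec$learning_rate, t_step)
      params <- au$params; state <- au$state
      ep_sse <- ep_sse + sum(resid^2); ep_n <- ep_n + length(bi)
    }
    history[epoch] <- sqrt(ep_sse / ep_n) * y_sd
  }
  structure(
    list(spec = spec, params = params,
         x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
         history = history, p = p),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> %d conv blocks x %d filters, %d bands; final training RMSE %.4g\n",
    x$spec$n_conv_layers, x$spec$filters_per_layer, x$p,
    x$history[length(x$history)]))
  invisible(x)
}

#' Predict from a trained CNN
#'
#' Inference mode: batch normalization uses the stored running statistics,
#' so repeated calls on the same input are identical.
#'
#' @param object a `cnn_model`.
#' @param newdata matrix (or [spectrum_matrix()]) with the training band count.
#' @param ... unused.
#' @return numeric vector of predictions in original target units.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop(sprintf("model expects %d bands, got %d", object$p, ncol(newdata)))
  }
  Xs <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_sd, `/`)
  fw <- cnn_forward(object$params, Xs, object$spec, training = FALSE)
  fw$yhat * object$y_sd + object$y_mean
}
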