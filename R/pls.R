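#' @keywords internal
# PLS1 NIPALS on mean-centered data. Returns the per-LV cumulative
# coefficient path so one decomposition serves every candidate LV count
# (the trick cross-validation and CARS rely on).
pls1_core <- function(X, y, ncomp, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1) stop("cannot fit PLS with fewer than 2 samples or 1 variable")
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2, x_means)
  yd <- y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    a_done <- a
  }
  if (a_done == 0L) stop("PLS found no usable component (degenerate X or y)")
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  # b_A = W (P'W)^{-1}_{1:A} q_{1:A}; cumulative sums give the whole path
  R <- W %*% solve(crossprod(P, W))
  Rq <- sweep(R, 2, q, `*`)
  coef_path <- Rq %*% upper.tri(diag(a_done), diag = TRUE)
  list(x_means = x_means, y_mean = y_mean, W = W, P = P, q = q,
       coef_path = coef_path, ncomp = a_done)
}

# CV RMSE per latent-variable count with a fixed fold assignment.
# Used both by pls_fit and by CARS (which must compare subsets on the
# same folds).
pls_cv_rmse_by_lv <- function(X, y, fold_id, max_lv) {
  X <- as.matrix(X)
  folds <- sort(unique(fold_id))
  min_train <- min(table(factor(fold_id, levels = folds)))
  a_max <- min(max_lv, nrow(X) - max(table(fold_id)) - 1L, ncol(X))
  if (a_max < 1) stop("cross-validation folds leave too few training samples")
  sse <- numeric(a_max)
  cnt <- 0L
  for (f in folds) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    fit <- pls1_core(X[tr, , drop = FALSE], y[tr], a_max)
    pred <- sweep(X[te, , drop = FALSE], 2, fit$x_means) %*% fit$coef_path + fit$y_mean
    a_fit <- ncol(pred)
    err2 <- (pred - y[te])^2
    sse[seq_len(a_fit)] <- sse[seq_len(a_fit)] + colSums(err2)
    if (a_fit < a_max) {
      # rank-limited fold: larger LV counts fall back to the largest fitted
      sse[(a_fit + 1L):a_max] <- sse[(a_fit + 1L):a_max] + sum(err2[, a_fit])
    }
    cnt <- cnt + length(te)
  }
  sqrt(sse / cnt)
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares on mean-centered spectra with a univariate
#' target. The number of latent variables (LVs) is chosen by k-fold
#' cross-validation as the minimizer of RMSECV (ties resolved toward fewer
#' LVs), capped at `max_lv`.
#'
#' @param X training spectra: numeric matrix (samples x bands) or
#'   [spectrum_matrix()].
#' @param y numeric target vector (% units), non-constant.
#' @param max_lv maximum number of latent variables (default 15).
#' @param cv_folds folds for the LV choice (default 10).
#' @param seed seed for the fold assignment.
#' @param n_lv optional fixed LV count, bypassing cross-validation.
#' @return A `pls_model`: centering vectors, the coefficient vector `b`
#'   (prediction is `(x - x_means) . b + y_mean`), the per-LV coefficient
#'   path and `cv_rmse_by_lv`.
#' @export
pls_fit <- function(X, y, max_lv = 15L, cv_folds = 10L, seed = 1L, n_lv = NULL) {
  if (inherits(X, "spectrum_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) does not match nrow(X)")
  if (stats::sd(y) == 0) stop("`y` has zero variance; no calibration is possible")
  cv_rmse <- NULL
  if (is.null(n_lv)) {
    if (n <= cv_folds) stop("need more samples than folds")
    set.seed(seed)
    fold_id <- sample(rep(seq_len(cv_folds), length.out = n))
    cv_rmse <- pls_cv_rmse_by_lv(X, y, fold_id, max_lv)
    n_lv <- which.min(cv_rmse)  # ties: smaller LV count
  }
  fit <- pls1_core(X, y, max(n_lv, 1L))
  n_lv <- min(n_lv, fit$ncomp)
  structure(
    list(n_lv = n_lv, max_lv = max_lv,
         x_means = fit$x_means, y_mean = fit$y_mean,
         b = fit$coef_path[, n_lv],
         coef_path = fit$coef_path, cv_rmse_by_lv = cv_rmse,
         W = fit$W, P = fit$P, q = fit$q),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d bands\n",
              x$n_lv, length(x$b)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix (or [spectrum_matrix()]) with the same
#'   band count the model was trained on.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) {
    stop(sprintf("model expects %d bands, got %d", length(object$b), ncol(newdata)))
  }
  drop(sweep(newdata, 2, object$x_means) %*% object$b) + object$y_mean
}
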