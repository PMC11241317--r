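#' Correlation and root-mean-square error of a prediction
#'
#' The two building blocks of calibration-model evaluation:
#' `R = cor(y_true, y_pred)` (Pearson) and
#' `RMSE = sqrt(mean((y_true - y_pred)^2))`. Applied to the calibration
#' set these are Rc/RMSEC, to the prediction set Rp/RMSEP.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 3.
#' @return list with `R` and `RMSE`. For a constant `y_true` the
#'   correlation is undefined and returned as `NA` with a warning.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 3) stop("need at least 3 observations")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  if (stats::sd(y_true) == 0) {
    warning("constant reference values: correlation undefined (NA)")
    return(list(R = NA_real_, RMSE = rmse))
  }
  R <- if (stats::sd(y_pred) == 0) 0 else stats::cor(y_true, y_pred)
  list(R = R, RMSE = rmse)
}

#' Residual prediction deviation
#'
#' `RPD = SD(y_true over the prediction set) / RMSEP` with the sample SD
#' (denominator n - 1). Conventional reading: RPD > 2 means the model can
#' predict, RPD > 2.5 means it predicts robustly.
#'
#' @param y_true reference values of the prediction set (length >= 3).
#' @param rmsep prediction-set RMSE (> 0; `rmsep = 0` returns `Inf` with a
#'   warning rather than an error).
#' @return the RPD value.
#' @examples
#' rpd(c(1, 2, 3), 0.4)  # SD = 1, so 2.5
#' @export
rpd <- function(y_true, rmsep) {
  if (length(y_true) < 3) stop("prediction set must have >= 3 samples")
  if (rmsep < 0) stop("`rmsep` must be nonnegative")
  if (rmsep == 0) {
    warning("RMSEP is zero; RPD is infinite")
    return(Inf)
  }
  stats::sd(y_true) / rmsep
}

#' Seeded train/test split
#'
#' Disjoint, exhaustive random partition at a named ratio: `"pls_2to1"`
#' (train 2/3), `"cnn_4to1"` (train 4/5), or a custom training fraction.
#' Sizes are `floor(fraction * n)` / remainder.
#'
#' @param n number of samples (>= 10).
#' @param scheme `"pls_2to1"`, `"cnn_4to1"`, or `"custom"`.
#' @param fraction training fraction when `scheme = "custom"`.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @examples
#' s <- make_split(576, "pls_2to1", seed = 1)
#' lengths(s)  # 384 192
#' @export
make_split <- function(n, scheme = c("pls_2to1", "cnn_4to1", "custom"),
                       fraction = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (n < 10) stop("need at least 10 samples to split")
  frac <- switch(scheme,
    pls_2to1 = 2 / 3,
    cnn_4to1 = 4 / 5,
    custom = {
      if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
        stop("custom scheme needs 0 < fraction < 1")
      }
      fraction
    }
  )
  set.seed(seed)
  perm <- sample(n)
  n_train <- floor(frac * n)
  list(train = sort(perm[seq_len(n_train)]), test = sort(perm[-seq_len(n_train)]))
}
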