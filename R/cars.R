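#' Configuration for CARS wavelength selection
#'
#' @param n_runs number of Monte Carlo sampling runs (default 50).
#' @param cv_folds folds for the RMSECV evaluation of each retained subset
#'   (default 10).
#' @param sample_fraction fraction of calibration samples drawn (without
#'   replacement) for each run's coefficient fit (default 0.8).
#' @param max_lv latent-variable cap for the internal PLS models.
#' @param seed integer seed.
#' @return A `cars_config` list.
#' @export
cars_config <- function(n_runs = 50L, cv_folds = 10L, sample_fraction = 0.8,
                        max_lv = 15L, seed = 1L) {
  stopifnot(n_runs >= 2, cv_folds >= 2,
            sample_fraction > 0, sample_fraction <= 1, max_lv >= 1)
  structure(
    list(n_runs = as.integer(n_runs), cv_folds = as.integer(cv_folds),
         sample_fraction = sample_fraction, max_lv = as.integer(max_lv),
         seed = as.integer(seed)),
    class = "cars_config"
  )
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength selection. Starting from the full spectrum, each
#' Monte Carlo run (i) records the 10-fold RMSECV of a PLS model on the
#' currently retained bands (fold assignment fixed once, so all subsets are
#' compared on the same folds), (ii) fits PLS on a random
#' `sample_fraction` subset of samples and converts the absolute regression
#' coefficients into weights, (iii) applies the exponentially decreasing
#' function (EDF) -- the retention ratio decays from 1 at the first run to
#' `2/p` at the last -- keeping the top-weighted bands, and (iv) applies
#' adaptive reweighted sampling (ARS): weighted draws with replacement
#' among the survivors, keeping bands drawn at least once. The retained
#' subset with minimal RMSECV over all runs is returned. Because the first
#' recorded subset is the full spectrum, the winning RMSECV can never
#' exceed the full-spectrum RMSECV on those folds, and retained sets are
#' nested across runs.
#'
#' Ties (equal weights, equal RMSECV) resolve toward the lowest band index
#' / earliest run, so a fixed seed reproduces the selection exactly.
#'
#' @param X calibration spectra: matrix or [spectrum_matrix()].
#' @param y numeric target vector.
#' @param config a [cars_config()].
#' @return A `selection_result`: sorted `selected` indices,
#'   `selected_labels` (rounded nm, when a grid is available), a `trace`
#'   data frame (run, n_vars, rmsecv, n_lv), `best_iteration`, and the
#'   per-run retained sets in `history`.
#' @export
cars_select <- function(X, y, config = cars_config()) {
  grid <- if (inherits(X, "spectrum_matrix")) X$grid else NULL
  if (inherits(X, "spectrum_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) does not match nrow(X)")
  if (p < 2) stop("CARS needs at least 2 bands")
  if (n < 2 * config$cv_folds) stop("CARS needs n >= 2 * cv_folds samples")

  N <- config$n_runs
  # EDF schedule: r_i = a exp(-k i) with r_1 = 1 and r_N = 2/p
  k_dec <- log(p / 2) / (N - 1)
  ratio <- exp(k_dec) * exp(-k_dec * seq_len(N))

  set.seed(config$seed)
  fold_id <- sample(rep(seq_len(config$cv_folds), length.out = n))
  n_mc <- max(2L, round(config$sample_fraction * n))

  retained <- seq_len(p)
  history <- vector("list", N)
  trace <- data.frame(run = integer(0), n_vars = integer(0),
                      rmsecv = numeric(0), n_lv = integer(0))
  truncated <- FALSE
  for (i in seq_len(N)) {
    history[[i]] <- retained
    cv <- pls_cv_rmse_by_lv(X[, retained, drop = FALSE], y, fold_id, config$max_lv)
    n_lv <- which.min(cv)
    trace <- rbind(trace, data.frame(run = i, n_vars = length(retained),
                                     rmsecv = cv[n_lv], n_lv = n_lv))
    if (i == N) break
    # coefficient weights from a Monte Carlo sample subset
    mc <- sample(n, n_mc)
    fit <- pls1_core(X[mc, retained, drop = FALSE], y[mc],
                     min(n_lv, config$max_lv))
    b <- fit$coef_path[, min(n_lv, fit$ncomp)]
    w <- abs(b)
    if (sum(w) == 0) w <- rep(1, length(w))
    # EDF: keep the top-weighted ceil(r_{i+1} * p) bands
    keep_n <- min(length(retained), ceiling(ratio[i + 1] * p))
    ord <- order(w, decreasing = TRUE)  # ties: lowest position first
    edf_pos <- ord[seq_len(keep_n)]
    # ARS: weighted draws with replacement; drawn-at-least-once survive
    w_edf <- w[edf_pos] / sum(w[edf_pos])
    drawn <- unique(sample(edf_pos, size = keep_n, replace = TRUE, prob = w_edf))
    retained <- sort(retained[drawn])
    if (length(retained) < 2) {
      warning(sprintf("retained set collapsed below 2 bands at run %d; schedule truncated", i))
      truncated <- TRUE
      break
    }
  }
  best <- which.min(trace$rmsecv)
  selected <- sort(history[[trace$run[best]]])
  structure(
    list(method = "CARS",
         selected = selected,
         selected_labels = if (!is.null(grid)) grid$labels[selected] else selected,
         trace = trace, best_iteration = best,
         history = history[seq_len(nrow(trace))],
         truncated = truncated, config = config),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  crit <- if (!is.null(x$trace$rmsecv)) x$trace$rmsecv else x$trace$rmse
  cat(sprintf("<selection_result:%s> %d bands selected (best of %d iterations, RMSE %.4g)\n",
              x$method, length(x$selected), nrow(x$trace), crit[x$best_iteration]))
  invisible(x)
}

#' Variable-reduction percentage
#'
#' `100 * (1 - selected / total)`, reported at two decimals -- the figure
#' quoted when a selector shrinks a 616-band spectrum to a handful of
#' characteristic wavelengths.
#'
#' @param total total number of variables (> 0).
#' @param selected number of selected variables (0 < selected <= total).
#' @return the reduction percentage, rounded to 2 decimals.
#' @examples
#' reduction_percentage(616, 12)  # 98.05
#' @export
reduction_percentage <- function(total, selected) {
  if (total <= 0) stop("`total` must be positive")
  if (selected <= 0) stop("`selected` must be positive")
  if (selected > total) stop("`selected` cannot exceed `total`")
  round(100 * (1 - selected / total), 2)
}
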