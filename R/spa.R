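#' Configuration for SPA wavelength selection
#'
#' @param k_min,k_max minimum and maximum number of selected variables
#'   (defaults 1 and 30).
#' @param validation_fraction fraction of samples held out to score
#'   candidate chains by multiple-linear-regression RMSE (default 1/3).
#' @param starts candidate starting bands (indices); `NULL` tries every band.
#' @param seed integer seed for the validation split.
#' @return A `spa_config` list.
#' @export
spa_config <- function(k_min = 1L, k_max = 30L, validation_fraction = 1 / 3,
                       starts = NULL, seed = 1L) {
  stopifnot(k_min >= 1, k_min <= k_max,
            validation_fraction > 0, validation_fraction < 1)
  structure(
    list(k_min = as.integer(k_min), k_max = as.integer(k_max),
         validation_fraction = validation_fraction,
         starts = if (!is.null(starts)) as.integer(starts) else NULL,
         seed = as.integer(seed)),
    class = "spa_config"
  )
}

# Successive-projections chain from one starting column of the centered
# calibration block: each step picks the column with maximal norm after
# projection onto the orthogonal complement of the span of the chosen
# columns. Ties resolve to the lowest band index. Stops early on rank
# deficiency (residual norms ~ 0).
spa_chain <- function(Xc, start, k_max, tol = 1e-10) {
  p <- ncol(Xc)
  chain <- integer(0)
  proj <- Xc
  current <- as.integer(start)
  scale0 <- max(colSums(Xc^2), 1)
  for (step in seq_len(k_max)) {
    chain <- c(chain, current)
    if (step == k_max) break
    xj <- proj[, current]
    nj <- sum(xj^2)
    if (nj < tol * scale0) break
    proj <- proj - xj %*% (crossprod(xj, proj) / nj)
    nrm2 <- colSums(proj^2)
    nrm2[chain] <- -Inf
    if (max(nrm2) < tol * scale0) break
    current <- as.integer(which.max(nrm2))  # ties: lowest index
  }
  chain
}

#' Successive projections algorithm (SPA)
#'
#' Forward wavelength selection minimizing collinearity: from each
#' candidate starting band a chain is grown on the centered calibration
#' block by repeatedly picking the band whose column has maximal norm
#' after projection orthogonal to the span of the bands already chosen
#' (chains are nested: the k-chain is a prefix of the (k+1)-chain). Every
#' chain prefix with `k_min <= k <= k_max` bands is scored by the RMSE of
#' an ordinary multiple linear regression on a held-out validation split;
#' the prefix with minimal validation RMSE wins (ties: earliest start,
#' then fewer bands).
#'
#' @param X spectra: matrix or [spectrum_matrix()].
#' @param y numeric target vector.
#' @param config a [spa_config()].
#' @return A `selection_result` with sorted `selected` indices, the winning
#'   `chain` in pick order, a `trace` of validation RMSE by k for the
#'   winning start, and `best_iteration` (position of the winning k).
#' @export
spa_select <- function(X, y, config = spa_config()) {
  grid <- if (inherits(X, "spectrum_matrix")) X$grid else NULL
  if (inherits(X, "spectrum_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) does not match nrow(X)")
  k_max <- min(config$k_max, p)
  k_min <- min(config$k_min, k_max)
  if (n <= k_max + 1) stop("SPA needs n > k_max + 1 samples")

  set.seed(config$seed)
  n_val <- max(1L, round(config$validation_fraction * n))
  val <- sort(sample(n, n_val))
  cal <- setdiff(seq_len(n), val)
  if (length(cal) <= k_max + 1) stop("calibration split too small for k_max")

  Xc <- sweep(X[cal, , drop = FALSE], 2, colMeans(X[cal, , drop = FALSE]))
  starts <- if (is.null(config$starts)) seq_len(p) else config$starts

  best <- list(rmse = Inf, start = NA_integer_, k = NA_integer_, chain = NULL,
               curve = NULL)
  y_cal <- y[cal]; y_val <- y[val]
  for (s in starts) {
    chain <- spa_chain(Xc, s, k_max)
    if (length(chain) < k_min) next
    # one unpivoted QR of the augmented calibration block serves every
    # nested prefix of the chain
    A <- cbind(1, X[cal, chain, drop = FALSE])
    qr_a <- qr(A)
    qty <- qr.qty(qr_a, y_cal)
    Rm <- qr.R(qr_a)
    Aval <- cbind(1, X[val, chain, drop = FALSE])
    curve <- rep(NA_real_, length(chain))
    for (k in seq_along(chain)) {
      if (k < k_min) next
      m <- k + 1L
      if (abs(Rm[m, m]) < 1e-10 * abs(Rm[1, 1])) break  # rank-deficient prefix
      beta <- backsolve(Rm[seq_len(m), seq_len(m), drop = FALSE], qty[seq_len(m)])
      pred <- drop(Aval[, seq_len(m), drop = FALSE] %*% beta)
      curve[k] <- sqrt(mean((y_val - pred)^2))
    }
    if (all(is.na(curve))) next
    k_best <- which.min(curve)  # NAs ignored; ties: smaller k
    if (curve[k_best] < best$rmse) {
      best <- list(rmse = curve[k_best], start = s, k = k_best,
                   chain = chain, curve = curve)
    }
  }
  if (!is.finite(best$rmse)) stop("SPA found no scoreable chain (rank-deficient data)")
  chain_sel <- best$chain[seq_len(best$k)]
  keep <- which(!is.na(best$curve))
  trace <- data.frame(k = keep, rmse = best$curve[keep])
  structure(
    list(method = "SPA",
         selected = sort(chain_sel),
         selected_labels = if (!is.null(grid)) grid$labels[sort(chain_sel)] else sort(chain_sel),
         chain = chain_sel,
         start = best$start,
         trace = trace,
         best_iteration = which(keep == best$k),
         config = config),
    class = "selection_result"
  )
}
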