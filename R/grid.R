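#' Fit and evaluate one pipeline configuration
#'
#' Splits the samples, optionally restricts to selected bands, fits the
#' requested model on the training (calibration) partition and reports the
#' five evaluation numbers: Rc, RMSEC (calibration set), Rp, RMSEP
#' (prediction set) and RPD = SD(prediction-set reference)/RMSEP.
#'
#' @param X spectra: matrix or [spectrum_matrix()] (already preprocessed).
#' @param y numeric target vector (% units).
#' @param model `"PLS"` or `"CNN"`.
#' @param scheme split scheme; defaults to the model's convention
#'   (`"pls_2to1"` for PLS, `"cnn_4to1"` for CNN).
#' @param seed seed controlling the split and the model's internal RNG.
#' @param bands optional integer vector of band indices to use.
#' @param max_lv,cv_folds PLS latent-variable cap and CV folds.
#' @param cnn a [cnn_spec()] for the CNN branch (its seed is overridden by
#'   `seed` so one argument drives the whole cell).
#' @return A `fit_report` list: the five metrics, `n_input_vars`, `n_lv`
#'   (PLS) and the split bookkeeping (`train`, `test`, `sd_test`).
#' @export
fit_eval <- function(X, y, model = c("PLS", "CNN"), scheme = NULL, seed = 1L,
                     bands = NULL, max_lv = 15L, cv_folds = 10L,
                     cnn = cnn_spec()) {
  model <- match.arg(model)
  vals <- if (inherits(X, "spectrum_matrix")) X$values else as.matrix(X)
  n <- nrow(vals)
  if (length(y) != n) stop("length(y) does not match nrow(X)")
  if (is.null(scheme)) scheme <- if (model == "PLS") "pls_2to1" else "cnn_4to1"
  split <- make_split(n, scheme, seed = seed)
  if (is.null(bands)) bands <- seq_len(ncol(vals))
  Xtr <- vals[split$train, bands, drop = FALSE]
  Xte <- vals[split$test, bands, drop = FALSE]
  ytr <- y[split$train]; yte <- y[split$test]

  if (model == "PLS") {
    fit <- pls_fit(Xtr, ytr, max_lv = max_lv, cv_folds = cv_folds, seed = seed)
    pred_tr <- predict(fit, Xtr); pred_te <- predict(fit, Xte)
    n_lv <- fit$n_lv
  } else {
    spec <- cnn
    spec$seed <- as.integer(seed)
    fit <- cnn_fit(Xtr, ytr, spec)
    pred_tr <- predict(fit, Xtr); pred_te <- predict(fit, Xte)
    n_lv <- NA_integer_
  }
  cal <- regression_metrics(ytr, pred_tr)
  prd <- regression_metrics(yte, pred_te)
  structure(
    list(model = model, scheme = scheme, seed = seed,
         n_input_vars = length(bands), n_lv = n_lv,
         Rc = cal$R, RMSEC = cal$RMSE, Rp = prd$R, RMSEP = prd$RMSE,
         RPD = rpd(yte, prd$RMSE), sd_test = stats::sd(yte),
         train = split$train, test = split$test, fit = fit),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "<fit_report:%s> %d vars | Rc %.4f RMSEC %.4f | Rp %.4f RMSEP %.4f | RPD %.4f\n",
    x$model, x$n_input_vars, x$Rc, x$RMSEC, x$Rp, x$RMSEP, x$RPD))
  invisible(x)
}

#' Grid configuration for the treatment x selector x model study
#'
#' @param treatments named list of [preprocess_spec()]s (default: the seven
#'   standard treatments).
#' @param selectors subset of `c("none", "CARS", "SPA")`.
#' @param models subset of `c("PLS", "CNN")`.
#' @param seed integer seed driving splits, selectors and model fits.
#' @param cars,spa,cnn component configurations.
#' @param selection_on `"train"` (default: selectors see only the cell's
#'   calibration partition, avoiding selection leakage) or `"full"`.
#' @param shared_split if `TRUE` both model families are evaluated on the
#'   same 2:1 partition (fair model comparison); otherwise PLS uses 2:1
#'   and CNN 4:1, each family's convention.
#' @param max_lv,cv_folds PLS settings.
#' @return A `grid_config` list.
#' @export
grid_config <- function(treatments = standard_treatments(),
                        selectors = c("none", "CARS", "SPA"),
                        models = c("PLS", "CNN"),
                        seed = 1L,
                        cars = cars_config(), spa = spa_config(),
                        cnn = cnn_spec(),
                        selection_on = c("train", "full"),
                        shared_split = FALSE,
                        max_lv = 15L, cv_folds = 10L) {
  selection_on <- match.arg(selection_on)
  selectors <- match.arg(selectors, c("none", "CARS", "SPA"), several.ok = TRUE)
  models <- match.arg(models, c("PLS", "CNN"), several.ok = TRUE)
  if (length(treatments) == 0) stop("need at least one treatment")
  if (is.null(names(treatments))) stop("`treatments` must be a named list")
  structure(
    list(treatments = treatments, selectors = selectors, models = models,
         seed = as.integer(seed), cars = cars, spa = spa, cnn = cnn,
         selection_on = selection_on, shared_split = shared_split,
         max_lv = as.integer(max_lv), cv_folds = as.integer(cv_folds)),
    class = "grid_config"
  )
}

run_one_cell <- function(Xp, y, treatment_name, selector, model, config) {
  scheme <- if (config$shared_split || model == "PLS") "pls_2to1" else "cnn_4to1"
  split <- make_split(nrow(Xp$values), scheme, seed = config$seed)
  sel_rows <- if (config$selection_on == "train") split$train else seq_along(y)
  bands <- NULL
  if (selector != "none") {
    Xsel <- spectrum_matrix(Xp$values[sel_rows, , drop = FALSE], Xp$grid,
                            sample_ids = Xp$sample_ids[sel_rows],
                            tissue = Xp$tissue, variety = Xp$variety)
    res <- if (selector == "CARS") {
      cfg <- config$cars; cfg$seed <- config$seed
      cars_select(Xsel, y[sel_rows], cfg)
    } else {
      cfg <- config$spa; cfg$seed <- config$seed
      spa_select(Xsel, y[sel_rows], cfg)
    }
    bands <- res$selected
  }
  rep <- fit_eval(Xp, y, model = model, scheme = scheme, seed = config$seed,
                  bands = bands, max_lv = config$max_lv,
                  cv_folds = config$cv_folds, cnn = config$cnn)
  rep$treatment <- treatment_name
  rep$selector <- selector
  rep
}

#' Run the full treatment x selector x model grid
#'
#' One [fit_eval()] per grid cell, with the wavelength selector (when any)
#' fitted on the cell's calibration partition only (default). Failures are
#' recorded per cell and do not stop the grid. The returned table mirrors
#' the conventional report layout: Treatment, Input Variable, Rc, RMSEC,
#' Rp, RMSEP, RPD.
#'
#' @param X a [spectrum_matrix()] of raw spectra.
#' @param y numeric target vector.
#' @param config a [grid_config()].
#' @return data frame with one row per cell (columns `treatment`,
#'   `selector`, `model`, `tissue`, `seed`, `n_input_vars`, `n_lv`, `Rc`,
#'   `RMSEC`, `Rp`, `RMSEP`, `RPD`, `sd_test`, `error`); the full
#'   `fit_report` objects are attached as the `"reports"` attribute.
#' @export
run_grid <- function(X, y, config = grid_config()) {
  if (!inherits(X, "spectrum_matrix")) stop("`X` must be a spectrum_matrix")
  if (nrow(X$values) < 60) stop("grid evaluation needs at least 60 samples")
  rows <- list(); reports <- list()
  for (tn in names(config$treatments)) {
    Xp <- tryCatch(preprocess(X, config$treatments[[tn]]), error = function(e) e)
    for (sel in config$selectors) {
      for (mod in config$models) {
        label <- paste(c(if (tn != "Raw") tn, if (sel != "none") sel, mod),
                       collapse = " + ")
        if (tn == "Raw" && sel == "none") label <- paste("Raw +", mod)
        cell <- if (inherits(Xp, "error")) {
          Xp
        } else {
          tryCatch(run_one_cell(Xp, y, tn, sel, mod, config),
                   error = function(e) e)
        }
        if (inherits(cell, "error")) {
          rows[[label]] <- data.frame(
            treatment = tn, selector = sel, model = mod, tissue = X$tissue,
            seed = config$seed, n_input_vars = NA_integer_, n_lv = NA_integer_,
            Rc = NA_real_, RMSEC = NA_real_, Rp = NA_real_, RMSEP = NA_real_,
            RPD = NA_real_, sd_test = NA_real_,
            error = conditionMessage(cell), stringsAsFactors = FALSE
          )
        } else {
          reports[[label]] <- cell
          rows[[label]] <- data.frame(
            treatment = tn, selector = sel, model = mod, tissue = X$tissue,
            seed = config$seed, n_input_vars = cell$n_input_vars,
            n_lv = cell$n_lv, Rc = cell$Rc, RMSEC = cell$RMSEC,
            Rp = cell$Rp, RMSEP = cell$RMSEP, RPD = cell$RPD,
            sd_test = cell$sd_test, error = NA_character_,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$label <- names(rows)
  attr(out, "reports") <- reports
  out
}

#' Rank evaluation reports
#'
#' Sorts by RPD descending, ties broken by RMSEP ascending, and attaches
#' the best report per category (raw full spectrum / pretreated /
#' wavelength-selected) -- the way calibration studies summarize their
#' grids.
#'
#' @param reports data frame from [run_grid()].
#' @return the sorted data frame, with the per-category winners in the
#'   `"best_by_category"` attribute.
#' @export
rank_reports <- function(reports) {
  if (nrow(reports) == 0) stop("no reports to rank")
  ok <- !is.na(reports$RPD)
  ranked <- reports[ok, , drop = FALSE]
  ranked <- ranked[order(-ranked$RPD, ranked$RMSEP), , drop = FALSE]
  category <- with(ranked, ifelse(selector != "none", "selected",
                                  ifelse(treatment == "Raw", "raw", "pretreated")))
  best <- ranked[!duplicated(category), , drop = FALSE]
  best$category <- category[!duplicated(category)]
  out <- rbind(ranked, reports[!ok, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "best_by_category") <- best
  out
}

#' Render a report table in the conventional column layout
#'
#' @param reports data frame from [run_grid()].
#' @return character vector of aligned text lines (Treatment, Input
#'   Variable, Rc, RMSEC, Rp, RMSEP, RPD; correlations and errors at 4
#'   decimals, RPD at 4).
#' @export
format_report_table <- function(reports) {
  df <- data.frame(
    Treatment = reports$label,
    `Input Variable` = reports$n_input_vars,
    Rc = sprintf("%.4f", reports$Rc), RMSEC = sprintf("%.4f", reports$RMSEC),
    Rp = sprintf("%.4f", reports$Rp), RMSEP = sprintf("%.4f", reports$RMSEP),
    RPD = sprintf("%.4f", reports$RPD),
    check.names = FALSE
  )
  c(paste(format(names(df), width = 18), collapse = " "),
    apply(df, 1, function(r) paste(format(r, width = 18), collapse = " ")))
}

#' Write grid reports to CSV and JSON
#'
#' @param reports data frame from [run_grid()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(reports[, setdiff(names(reports), "error")],
                   file.path(dir, "reports.csv"), row.names = FALSE)
  jsonlite::write_json(reports, file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(format_report_table(reports), file.path(dir, "reports.txt"))
  invisible(dir)
}
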