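# small but complete grid study: 3 informative bands among noise so the
# selectors have something to find, modest sizes so cells run in seconds
grid_fixture <- function(n = 80, p = 64, seed = 2) {
  cfg <- synth_config(n_samples = n, peak_centers = c(530, 700, 850),
                      peak_widths = c(15, 25, 20), seed = seed)
  generate_dataset(cfg, small_grid(p))
}

fast_grid_config <- function(...) {
  grid_config(
    treatments = standard_treatments()[c("Raw", "SNV")],
    cars = cars_config(n_runs = 15, cv_folds = 5),
    spa = spa_config(k_max = 8),
    cnn = cnn_spec(batch_size = 16, epochs = 4),
    cv_folds = 5,
    ...
  )
}

test_that("every report satisfies the RPD identity and the size contracts", {
  ds <- grid_fixture()
  out <- run_grid(ds$spectra, ds$targets,
                  fast_grid_config(selectors = c("none", "CARS"),
                                   models = "PLS", seed = 3))
  expect_identical(nrow(out), 4L)
  expect_true(all(is.na(out$error)))
  for (i in seq_len(nrow(out))) {
    expect_equal(out$RPD[i] * out$RMSEP[i], out$sd_test[i], tolerance = 1e-9)
    expect_true(abs(out$Rc[i]) <= 1 && abs(out$Rp[i]) <= 1)
    expect_gte(out$RMSEC[i], 0)
  }
  none_rows <- out$selector == "none"
  expect_true(all(out$n_input_vars[none_rows] == 64L))
  expect_true(all(out$n_input_vars[!none_rows] < 64L))
})

test_that("grid output is seed-deterministic cell by cell", {
  ds <- grid_fixture()
  cfg <- fast_grid_config(selectors = "none", models = c("PLS", "CNN"), seed = 5)
  g1 <- run_grid(ds$spectra, ds$targets, cfg)
  g2 <- run_grid(ds$spectra, ds$targets, cfg)
  expect_equal(g1[, c("Rc", "RMSEC", "Rp", "RMSEP", "RPD")],
               g2[, c("Rc", "RMSEC", "Rp", "RMSEP", "RPD")])
  # running one cell alone reproduces its in-grid result
  solo <- fit_eval(ds$spectra, ds$targets, "PLS", seed = 5, cv_folds = 5)
  row <- g1[g1$model == "PLS" & g1$treatment == "Raw", ]
  expect_equal(row$Rp, solo$Rp, tolerance = 1e-12)
  expect_equal(row$RMSEP, solo$RMSEP, tolerance = 1e-12)
})

test_that("failed cells are recorded without stopping the grid", {
  ds <- grid_fixture(n = 64)
  cfg <- fast_grid_config(selectors = "none", models = "PLS", seed = 1)
  # sabotage one treatment: SNV on a constant spectrum row fails
  ds$spectra$values[1, ] <- 50
  out <- run_grid(ds$spectra, ds$targets, cfg)
  snv_rows <- out$treatment == "SNV"
  expect_true(all(!is.na(out$error[snv_rows])))
  expect_true(all(is.na(out$error[!snv_rows])))
  expect_true(all(is.finite(out$Rp[!snv_rows])))
})

test_that("reports rank by RPD with RMSEP tie-breaking and per-category bests", {
  df <- data.frame(
    treatment = c("Raw", "DET", "DET", "SNV"),
    selector = c("none", "CARS", "none", "none"),
    model = "PLS", tissue = "outer", seed = 1,
    n_input_vars = c(616L, 75L, 616L, 616L), n_lv = 5L,
    Rc = 0.8, RMSEC = 0.4, Rp = c(0.78, 0.86, 0.75, 0.75),
    RMSEP = c(0.43, 0.37, 0.30, 0.40),
    RPD = c(2.30, 2.64, 2.25, 2.25),
    sd_test = 0.98, error = NA_character_,
    label = c("Raw + PLS", "DET + CARS + PLS", "DET + PLS", "SNV + PLS")
  )
  ranked <- rank_reports(df)
  expect_identical(ranked$label[1], "DET + CARS + PLS")   # RPD 2.64 first
  # equal RPD 2.25: smaller RMSEP wins
  expect_lt(which(ranked$label == "DET + PLS"), which(ranked$label == "SNV + PLS"))
  best <- attr(ranked, "best_by_category")
  expect_setequal(best$category, c("raw", "pretreated", "selected"))
  expect_identical(best$label[best$category == "selected"], "DET + CARS + PLS")
  one <- rank_reports(df[1, , drop = FALSE])
  expect_identical(one$label, "Raw + PLS")
})

test_that("report tables and files render in the conventional layout", {
  df <- data.frame(
    treatment = "Raw", selector = "none", model = "PLS", tissue = "inner",
    seed = 1, n_input_vars = 616L, n_lv = 7L,
    Rc = 0.8159, RMSEC = 0.422, Rp = 0.8429, RMSEP = 0.403, RPD = 2.45,
    sd_test = 0.98735, error = NA_character_, label = "Raw + PLS"
  )
  txt <- format_report_table(df)
  expect_match(txt[1], "Rc.*RMSEC.*Rp.*RMSEP.*RPD")
  expect_match(txt[2], "0.8159")
  dir <- tempfile()
  write_reports(df, dir)
  expect_true(all(file.exists(file.path(dir, c("reports.csv", "reports.json",
                                               "reports.txt")))))
  back <- utils::read.csv(file.path(dir, "reports.csv"))
  expect_equal(back$RPD, 2.45)
})

test_that("selection serialization writes JSON and band lists", {
  d <- sparse_signal_data(n = 60, p = 12, seed = 4)
  g <- small_grid(12)
  sm <- spectrum_matrix(d$X + 50, g)
  res <- spa_select(sm, d$y, spa_config(k_max = 5, seed = 2))
  fj <- tempfile(fileext = ".json"); ft <- tempfile(fileext = ".txt")
  write_selection_json(res, fj)
  obj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_identical(obj$method, "SPA")
  expect_identical(as.integer(obj$selected), res$selected)
  write_band_list(res, ft)
  expect_identical(readLines(ft),
                   paste(res$selected_labels, collapse = ","))
})
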