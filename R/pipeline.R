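#' Pipeline run configuration
#'
#' Describes one end-to-end analysis: the input (exactly one of a dataset
#' file / in-memory dataset / simulation config), preprocessing switches, the
#' variable-selection method, the calibration model, tuning parameters, the
#' seed and an optional output directory for reports.
#'
#' @param dataset a [spectral_dataset()], or `NULL`.
#' @param dataset_path path to a dataset file readable by [read_dataset()],
#'   or `NULL`.
#' @param sim_config a [simulation_config()], or `NULL`.
#' @param denoise logical: apply [denoise_dataset()] first?
#' @param selection one of `"full"`, `"ipls"`, `"bipls"`, `"ipls_spa"`,
#'   `"bipls_spa"`.
#' @param model one of `"pls"`, `"svm"`, `"univariate"`, `"index1"`,
#'   `"index2"`.
#' @param k_range interval counts scanned by iPLS/BiPLS.
#' @param max_lv largest PLS latent-variable count.
#' @param spa_max maximum SPA chain length.
#' @param svm_grid SVM hyperparameter grid ([default_svm_grid()]).
#' @param n_pcs SVM principal-component count (`NULL`: chosen by CV).
#' @param max_pcs cap on the SVM component search.
#' @param catalog line catalog for univariate models
#'   (default [default_line_catalog()]).
#' @param seed integer seed funnelling all run randomness.
#' @param output_dir directory for report files, or `NULL` to skip writing.
#' @return An object of class `libs_run_config`.
#' @export
run_config <- function(dataset = NULL, dataset_path = NULL, sim_config = NULL,
                       denoise = TRUE,
                       selection = c("full", "ipls", "bipls", "ipls_spa",
                                     "bipls_spa"),
                       model = c("pls", "svm", "univariate", "index1",
                                 "index2"),
                       k_range = 2:30, max_lv = 10, spa_max = 30,
                       svm_grid = default_svm_grid(), n_pcs = NULL,
                       max_pcs = 13, catalog = NULL, seed = 1,
                       output_dir = NULL) {
  selection <- match.arg(selection)
  model <- match.arg(model)
  sources <- c(!is.null(dataset), !is.null(dataset_path), !is.null(sim_config))
  if (sum(sources) != 1L)
    stop("exactly one of dataset, dataset_path, sim_config must be given")
  if (!is.null(dataset)) stopifnot(inherits(dataset, "libs_dataset"))
  if (!is.null(sim_config)) stopifnot(inherits(sim_config, "libs_sim_config"))
  if (model %in% c("index1", "index2") && selection != "full")
    message("note: index models use fixed lines; selection = \"", selection,
            "\" only affects the reported channel set")
  structure(list(dataset = dataset, dataset_path = dataset_path,
                 sim_config = sim_config, denoise = denoise,
                 selection = selection, model = model, k_range = k_range,
                 max_lv = max_lv, spa_max = spa_max, svm_grid = svm_grid,
                 n_pcs = n_pcs, max_pcs = max_pcs, catalog = catalog,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "libs_run_config")
}

#' Run the full LIBS calibration pipeline
#'
#' Simulate/load -> denoise -> rank-ordered split -> variable selection on
#' the calibration set -> model fitting on the calibration set -> evaluation
#' on the held-out prediction set -> optional report files. Variable
#' selection, latent-variable/hyperparameter choice and PCA loadings use the
#' calibration samples only; the prediction set enters only the final
#' metrics. Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @return An object of class `libs_run_report`: list with `config` (echo of
#'   scalar parameters), `data`, `split`, `selection`, `model`, `metrics`
#'   (or `table` for `model = "univariate"`), and per-stage `timings`
#'   (seconds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "libs_run_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  set.seed(config$seed)
  data <- if (!is.null(config$dataset)) {
    config$dataset
  } else if (!is.null(config$dataset_path)) {
    read_dataset(config$dataset_path)
  } else {
    sim <- config$sim_config
    if (is.null(sim$seed)) sim$seed <- config$seed
    simulate_dataset(sim)
  }
  timings["load"] <- tic() - t0; t0 <- tic()

  if (isTRUE(config$denoise)) data <- denoise_dataset(data)
  timings["denoise"] <- tic() - t0; t0 <- tic()

  split <- split_rank_ordered(data$reference)
  cal <- subset_dataset(data, split$calibration)
  timings["split"] <- tic() - t0; t0 <- tic()

  selection <- switch(config$selection,
    full = selection_result("full", cal, seq_along(cal$wavelengths)),
    ipls = ipls_select(cal, config$k_range, config$max_lv),
    bipls = bipls_select(cal, config$k_range, config$max_lv),
    ipls_spa = {
      pre <- ipls_select(cal, config$k_range, config$max_lv)
      out <- spa_select(cal, pre$channels, config$spa_max)
      out$method <- "ipls_spa"; out$pre_selection <- pre; out
    },
    bipls_spa = {
      pre <- bipls_select(cal, config$k_range, config$max_lv)
      out <- spa_select(cal, pre$channels, config$spa_max)
      out$method <- "bipls_spa"; out$pre_selection <- pre; out
    })
  timings["selection"] <- tic() - t0; t0 <- tic()

  pred <- subset_dataset(data, split$prediction)
  ch <- selection$channels
  report <- list(config = config[setdiff(names(config),
                                         c("dataset", "sim_config"))],
                 data = data, split = split, selection = selection)

  if (config$model == "pls") {
    Xc <- cal$intensities[, ch, drop = FALSE]
    lv <- choose_lv_loocv(Xc, cal$reference, config$max_lv)
    model <- fit_pls(Xc, cal$reference, lv$n_lv, channels = ch)
    report$model <- model
    report$metrics <- evaluate(model, Xc, cal$reference,
                               pred$intensities[, ch, drop = FALSE],
                               pred$reference)
  } else if (config$model == "svm") {
    Xc <- cal$intensities[, ch, drop = FALSE]
    # a narrow selection (e.g. after SPA) can support fewer components than
    # the configured default; cap rather than error
    n_pcs <- config$n_pcs
    if (!is.null(n_pcs)) n_pcs <- min(n_pcs, nrow(Xc) - 1L, ncol(Xc))
    model <- fit_svm_pcs(Xc, cal$reference, n_pcs = n_pcs,
                         grid = config$svm_grid, seed = config$seed,
                         max_pcs = config$max_pcs)
    report$model <- model
    report$metrics <- evaluate(model, Xc, cal$reference,
                               pred$intensities[, ch, drop = FALSE],
                               pred$reference)
  } else if (config$model == "univariate") {
    catalog <- config$catalog
    if (is.null(catalog)) {
      catalog <- default_line_catalog()
      catalog <- catalog[catalog$element == "Cd", ]
    }
    if (config$selection != "full")
      catalog <- lines_in_ranges(catalog, selection$wavelength_ranges[, 1:2])
    if (!nrow(catalog))
      stop("no catalogued lines fall inside the selected wavelength ranges")
    report$table <- univariate_table(data, split, catalog)
  } else {                                 # index1 / index2
    i508 <- extract_line(data, 508.58)
    i466 <- extract_line(data, 466.23)
    x <- if (config$model == "index1") {
      index1(i508, extract_line(data, 361.05), i466)
    } else {
      index2(i508, i466)
    }
    model <- fit_univariate(x, data$reference, split)
    report$model <- model
    report$metrics <- model$metrics
  }
  timings["model"] <- tic() - t0
  report$timings <- timings
  report <- structure(report, class = "libs_run_report")
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.libs_run_report <- function(x, ...) {
  cat("<libs_run_report> selection=", x$config$selection, " model=",
      x$config$model, " seed=", x$config$seed, "\n", sep = "")
  if (!is.null(x$selection))
    cat("  ", length(x$selection$channels), " selected channels\n", sep = "")
  if (!is.null(x$metrics)) print(x$metrics)
  if (!is.null(x$table)) print(x$table, digits = 4)
  invisible(x)
}

#' Write the report files of a pipeline run
#'
#' Emits, into `dir`: `metrics.tsv` (method, model, channel count, factor,
#' R2c, RMSECV, R2p, RMSEP — one row, or one per line for univariate runs),
#' `selection_channels.tsv` / `selection_ranges.tsv`, `split.tsv`, and
#' `run_info.yaml` (parameter echo, seed and stage timings).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "libs_run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  if (!is.null(report$metrics)) {
    m <- report$metrics
    factor_n <- if (!is.null(report$model$n_lv)) report$model$n_lv
                else if (!is.null(report$model$n_pcs)) report$model$n_pcs
                else 1L
    tab <- data.frame(method = cfg$selection, model = cfg$model,
                      n_channels = length(report$selection$channels),
                      factor = factor_n, r2_cal = m$r2_cal,
                      rmsecv = m$rmsecv, r2_pred = m$r2_pred, rmsep = m$rmsep)
  } else {
    tab <- cbind(method = cfg$selection, model = cfg$model, report$table)
  }
  data.table::fwrite(tab, file.path(dir, "metrics.tsv"), sep = "\t")
  write_selection(report$selection, file.path(dir, "selection"))
  write_split(report$split, report$data$ids, file.path(dir, "split.tsv"))
  info <- list(selection = cfg$selection, model = cfg$model, seed = cfg$seed,
               denoise = cfg$denoise, k_range = range(cfg$k_range),
               max_lv = cfg$max_lv, spa_max = cfg$spa_max,
               timings_sec = as.list(round(report$timings, 3)))
  yaml::write_yaml(info, file.path(dir, "run_info.yaml"))
  invisible(dir)
}
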