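#' Run the full multi-area LUR pipeline
#'
#' One call from study (simulated or on disk) to reports: simulate (optional)
#' -> extract predictors -> temporally adjust the seasonal samples -> build
#' the combined stepwise model -> evaluate (hold-out validation, LOAOCV,
#' Model_intra) -> transferability. Every stage logs its counts to standard
#' error and all outputs land in one directory with a `manifest.json` of
#' md5 hashes, so a re-run with the same seed is verifiably identical.
#'
#' @param config A list with components:
#'   \describe{
#'     \item{simulate}{list with `config` (a [study_config()]), `variables`
#'       (a [lur_variables()] set), `true_sd` (named vector passed to
#'       [true_model_from_sd()]), and optional `intercept`,
#'       `background_weight`, `mode` (`"geometry"` or `"tabular"`); mutually
#'       exclusive with `paths`.}
#'     \item{paths}{list of input files: `sites`, `roads`, `rasters` (named
#'       vector by area or single path), `measurements`, `reference`,
#'       `predictors` optional; `variables` must then be supplied as an R
#'       object in `config$variables`.}
#'     \item{options}{[lur_options()]; default used when absent.}
#'     \item{evaluation}{list: `holdout_fraction` (default 0.25; `NULL`
#'       disables HV), `loaocv` (default `TRUE`), `transfer` (default
#'       `TRUE`).}
#'     \item{seed}{integer; required whenever any stochastic stage runs.}
#'     \item{out}{output directory.}
#'   }
#' @param verbose Log stage progress to standard error (default `TRUE`).
#' @return A list with `model`, `holdout`, `loaocv_report`, `model_intra`,
#'   `transfer`, `manifest` (invisible file hashes), and `data`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  log_msg <- function(...) if (verbose) message(sprintf(...))
  if (is.null(config$out)) stop_data("run_pipeline: config$out is required")
  has_sim <- !is.null(config$simulate)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths)
    stop_data("run_pipeline: exactly one of config$simulate / config$paths")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  ev <- utils::modifyList(list(holdout_fraction = 0.25, loaocv = TRUE,
                               transfer = TRUE),
                          config$evaluation %||% list())
  if (is.null(config$seed) && (has_sim || !is.null(ev$holdout_fraction)))
    stop_data("run_pipeline: seed required for stochastic stages")

  if (has_sim) {
    sim <- config$simulate
    scfg <- sim$config
    scfg$seed <- as.integer(config$seed)
    log_msg("[simulate] %d areas x %d sites, seed %d",
            scfg$n_areas, scfg$sites_per_area, scfg$seed)
    study <- generate_study(scfg)
    mode <- sim$mode %||% if (scfg$geometry) "geometry" else "tabular"
    table <- generate_predictor_table(study, sim$variables, mode = mode)
    tm <- true_model_from_sd(table, sim$true_sd,
                             intercept = sim$intercept %||% 0,
                             background_weight = sim$background_weight %||% 1)
    campaign <- generate_concentrations(study, table, tm)
    write_study(study, campaign, config$out)
    sites <- study$sites
    seasonal <- campaign$seasonal
    reference <- campaign$reference
    vars <- sim$variables
  } else {
    p <- config$paths
    st <- read_site_table(p$sites)
    sites <- st$sites
    seasonal <- read_measurements(p$measurements)
    reference <- read_reference(p$reference)
    vars <- config$variables
    if (is.null(vars)) stop_data("run_pipeline: config$variables required")
    if (!is.null(p$predictors)) {
      pv <- read_csv_strict(p$predictors, "site_id")
      table <- predictor_table(pv, vars)
    } else {
      roads <- read_roads(p$roads)
      rasters <- if (length(p$rasters) > 1L || !is.null(names(p$rasters)))
        lapply(p$rasters, read_raster) else read_raster(p$rasters)
      table <- extract_predictors(sites, roads, rasters, vars)
    }
  }
  if (has_sim) {
    # predictors already extracted above in the simulate branch
  }
  log_msg("[extract] %d sites x %d predictors", nrow(table$values),
          nrow(table$vars))
  utils::write.csv(table$values, file.path(config$out, "predictors.csv"),
                   row.names = FALSE, quote = FALSE)

  annual <- adjust_measurements(seasonal, reference, sites)
  log_msg("[adjust] %d annual averages from %d samples", nrow(annual),
          nrow(seasonal))
  utils::write.csv(annual, file.path(config$out, "annual_adjusted.csv"),
                   row.names = FALSE, quote = FALSE)

  data <- lur_data(sites, table, annual)
  options <- config$options %||% lur_options()
  model <- supervised_stepwise(data, options)
  log_msg("[build] %d terms, R2 %.3f", nrow(model$terms), model$r2)
  write_model(model, file.path(config$out, "model.json"))

  intra <- model_intra_r2(model, data)
  jsonlite::write_json(intra, file.path(config$out, "model_intra.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  holdout <- NULL
  if (!is.null(ev$holdout_fraction)) {
    split <- stratified_holdout_split(sites, ev$holdout_fraction,
                                      seed = config$seed)
    holdout <- holdout_validate(data, split, options)
    log_msg("[holdout] HV R2 %.3f, RMSE %.3f, %d cells truncated",
            holdout$overall_r2, holdout$rmse, holdout$truncated)
    write_report_json(holdout, file.path(config$out, "holdout.json"))
  }
  cv <- NULL
  if (isTRUE(ev$loaocv)) {
    cv <- loaocv(data, options)
    log_msg("[loaocv] %d refits, pooled R2 %.3f", cv$n_models, cv$overall_r2)
    write_report_json(cv, file.path(config$out, "loaocv.json"))
  }
  transfer <- NULL
  if (isTRUE(ev$transfer)) {
    transfer <- transfer_excluding_each_area(data, options)
    log_msg("[transfer] %d refits, median TRANS_intra R2 %.3f",
            transfer$n_models,
            transfer$summary$trans_intra_r2[["median"]])
    jsonlite::write_json(list(per_area = transfer$per_area,
                              summary = transfer$summary),
                         file.path(config$out, "transfer.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(transfer$per_area,
                     file.path(config$out, "transfer_per_area.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  files <- sort(list.files(config$out, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = config$seed,
                   n_sites = nrow(sites),
                   n_areas = length(unique(sites$area_code)),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("[done] %d output files in %s", length(files), config$out)
  invisible(list(model = model, holdout = holdout, loaocv_report = cv,
                 model_intra = intra, transfer = transfer,
                 manifest = manifest, data = data))
}

write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(overall_r2 = report$overall_r2, overall_r2_mse = report$overall_r2_mse,
         rmse = report$rmse, median_r2 = report$median_r2,
         iqr_r2 = report$iqr_r2, median_slope = report$median_slope,
         iqr_slope = report$iqr_slope, truncated = report$truncated,
         split = report$split, n = report$n, per_area = report$per_area),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
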