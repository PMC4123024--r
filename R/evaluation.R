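#' Squared Pearson correlation between predictions and observations
#'
#' The validation R-squared used throughout: the square of the Pearson
#' correlation coefficient. Note it is sign-blind (perfectly anti-correlated
#' predictions also score 1) and hides calibration bias; the MSE-based
#' variant `1 - SSE/SST` is reported alongside in evaluation reports as a
#' secondary diagnostic.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return Squared Pearson correlation, or `NA` when either vector is
#'   constant or fewer than 3 pairs are available.
#' @export
pearson_r2 <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) return(NA_real_)
  stats::cor(pred[ok], obs[ok])^2
}

#' Root mean squared error
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return `sqrt(mean((pred - obs)^2))`, in concentration units.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 1L)
  sqrt(mean((pred - obs)^2))
}

r2_mse <- function(pred, obs) {
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Per-area agreement metrics
#'
#' For every area with at least 3 evaluable sites: the squared Pearson
#' correlation and the least-squares slope of predictions regressed on
#' observations (so a slope below 1 expresses compression of the predicted
#' contrasts). Smaller areas are reported with `NA` metrics rather than
#' silently dropped.
#'
#' @param pred,obs Numeric vectors.
#' @param area Area labels, same length.
#' @return List with `per_area` data frame (`area`, `n`, `r2`, `slope`,
#'   `rmse`) and `median_r2`, `iqr_r2`, `median_slope`, `iqr_slope`
#'   (75th - 25th percentile, linear-interpolation quantiles).
#' @export
per_area_metrics <- function(pred, obs, area) {
  areas <- sort(unique(area))
  rows <- lapply(areas, function(a) {
    i <- area == a
    n <- sum(i)
    if (n < 3L) {
      warning(sprintf("area '%s' has %d site(s); metrics reported as NA", a, n))
      return(data.frame(area = a, n = n, r2 = NA_real_, slope = NA_real_,
                        rmse = NA_real_, stringsAsFactors = FALSE))
    }
    sl <- if (stats::sd(obs[i]) > 0)
      sum((obs[i] - mean(obs[i])) * (pred[i] - mean(pred[i]))) /
        sum((obs[i] - mean(obs[i]))^2) else NA_real_
    data.frame(area = a, n = n, r2 = pearson_r2(pred[i], obs[i]),
               slope = sl, rmse = rmse(pred[i], obs[i]),
               stringsAsFactors = FALSE)
  })
  per_area <- do.call(rbind, rows)
  list(per_area = per_area,
       median_r2 = median_na(per_area$r2), iqr_r2 = iqr_linear(per_area$r2),
       median_slope = median_na(per_area$slope),
       iqr_slope = iqr_linear(per_area$slope))
}

new_evaluation_report <- function(pred, obs, area, split, truncated,
                                  extra = list()) {
  pa <- per_area_metrics(pred, obs, area)
  structure(c(list(
    overall_r2 = pearson_r2(pred, obs),
    overall_r2_mse = r2_mse(pred, obs),
    rmse = rmse(pred, obs),
    per_area = pa$per_area,
    median_r2 = pa$median_r2, iqr_r2 = pa$iqr_r2,
    median_slope = pa$median_slope, iqr_slope = pa$iqr_slope,
    truncated = truncated, split = split, n = length(pred)), extra),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s: overall R2 %.3f, RMSE %.3f (n = %d)\n", x$split,
              x$overall_r2, x$rmse, x$n))
  cat(sprintf("  per-area R2 median %.3f (IQR %.3f), slope median %.3f\n",
              x$median_r2, x$iqr_r2, x$median_slope))
  if (x$truncated > 0)
    cat(sprintf("  %d predictor cell(s) truncated to training range\n",
                x$truncated))
  invisible(x)
}

#' Within-area fit of a combined model (Model_intra R-squared)
#'
#' Applies the combined multi-area model to each area's own training sites
#' and reports the per-area squared Pearson correlation with its median and
#' IQR: the quantity directly comparable with the R-squared of city-specific
#' models. No truncation is involved (training sites are inside the training
#' ranges by construction).
#'
#' @param model A `lur_model` fitted on `data`.
#' @param data The [lur_data()] used for fitting.
#' @return List with `per_area`, `median_r2`, `iqr_r2`.
#' @export
model_intra_r2 <- function(model, data) {
  pred <- predict(model, data, truncate = FALSE)
  pa <- per_area_metrics(pred, data$annual$value, data$sites$area_code)
  list(per_area = pa$per_area, median_r2 = pa$median_r2, iqr_r2 = pa$iqr_r2)
}

#' Leave-one-area-out cross-validation
#'
#' For each of the M areas, refits the full supervised stepwise model on the
#' remaining M-1 areas, predicts the left-out area with predictor truncation,
#' and pools all left-out predictions for the overall R-squared and RMSE.
#' Exactly M models are fitted. The left-out area's regional background value
#' is computed from its own regional background sites (the minimal
#' measurement any area must supply).
#'
#' @param data A [lur_data()] with at least 2 areas.
#' @param options [lur_options()].
#' @param truncate Truncate predictors to each training model's ranges
#'   (default `TRUE`).
#' @return An `evaluation_report`; the refitted models are attached as
#'   attribute `"models"` (named by left-out area).
#' @export
loaocv <- function(data, options = lur_options(), truncate = TRUE) {
  areas <- sort(unique(data$sites$area_code))
  if (length(areas) < 2L)
    stop_data("loaocv: need at least 2 areas")
  pred <- obs <- numeric(0); lab <- character(0)
  truncated <- 0L
  models <- vector("list", length(areas))
  names(models) <- areas
  for (a in areas) {
    train <- subset_areas(data, setdiff(areas, a))
    test <- subset_areas(data, a)
    m <- supervised_stepwise(train, options)
    p <- predict(m, test, truncate = truncate)
    truncated <- truncated + attr(p, "truncated")
    pred <- c(pred, p); obs <- c(obs, test$annual$value)
    lab <- c(lab, test$sites$area_code)
    models[[a]] <- m
  }
  rep <- new_evaluation_report(pred, obs, lab, "leave-one-area-out CV",
                               truncated,
                               extra = list(n_models = length(areas)))
  attr(rep, "models") <- models
  rep
}

#' Stratified hold-out split of monitoring sites
#'
#' Draws, independently within every area, a simple random sample of
#' `round(fraction * n_area)` sites into the test set. A designated split
#' (e.g. paired-measurement sites as training, single-pollutant sites as
#' test) is requested by passing the test site ids explicitly. Deterministic
#' for a fixed seed; an area with a single site stays entirely in training
#' with a warning.
#'
#' @param sites Site table.
#' @param fraction Test fraction in (0, 1); ignored when `test_ids` given.
#' @param seed Integer seed for the random draw.
#' @param test_ids Optional character vector of designated test site ids.
#' @return List with `train_ids` and `test_ids`.
#' @export
stratified_holdout_split <- function(sites, fraction = 0.25, seed = 1L,
                                     test_ids = NULL) {
  if (!is.null(test_ids)) {
    unknown <- setdiff(test_ids, sites$site_id)
    if (length(unknown))
      stop_data("stratified_holdout_split: unknown site id '%s'", unknown[1L])
    return(list(train_ids = setdiff(sites$site_id, test_ids),
                test_ids = test_ids))
  }
  if (!(fraction > 0 && fraction < 1))
    stop_data("stratified_holdout_split: fraction must be in (0, 1)")
  test <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(sites$site_id, sites$area_code), function(ids) {
      if (length(ids) < 2L) {
        warning("stratum with a single site left entirely in training")
        return(character(0))
      }
      k <- round(fraction * length(ids))
      if (k == 0L) return(character(0))
      sample(ids, k)
    }), use.names = FALSE)
  })
  list(train_ids = setdiff(sites$site_id, test), test_ids = test)
}

#' Hold-out validation
#'
#' Fits the model on the training sites only and evaluates predictions at
#' the held-out sites (with predictor truncation by default): the measure of
#' predictive power at independent locations within the modeled areas.
#'
#' @param data Full [lur_data()].
#' @param split A list with disjoint non-empty `train_ids` and `test_ids`
#'   (see [stratified_holdout_split()]).
#' @param options [lur_options()].
#' @param truncate Truncate predictors to training ranges (default `TRUE`).
#' @return An `evaluation_report` with the fitted model attached as
#'   attribute `"model"`.
#' @export
holdout_validate <- function(data, split, options = lur_options(),
                             truncate = TRUE) {
  if (!length(split$train_ids) || !length(split$test_ids))
    stop_data("holdout_validate: empty training or test set")
  if (length(intersect(split$train_ids, split$test_ids)))
    stop_data("holdout_validate: training and test sets overlap")
  keep <- function(ids) {
    s <- data$sites[data$sites$site_id %in% ids, , drop = FALSE]
    lur_data(s,
             predictor_table(data$predictors$values[
               data$predictors$values$site_id %in% ids, , drop = FALSE],
               data$predictors$vars),
             data$annual[data$annual$site_id %in% ids, , drop = FALSE])
  }
  train <- keep(split$train_ids)
  test <- keep(split$test_ids)
  # the regional background variable is an area-level covariate computed from
  # the campaign's regional background sites; carry it from the full data so
  # the split does not redefine it
  bg_full <- regional_background_variable(data$annual, data$sites)
  names(bg_full) <- data$sites$site_id
  add_bg <- function(d) {
    if ("regional_background" %in% d$predictors$vars$name) return(d)
    v <- d$predictors$values
    v$regional_background <- unname(bg_full[v$site_id])
    d$predictors <- predictor_table(
      v, rbind(d$predictors$vars,
               lur_variable("regional_background", "regional_background",
                            direction = "positive", forced = TRUE)))
    d
  }
  if (options$force_background) { train <- add_bg(train); test <- add_bg(test) }
  m <- supervised_stepwise(train, options)
  p <- predict(m, test, truncate = truncate)
  rep <- new_evaluation_report(p, test$annual$value, test$sites$area_code,
                               "hold-out validation",
                               attr(p, "truncated"))
  attr(rep, "model") <- m
  rep
}
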