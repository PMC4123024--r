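#' Area-exclusion transferability analysis
#'
#' Rebuilds the combined model once for every study area with that area's
#' observations completely excluded, then applies the transferred model
#' directly to the excluded area's sites (with predictor truncation). The
#' TRANS_intra R-squared — the squared Pearson correlation between observed
#' and predicted values in the excluded area — measures how well the model
#' transfers to an area that contributed nothing to model building. The
#' excluded area's regional background value is computed from its own
#' regional background sites, the minimal measurement a new area must
#' supply. M areas produce exactly M refitted models.
#'
#' @param data A [lur_data()] with at least 3 areas.
#' @param options [lur_options()].
#' @param truncate Truncate predictors to training ranges (default `TRUE`).
#' @return A `transfer_report`: `per_area` data frame (one row per excluded
#'   area: refit `model_r2`, refit median `model_intra_r2`, `trans_intra_r2`,
#'   `rmse`, `truncated`, `n_terms`, `terms`), `summary` list of
#'   median/IQR over areas, and the refitted models as attribute `"models"`.
#' @export
transfer_excluding_each_area <- function(data, options = lur_options(),
                                         truncate = TRUE) {
  areas <- sort(unique(data$sites$area_code))
  if (length(areas) < 3L)
    stop_data("transfer_excluding_each_area: need at least 3 areas")
  models <- vector("list", length(areas))
  names(models) <- areas
  rows <- vector("list", length(areas))
  for (k in seq_along(areas)) {
    a <- areas[k]
    train <- subset_areas(data, setdiff(areas, a))
    test <- subset_areas(data, a)
    m <- supervised_stepwise(train, options)
    stopifnot(a %in% m$provenance$excluded_areas)
    p <- predict(m, test, truncate = truncate)
    intra <- model_intra_r2(m, train)
    models[[a]] <- m
    rows[[k]] <- data.frame(
      area = a,
      model_r2 = m$r2,
      model_intra_r2 = intra$median_r2,
      trans_intra_r2 = pearson_r2(p, test$annual$value),
      rmse = rmse(p, test$annual$value),
      truncated = attr(p, "truncated"),
      n_terms = nrow(m$terms),
      terms = paste(m$terms$name, collapse = "+"),
      stringsAsFactors = FALSE)
  }
  per_area <- do.call(rbind, rows)
  summary <- list(
    model_r2 = c(median = median_na(per_area$model_r2),
                 iqr = iqr_linear(per_area$model_r2)),
    model_intra_r2 = c(median = median_na(per_area$model_intra_r2),
                       iqr = iqr_linear(per_area$model_intra_r2)),
    trans_intra_r2 = c(median = median_na(per_area$trans_intra_r2),
                       iqr = iqr_linear(per_area$trans_intra_r2)),
    rmse = c(median = median_na(per_area$rmse),
             iqr = iqr_linear(per_area$rmse)))
  rep <- structure(list(per_area = per_area, summary = summary,
                        n_models = length(areas)),
                   class = "transfer_report")
  attr(rep, "models") <- models
  rep
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("transferability: %d area-exclusion refits\n", x$n_models))
  s <- x$summary
  cat(sprintf("  model R2       median %.3f (IQR %.3f)\n",
              s$model_r2[["median"]], s$model_r2[["iqr"]]))
  cat(sprintf("  Model_intra R2 median %.3f (IQR %.3f)\n",
              s$model_intra_r2[["median"]], s$model_intra_r2[["iqr"]]))
  cat(sprintf("  TRANS_intra R2 median %.3f (IQR %.3f)\n",
              s$trans_intra_r2[["median"]], s$trans_intra_r2[["iqr"]]))
  cat(sprintf("  RMSE           median %.3f (IQR %.3f)\n",
              s$rmse[["median"]], s$rmse[["iqr"]]))
  invisible(x)
}
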