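#' Annual mean of a continuous reference series
#'
#' @param reference Data frame with `period` and `value` columns (one area's
#'   continuous series), or a numeric vector of period values.
#' @return Arithmetic mean over periods (ug/m3).
#' @export
reference_annual_mean <- function(reference) {
  v <- if (is.data.frame(reference)) reference$value else reference
  if (!length(v)) stop_data("reference_annual_mean: empty reference series")
  mean(v)
}

#' Temporally adjusted annual average for one site
#'
#' Converts a handful of 2-week samples into an annual average using the
#' difference method: each sample is corrected by the deviation of the
#' concurrent reference-site value from the reference annual mean,
#' `adjusted = mean(sample - (ref_period - ref_annual_mean))`. When the
#' site shares the reference's temporal deviations, this recovers the true
#' annual average exactly; with a constant reference it reduces to the plain
#' mean of the samples.
#'
#' @param values Numeric vector of the site's sample concentrations (ug/m3).
#' @param periods Periods of those samples; each must occur in the reference
#'   series.
#' @param reference Data frame with `period` and `value` for the site's area.
#' @return Adjusted annual average (ug/m3). Fewer than 3 samples triggers a
#'   warning and the result is computed on the available samples.
#' @export
adjust_annual_average <- function(values, periods, reference) {
  if (!length(values)) stop_data("adjust_annual_average: no samples")
  if (length(values) < 3L)
    warning(sprintf("only %d sample(s) available; annual average computed on those",
                    length(values)))
  i <- match(periods, reference$period)
  if (anyNA(i))
    stop_data("adjust_annual_average: period(s) %s missing from reference series",
              paste(periods[is.na(i)], collapse = ", "))
  ref_mean <- reference_annual_mean(reference)
  mean(values - (reference$value[i] - ref_mean))
}

#' Temporally adjust a whole campaign
#'
#' Applies [adjust_annual_average()] per site, matching each site to its
#' area's reference series.
#'
#' @param seasonal Measurement table: `site_id`, `period`, `value`.
#' @param reference Reference table: `area_code`, `period`, `value`.
#' @param sites Site table mapping `site_id` to `area_code`.
#' @return Data frame `site_id`, `value` (adjusted annual average), in site
#'   order of first appearance.
#' @export
adjust_measurements <- function(seasonal, reference, sites) {
  area_of <- sites$area_code[match(seasonal$site_id, sites$site_id)]
  if (anyNA(area_of))
    stop_data("adjust_measurements: measurement for unknown site '%s'",
              seasonal$site_id[is.na(area_of)][1L])
  ids <- unique(seasonal$site_id)
  refs <- split(reference, reference$area_code)
  vals <- vapply(ids, function(id) {
    rows <- seasonal$site_id == id
    adjust_annual_average(seasonal$value[rows], seasonal$period[rows],
                          refs[[area_of[rows][1L]]])
  }, 0)
  data.frame(site_id = ids, value = unname(vals), stringsAsFactors = FALSE)
}
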