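#' Extract buffer-based GIS predictors for monitoring sites
#'
#' Computes every variable in `vars` for every site from the road network and
#' land-use raster(s): road length and traffic load in discs and rings, major
#' road length, nearest-road traffic intensity, and land-use class areas.
#' Variables of category `regional_background` are skipped here (they are
#' derived from the measurements by the model builder), and `other_local`
#' variables are only available from the tabular generator.
#'
#' @param sites Site table (see [lur_data()]).
#' @param roads Road-segment table: `segment_id`, `x1, y1, x2, y2`,
#'   `intensity`, `is_major`.
#' @param rasters A single [lur_raster()] covering all sites, or a named list
#'   of rasters keyed by `area_code`.
#' @param vars A [lur_variables()] definition table.
#' @return A [predictor_table()] with columns in the order of `vars`.
#' @export
extract_predictors <- function(sites, roads, rasters, vars) {
  check_sites(sites)
  keep <- vars$category != "regional_background"
  vars_use <- vars[keep, , drop = FALSE]
  if (any(vars_use$category == "other_local"))
    stop_data("extract_predictors: variable '%s' (other_local) has no geometry",
              vars_use$name[vars_use$category == "other_local"][1L])
  n <- nrow(sites)
  out <- matrix(0, nrow = n, ncol = nrow(vars_use),
                dimnames = list(NULL, vars_use$name))
  per_area <- is.list(rasters) && !inherits(rasters, "lur_raster")
  for (i in seq_len(n)) {
    ctr <- c(sites$x[i], sites$y[i])
    ras <- if (per_area) rasters[[sites$area_code[i]]] else rasters
    for (j in seq_len(nrow(vars_use))) {
      v <- vars_use[j, ]
      out[i, j] <- switch(
        v$category,
        traffic_load = if (!is.na(v$inner_radius))
          ring_sum(ctr, roads, v$inner_radius, v$buffer_radius, "intensity")
        else buffer_sum(ctr, roads, v$buffer_radius, "intensity"),
        road_length = if (!is.na(v$inner_radius))
          ring_sum(ctr, roads, v$inner_radius, v$buffer_radius, "unit")
        else buffer_sum(ctr, roads, v$buffer_radius, "unit"),
        major_road_length = buffer_sum(ctr, roads, v$buffer_radius, "unit",
                                       major_only = TRUE),
        nearest_road_intensity = nearest_road_intensity(ctr, roads),
        land_use_area = {
          if (is.null(ras))
            stop_data("extract_predictors: no raster for area '%s'",
                      sites$area_code[i])
          raster_class_area_in_disc(ras, ctr, v$buffer_radius,
                                    v$classes[[1L]])
        },
        stop_data("extract_predictors: unknown category '%s'", v$category))
    }
  }
  predictor_table(cbind(data.frame(site_id = sites$site_id,
                                   stringsAsFactors = FALSE),
                        as.data.frame(out)),
                  vars_use)
}
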