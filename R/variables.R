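#' Define a candidate predictor variable
#'
#' A variable definition records how a predictor is computed (its category and
#' buffer geometry), the a-priori direction of effect that the stepwise
#' selection enforces, and whether the variable is forced into the model
#' unconditionally (as the regional background concentration is in combined
#' multi-area models).
#'
#' @param name Variable name, unique within a variable set.
#' @param category One of `"traffic_load"`, `"road_length"`,
#'   `"major_road_length"`, `"land_use_area"`, `"nearest_road_intensity"`,
#'   `"regional_background"`, `"other_local"`.
#' @param buffer_radius Buffer radius in meters (`NA` for point variables such
#'   as nearest-road intensity).
#' @param inner_radius Inner radius in meters for ring variables (e.g. traffic
#'   load between 50 m and 1,000 m); `NA` for plain discs.
#' @param direction A-priori direction of effect, `"positive"` or
#'   `"negative"`. Candidates whose fitted coefficient contradicts this are
#'   never admitted.
#' @param forced Logical; forced variables enter the model first and are exempt
#'   from p-value pruning and VIF removal.
#' @param classes Integer vector of land-use class codes summed by
#'   `land_use_area` variables (see [landuse_classes()]).
#' @param meanlog,sdlog Log-normal marginal parameters used by the tabular
#'   predictor generator; defaults per category are filled in when `NA`.
#' @return A one-row data frame; combine rows with [lur_variables()].
#' @seealso [lur_variables()], [default_variable_set()]
#' @export
lur_variable <- function(name, category,
                         buffer_radius = NA_real_, inner_radius = NA_real_,
                         direction = "positive", forced = FALSE,
                         classes = NULL, meanlog = NA_real_, sdlog = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  cats <- c("traffic_load", "road_length", "major_road_length", "land_use_area",
            "nearest_road_intensity", "regional_background", "other_local")
  category <- match.arg(category, cats)
  direction <- match.arg(direction, c("positive", "negative"))
  if (!is.na(inner_radius) && !is.na(buffer_radius) &&
      buffer_radius <= inner_radius)
    stop_data("variable '%s': buffer_radius must exceed inner_radius", name)
  d <- data.frame(name = name, category = category,
                  buffer_radius = as.numeric(buffer_radius),
                  inner_radius = as.numeric(inner_radius),
                  direction = direction, forced = isTRUE(forced),
                  meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog),
                  stringsAsFactors = FALSE)
  d$classes <- list(if (is.null(classes)) integer(0) else as.integer(classes))
  d
}

#' Combine variable definitions into a variable set
#'
#' @param ... One-row definitions from [lur_variable()] (or data frames of
#'   such rows).
#' @return A `lur_variables` data frame, one row per variable.
#' @export
lur_variables <- function(...) {
  defs <- do.call(rbind, list(...))
  if (anyDuplicated(defs$name))
    stop_data("duplicate variable name: %s",
              defs$name[duplicated(defs$name)][1L])
  class(defs) <- c("lur_variables", "data.frame")
  defs
}

#' Land-use class codes used by the synthetic raster
#' @return Named integer vector mapping class labels to raster codes.
#' @export
landuse_classes <- function() {
  c(natural_green = 1L, residential = 2L, other = 3L)
}

# tabular-mode marginal defaults by category (lognormal, meters / vehicles)
default_marginal <- function(category) {
  switch(category,
         traffic_load            = c(meanlog = 12.0, sdlog = 1.0),
         road_length             = c(meanlog = 8.0,  sdlog = 0.7),
         major_road_length       = c(meanlog = 7.0,  sdlog = 0.9),
         land_use_area           = c(meanlog = 14.0, sdlog = 0.8),
         nearest_road_intensity  = c(meanlog = 8.5,  sdlog = 1.0),
         other_local             = c(meanlog = 9.0,  sdlog = 0.8),
         c(meanlog = 9.0, sdlog = 0.8))
}

#' Default multi-area candidate variable set
#'
#' The candidate set mirrors the variables that dominate combined European LUR
#' models: traffic load and road length in small and large buffers, a 50 m to
#' 1,000 m traffic-load ring, nearest-road traffic intensity, and natural/green
#' land-use area in a 5,000 m buffer (negative direction). The regional
#' background concentration is not listed here; it is computed from the
#' measurements and forced by the model builder.
#'
#' @return A [lur_variables()] data frame.
#' @export
default_variable_set <- function() {
  lur_variables(
    lur_variable("traffic_load_50", "traffic_load", buffer_radius = 50),
    lur_variable("traffic_load_50_1000", "traffic_load",
                 buffer_radius = 1000, inner_radius = 50),
    lur_variable("road_length_100", "road_length", buffer_radius = 100),
    lur_variable("road_length_1000", "road_length", buffer_radius = 1000),
    lur_variable("major_road_length_300", "major_road_length",
                 buffer_radius = 300),
    lur_variable("nearest_road_intensity", "nearest_road_intensity"),
    lur_variable("natural_green_5000", "land_use_area", buffer_radius = 5000,
                 direction = "negative",
                 classes = landuse_classes()[["natural_green"]])
  )
}
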