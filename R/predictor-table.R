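#' Construct a predictor table
#'
#' A site-by-variable matrix of predictor values together with the per-variable
#' metadata (buffer radius, direction constraint, forced flag) that the model
#' builder needs.
#'
#' @param values Data frame with a `site_id` column followed by one numeric
#'   column per variable.
#' @param vars A [lur_variables()] data frame describing every value column.
#' @return A `predictor_table` object.
#' @export
predictor_table <- function(values, vars) {
  stopifnot(is.data.frame(values), "site_id" %in% names(values))
  cols <- setdiff(names(values), "site_id")
  missing <- setdiff(cols, vars$name)
  if (length(missing))
    stop_data("predictor_table: no definition for column(s): %s",
              paste(missing, collapse = ", "))
  if (anyDuplicated(values$site_id))
    stop_data("predictor_table: duplicate site_id")
  if (anyNA(values[cols]))
    stop_data("predictor_table: missing values are not allowed")
  vars <- vars[match(cols, vars$name), , drop = FALSE]
  rownames(vars) <- NULL
  structure(list(values = values, vars = vars), class = "predictor_table")
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("predictor table: %d sites x %d variables (%s)\n",
              nrow(x$values), nrow(x$vars),
              paste(x$vars$name, collapse = ", ")))
  invisible(x)
}

# numeric matrix of predictor values, rows in site order
predictor_matrix <- function(table) {
  m <- as.matrix(table$values[, table$vars$name, drop = FALSE])
  rownames(m) <- table$values$site_id
  m
}

#' Bundle sites, predictors and annual observations into a modeling dataset
#'
#' @param sites Site table: `site_id`, `area_code`, `region`, `site_type`
#'   (one of street / urban_background / regional_background), `x`, `y`.
#' @param predictors A [predictor_table()] covering every site.
#' @param annual Data frame with `site_id` and `value` (annual average
#'   concentration, ug/m3).
#' @return A `lur_data` object with components aligned in site order.
#' @export
lur_data <- function(sites, predictors, annual) {
  check_sites(sites)
  i <- match(sites$site_id, predictors$values$site_id)
  if (anyNA(i))
    stop_data("lur_data: predictor table is missing %d site(s)", sum(is.na(i)))
  predictors$values <- predictors$values[i, , drop = FALSE]
  j <- match(sites$site_id, annual$site_id)
  if (anyNA(j))
    stop_data("lur_data: annual observations missing for %d site(s)",
              sum(is.na(j)))
  structure(list(sites = sites, predictors = predictors,
                 annual = annual[j, , drop = FALSE]),
            class = "lur_data")
}

#' @export
print.lur_data <- function(x, ...) {
  cat(sprintf("LUR dataset: %d sites in %d areas (%d regions), %d predictors\n",
              nrow(x$sites), length(unique(x$sites$area_code)),
              length(unique(x$sites$region)), nrow(x$predictors$vars)))
  invisible(x)
}

check_sites <- function(sites) {
  need <- c("site_id", "area_code", "region", "site_type", "x", "y")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop_data("site table: missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sites$site_id)) {
    dup <- sites$site_id[duplicated(sites$site_id)][1L]
    stop_data("site table: duplicate site_id '%s'", dup)
  }
  bad <- !sites$site_type %in% site_types()
  if (any(bad))
    stop_data("site table row %d: unknown site_type '%s'",
              which(bad)[1L], sites$site_type[bad][1L])
  invisible(sites)
}

site_types <- function() c("street", "urban_background", "regional_background")

# restrict a dataset to a subset of areas; records provenance of exclusions
subset_areas <- function(data, keep_areas) {
  keep <- data$sites$area_code %in% keep_areas
  excluded <- setdiff(unique(data$sites$area_code), keep_areas)
  out <- lur_data(
    data$sites[keep, , drop = FALSE],
    predictor_table(data$predictors$values[
      data$predictors$values$site_id %in% data$sites$site_id[keep], ,
      drop = FALSE], data$predictors$vars),
    data$annual[data$annual$site_id %in% data$sites$site_id[keep], ,
                drop = FALSE])
  attr(out, "excluded_areas") <- sort(c(attr(data, "excluded_areas"), excluded))
  out
}

#' Restrict a dataset to one region
#'
#' Regional models (e.g. north / west / central / south Europe) are built by
#' running the same model builder on the region's areas only.
#'
#' @param data A [lur_data()] object.
#' @param region Region label present in `data$sites$region`.
#' @return The restricted `lur_data`.
#' @export
region_subset <- function(data, region) {
  if (!region %in% data$sites$region)
    stop_data("region_subset: unknown region '%s'", region)
  subset_areas(data, unique(data$sites$area_code[data$sites$region == region]))
}
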