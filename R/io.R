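# All tabular I/O uses a fixed CSV dialect: UTF-8, comma separator, '.'
# decimal mark, header row required. Coordinates and buffer radii are meters
# end to end; concentrations ug/m3.

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop_data("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  d
}

#' Read and write the site table
#'
#' Columns: `site_id`, `area_code`, `region`, `site_type`, `x`, `y`, plus an
#' optional `value` column of annual observations. Duplicate site ids and
#' unknown site types are rejected with the offending row identified.
#'
#' @param path CSV path.
#' @param sites Site table; `annual` an optional `site_id`/`value` frame
#'   merged into the file.
#' @return `read_site_table()`: list with `sites` and `annual` (`NULL` when
#'   the file has no `value` column).
#' @export
read_site_table <- function(path) {
  d <- read_csv_strict(path, c("site_id", "area_code", "region", "site_type",
                               "x", "y"))
  check_sites(d)
  annual <- NULL
  if ("value" %in% names(d))
    annual <- data.frame(site_id = d$site_id, value = d$value,
                         stringsAsFactors = FALSE)
  list(sites = d[c("site_id", "area_code", "region", "site_type", "x", "y")],
       annual = annual)
}

#' @rdname read_site_table
#' @export
write_site_table <- function(sites, path, annual = NULL) {
  out <- sites
  if (!is.null(annual))
    out$value <- annual$value[match(sites$site_id, annual$site_id)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write road-segment tables
#'
#' Columns: `segment_id`, `x1`, `y1`, `x2`, `y2`, `intensity`
#' (vehicles/day), `is_major` (logical).
#'
#' @param path CSV path.
#' @param roads Road table.
#' @export
read_roads <- function(path) {
  d <- read_csv_strict(path, c("segment_id", "x1", "y1", "x2", "y2",
                               "intensity", "is_major"))
  d$is_major <- as.logical(d$is_major)
  if (any(d$intensity < 0)) stop_data("%s: negative intensity", path)
  d
}

#' @rdname read_roads
#' @export
write_roads <- function(roads, path) {
  utils::write.csv(roads, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write measurement tables
#'
#' Long format: `site_id`, `period`, `value` (a `pollutant` column is carried
#' through when present). The reference table uses `area_code`, `period`,
#' `value`.
#'
#' @param path CSV path.
#' @param measurements,reference Data frames as above.
#' @export
read_measurements <- function(path) {
  read_csv_strict(path, c("site_id", "period", "value"))
}

#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_measurements
#' @export
read_reference <- function(path) {
  read_csv_strict(path, c("area_code", "period", "value"))
}

#' @rdname read_measurements
#' @export
write_reference <- function(reference, path) {
  utils::write.csv(reference, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

model_schema_version <- "1"

#' Serialize and restore a fitted LUR model
#'
#' JSON round-trip at full decimal precision: coefficients, the partial-R2
#' entry path, p-values, VIFs, training ranges and provenance are preserved
#' bit-exactly. A schema-version mismatch or missing ranges are explicit
#' errors.
#'
#' @param model A `lur_model`.
#' @param path JSON path.
#' @return `read_model()` returns the restored `lur_model`.
#' @export
write_model <- function(model, path) {
  payload <- list(schema_version = model_schema_version,
                  intercept = model$intercept,
                  terms = model$terms[setdiff(names(model$terms), "classes")],
                  ranges = model$ranges,
                  r2 = model$r2, adj_r2 = model$adj_r2, n = model$n,
                  sigma = model$sigma,
                  selection_path = model$selection_path,
                  options = model$options,
                  provenance = model$provenance)
  # 17 significant digits guarantee bit-exact double round-trips
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(p$schema_version), model_schema_version))
    stop_data("model file '%s': schema version '%s' (expected '%s')",
              path, p$schema_version %||% "<missing>", model_schema_version)
  if (is.null(p$ranges))
    stop_data("model file '%s': missing training ranges", path)
  terms <- as.data.frame(p$terms, stringsAsFactors = FALSE)
  if (!nrow(terms))
    terms <- data.frame(name = character(0), beta = numeric(0),
                        p_value = numeric(0), vif = numeric(0),
                        r2_at_entry = numeric(0),
                        adj_r2_at_entry = numeric(0),
                        forced = logical(0), direction = character(0))
  prov <- p$provenance
  prov$excluded_areas <- as.character(prov$excluded_areas %||% character(0))
  structure(list(intercept = p$intercept, terms = terms,
                 ranges = as.data.frame(p$ranges, stringsAsFactors = FALSE),
                 r2 = p$r2, adj_r2 = p$adj_r2, n = p$n, sigma = p$sigma,
                 selection_path = as.character(p$selection_path %||%
                                                 character(0)),
                 options = p$options, provenance = prov),
            class = "lur_model")
}

#' Write all artifacts of a synthetic study to a directory
#'
#' Emits `sites.csv`, `roads.csv` (geometry mode), one `raster_<area>.txt`
#' per area (geometry mode), `measurements.csv`, `reference.csv`,
#' `annual.csv` and `truth.json`, all re-readable by the package's own
#' readers.
#'
#' @param study A [generate_study()] result.
#' @param campaign A [generate_concentrations()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_site_table(study$sites, file.path(dir, "sites.csv"))
  if (!is.null(study$roads))
    write_roads(study$roads[setdiff(names(study$roads), "area_code")],
                file.path(dir, "roads.csv"))
  if (!is.null(study$rasters))
    for (a in names(study$rasters))
      write_raster(study$rasters[[a]],
                   file.path(dir, sprintf("raster_%s.txt", a)))
  write_measurements(campaign$seasonal, file.path(dir, "measurements.csv"))
  write_reference(campaign$reference, file.path(dir, "reference.csv"))
  utils::write.csv(campaign$annual, file.path(dir, "annual.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(intercept = campaign$truth$intercept,
         coefficients = as.list(campaign$truth$coefficients),
         background_weight = campaign$truth$background_weight,
         noise_sd = campaign$truth$noise_sd),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
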