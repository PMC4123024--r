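#' Configure a synthetic multi-area monitoring study
#'
#' The configuration describes a standardized multi-area campaign: a number of
#' study areas allocated to broad regions, a fixed number of sites per area
#' split across street, urban background and regional background locations,
#' an area-level background concentration distribution, and the noise
#' structure of the annual observations.
#'
#' Exactly one of `noise_sd`, `target_within_r2` or `target_r2` controls the
#' site-level noise: `noise_sd` is an absolute value (ug/m3);
#' `target_within_r2` sets the noise so that the expected within-area fraction
#' of variance explained by the local predictors is approximately the target;
#' `target_r2` does the same for the overall (within + between) fraction.
#' `variance_ratio`, when set, rescales the area background spread so that the
#' between-area variance of the generated annual means is `variance_ratio`
#' times the within-area variance (between-dominated PM2.5-like studies use a
#' ratio around 3; within-dominated NO2-like studies a ratio well below 1).
#'
#' @param n_areas Number of study areas, `>= 2`.
#' @param sites_per_area Sites per area, `>= 6`.
#' @param regions Character vector of region labels recycled across areas in
#'   order (default the four broad European regions).
#' @param site_type_mix Named fractions over
#'   street / urban_background / regional_background, summing to 1. Every area
#'   always receives at least one regional background site.
#' @param between_area_background List with `mean` and `sd` (ug/m3) of the
#'   area background distribution.
#' @param background_dist `"lognormal"` (backgrounds stay positive; the
#'   default) or `"normal"`.
#' @param noise_sd,target_within_r2,target_r2 Noise controls, see Details.
#' @param variance_ratio Optional between:within variance ratio calibration.
#' @param seasonal_amplitude Amplitude (ug/m3) of the area-shared sinusoidal
#'   seasonal deviation.
#' @param sampling_noise_sd SD (ug/m3) of the independent per-sample noise on
#'   each 2-week measurement.
#' @param geometry If `TRUE`, generate a road network and land-use raster per
#'   area (needed for geometric predictor extraction); if `FALSE`, only site
#'   locations are generated and predictors must come from the tabular
#'   generator.
#' @param area_size Side length (m) of each square study area.
#' @param n_arterials,n_local_roads Road network composition per area.
#' @param street_max_dist Maximum distance (m) from a street site to a
#'   high-intensity road.
#' @param street_min_intensity Minimum intensity (vehicles/day) of the road
#'   that qualifies a site as a street site.
#' @param rb_min_major_dist Minimum distance (m) from a regional background
#'   site to any major road.
#' @param cell_size Raster cell size (m).
#' @param seed Top-level integer seed; all randomness flows from it through
#'   named substreams.
#' @return A `study_config` object.
#' @export
study_config <- function(n_areas = 17, sites_per_area = 20,
                         regions = c("north", "west", "central", "south"),
                         site_type_mix = c(street = 0.475,
                                           urban_background = 0.425,
                                           regional_background = 0.10),
                         between_area_background = list(mean = 15, sd = 4),
                         background_dist = c("lognormal", "normal"),
                         noise_sd = NULL, target_within_r2 = NULL,
                         target_r2 = NULL, variance_ratio = NULL,
                         seasonal_amplitude = 3, sampling_noise_sd = 0.8,
                         geometry = TRUE, area_size = 20000,
                         n_arterials = 6, n_local_roads = 150,
                         street_max_dist = 50, street_min_intensity = 10000,
                         rb_min_major_dist = 1000, cell_size = 100,
                         seed = 1L) {
  if (n_areas < 2) stop_data("study_config: n_areas must be >= 2")
  if (sites_per_area < 6) stop_data("study_config: sites_per_area must be >= 6")
  mix <- site_type_mix[site_types()]
  if (anyNA(mix) || any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-9)
    stop_data("study_config: site_type_mix must be fractions over %s summing to 1",
              paste(site_types(), collapse = "/"))
  if (sum(!vapply(list(noise_sd, target_within_r2, target_r2), is.null,
                  TRUE)) > 1L)
    stop_data("study_config: give at most one of noise_sd / target_within_r2 / target_r2")
  if (!is.null(target_r2) && !is.null(variance_ratio))
    stop_data("study_config: target_r2 cannot be combined with variance_ratio")
  structure(list(
    n_areas = as.integer(n_areas), sites_per_area = as.integer(sites_per_area),
    regions = regions, site_type_mix = mix,
    between_area_background = between_area_background,
    background_dist = match.arg(background_dist),
    noise_sd = noise_sd, target_within_r2 = target_within_r2,
    target_r2 = target_r2, variance_ratio = variance_ratio,
    seasonal_amplitude = seasonal_amplitude,
    sampling_noise_sd = sampling_noise_sd,
    geometry = isTRUE(geometry), area_size = area_size,
    n_arterials = as.integer(n_arterials),
    n_local_roads = as.integer(n_local_roads),
    street_max_dist = street_max_dist,
    street_min_intensity = street_min_intensity,
    rb_min_major_dist = rb_min_major_dist, cell_size = cell_size,
    seed = as.integer(seed)), class = "study_config")
}

#' PM2.5-like and NO2-like study presets
#'
#' `pm25_like_config()` emulates a between-area-dominated pollutant: 17 study
#' areas, 20 sites each, area background variance three times the within-area
#' variance, local predictors explaining about half of the within-area
#' variance. `no2_like_config()` emulates a within-area-dominated
#' traffic-related pollutant: 23 areas, 40 sites each, background variance well
#' below the within-area variance, local predictors explaining about 70% of
#' it.
#'
#' @param ... Overrides passed on to [study_config()].
#' @return A `study_config`.
#' @export
pm25_like_config <- function(...) {
  args <- utils::modifyList(
    list(n_areas = 17, sites_per_area = 20,
         between_area_background = list(mean = 15, sd = 4),
         variance_ratio = 3, target_within_r2 = 0.5,
         seasonal_amplitude = 3, sampling_noise_sd = 0.8),
    list(...))
  do.call(study_config, args)
}

#' @rdname pm25_like_config
#' @export
no2_like_config <- function(...) {
  args <- utils::modifyList(
    list(n_areas = 23, sites_per_area = 40,
         between_area_background = list(mean = 22, sd = 5),
         variance_ratio = 0.3, target_within_r2 = 0.7,
         seasonal_amplitude = 6, sampling_noise_sd = 1.5),
    list(...))
  do.call(study_config, args)
}

# per-area site-type counts: at least 1 regional background site everywhere
site_type_counts <- function(n, mix) {
  n_rb <- max(1L, round(mix[["regional_background"]] * n))
  n_st <- round(mix[["street"]] * n)
  n_ub <- n - n_st - n_rb
  if (n_ub < 0L) { n_st <- n_st + n_ub; n_ub <- 0L }
  c(street = n_st, urban_background = n_ub, regional_background = n_rb)
}

#' Generate a synthetic multi-area study
#'
#' Generates the geographic world of a standardized multi-area campaign:
#' areas on a widely separated planar grid, each with a radial "city" road
#' network (a few high-intensity arterials through the center, many
#' low-intensity local roads, log-normal intensities), a land-use raster with
#' a residential core and green outskirts, and monitoring sites placed by
#' type: street sites within `street_max_dist` of a high-intensity road,
#' regional background sites at least `rb_min_major_dist` from any major road,
#' urban background sites in between. An area-level background concentration
#' is drawn for every area. Deterministic for a fixed config seed.
#'
#' @param config A [study_config()].
#' @return A `lur_study`: list with `config`, `sites`, `areas` (area table
#'   with region and background), `roads` and `rasters` (named list by area;
#'   `NULL` when `config$geometry` is `FALSE`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  n_areas <- config$n_areas
  spacing <- 3 * config$area_size
  ncols <- ceiling(sqrt(n_areas))
  area_codes <- sprintf("A%02d", seq_len(n_areas))
  centers <- data.frame(
    area_code = area_codes,
    region = rep(config$regions, length.out = n_areas),
    cx = ((seq_len(n_areas) - 1L) %% ncols) * spacing,
    cy = ((seq_len(n_areas) - 1L) %/% ncols) * spacing,
    stringsAsFactors = FALSE)

  bg <- config$between_area_background
  centers$background <- with_substream(config$seed, "background", {
    if (config$background_dist == "lognormal") {
      sdlog <- sqrt(log(1 + (bg$sd / bg$mean)^2))
      stats::rlnorm(n_areas, log(bg$mean) - sdlog^2 / 2, sdlog)
    } else stats::rnorm(n_areas, bg$mean, bg$sd)
  })

  roads <- NULL; rasters <- NULL
  if (config$geometry) {
    roads <- with_substream(config$seed, "roads", {
      do.call(rbind, lapply(seq_len(n_areas), function(a)
        generate_area_roads(centers[a, ], config)))
    })
    rasters <- with_substream(config$seed, "raster", {
      out <- lapply(seq_len(n_areas), function(a)
        generate_area_raster(centers[a, ], config))
      names(out) <- area_codes
      out
    })
  }

  sites <- with_substream(config$seed, "sites", {
    do.call(rbind, lapply(seq_len(n_areas), function(a) {
      ar <- centers[a, ]
      rd <- if (config$geometry)
        roads[roads$area_code == ar$area_code, , drop = FALSE] else NULL
      generate_area_sites(ar, rd, config)
    }))
  })
  rownames(sites) <- NULL

  structure(list(config = config, sites = sites, areas = centers,
                 roads = roads, rasters = rasters),
            class = "lur_study")
}

#' @export
print.lur_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d areas x %d sites (%s)%s\n",
              x$config$n_areas, x$config$sites_per_area,
              paste(unique(x$areas$region), collapse = "/"),
              if (x$config$geometry)
                sprintf(", %d road segments", nrow(x$roads)) else ""))
  invisible(x)
}

generate_area_roads <- function(area, config) {
  h <- config$area_size / 2
  k <- config$n_arterials
  ang <- sort(stats::runif(k, 0, 2 * pi))
  arterials <- data.frame(
    area_code = area$area_code,
    segment_id = sprintf("%s_M%03d", area$area_code, seq_len(k)),
    x1 = area$cx, y1 = area$cy,
    x2 = area$cx + h * cos(ang), y2 = area$cy + h * sin(ang),
    intensity = config$street_min_intensity *
      (1 + stats::rlnorm(k, meanlog = 0, sdlog = 0.5)),
    is_major = TRUE, stringsAsFactors = FALSE)
  m <- config$n_local_roads
  # locals cluster toward the center, skewed low intensities
  r <- pmin(abs(stats::rnorm(m, 0, h / 2)), 0.95 * h)
  th <- stats::runif(m, 0, 2 * pi)
  mx <- area$cx + r * cos(th); my <- area$cy + r * sin(th)
  len <- stats::runif(m, 300, 1500)
  dir <- stats::runif(m, 0, pi)
  locals <- data.frame(
    area_code = area$area_code,
    segment_id = sprintf("%s_L%03d", area$area_code, seq_len(m)),
    x1 = mx - len / 2 * cos(dir), y1 = my - len / 2 * sin(dir),
    x2 = mx + len / 2 * cos(dir), y2 = my + len / 2 * sin(dir),
    intensity = stats::rlnorm(m, meanlog = log(800), sdlog = 0.8),
    is_major = FALSE, stringsAsFactors = FALSE)
  rbind(arterials, locals)
}

generate_area_raster <- function(area, config) {
  h <- config$area_size / 2
  cs <- config$cell_size
  n <- ceiling(config$area_size / cs)
  cls <- landuse_classes()
  cx <- area$cx - h + (seq_len(n) - 0.5) * cs
  cy <- area$cy + h - (seq_len(n) - 0.5) * cs  # row 1 = north
  d <- sqrt(outer(cy - area$cy, cx - area$cx, function(a, b) a^2 + b^2))
  p_res <- exp(-(d / (0.45 * h))^2)            # residential core
  u <- matrix(stats::runif(n * n), n, n)
  codes <- matrix(cls[["other"]], n, n)
  codes[u < p_res] <- cls[["residential"]]
  green <- u > p_res & (u - p_res) < 0.5 * (d / h)  # green outskirts
  codes[green] <- cls[["natural_green"]]
  lur_raster(codes, area$cx - h, area$cy - h, cs)
}

generate_area_sites <- function(area, roads, config) {
  counts <- site_type_counts(config$sites_per_area, config$site_type_mix)
  h <- config$area_size / 2
  majors <- if (!is.null(roads))
    roads[roads$is_major & roads$intensity >= config$street_min_intensity, ,
          drop = FALSE] else NULL

  place_street <- function(k) {
    if (is.null(majors) || !nrow(majors)) {     # tabular mode: no constraint
      return(cbind(stats::runif(k, area$cx - h, area$cx + h),
                   stats::runif(k, area$cy - h, area$cy + h)))
    }
    i <- sample.int(nrow(majors), k, replace = TRUE)
    t <- stats::runif(k, 0.05, 0.9)
    off <- stats::runif(k, 5, 0.9 * config$street_max_dist)
    side <- sample(c(-1, 1), k, replace = TRUE)
    dx <- majors$x2[i] - majors$x1[i]; dy <- majors$y2[i] - majors$y1[i]
    L <- sqrt(dx^2 + dy^2)
    cbind(majors$x1[i] + t * dx - side * off * dy / L,
          majors$y1[i] + t * dy + side * off * dx / L)
  }
  place_reject <- function(k, accept) {
    out <- matrix(NA_real_, k, 2)
    filled <- 0L
    while (filled < k) {
      m <- 4L * (k - filled) + 8L
      x <- stats::runif(m, area$cx - h, area$cx + h)
      y <- stats::runif(m, area$cy - h, area$cy + h)
      ok <- accept(x, y)
      take <- min(sum(ok), k - filled)
      if (take > 0L) {
        out[filled + seq_len(take), ] <- cbind(x[ok], y[ok])[seq_len(take), ]
        filled <- filled + take
      }
    }
    out
  }
  min_major_dist <- function(x, y) {
    if (is.null(majors) || !nrow(majors)) return(rep(Inf, length(x)))
    vapply(seq_along(x), function(i)
      min(point_segment_distance(c(x[i], y[i]), majors)), 0)
  }
  st <- place_street(counts[["street"]])
  ub <- place_reject(counts[["urban_background"]], function(x, y) {
    d <- min_major_dist(x, y)
    d >= 2 * config$street_max_dist &
      sqrt((x - area$cx)^2 + (y - area$cy)^2) <= 0.7 * h
  })
  rb <- place_reject(counts[["regional_background"]], function(x, y)
    min_major_dist(x, y) >= config$rb_min_major_dist)

  xy <- rbind(st, ub, rb)
  types <- rep(names(counts), counts)
  data.frame(
    site_id = sprintf("%s_S%03d", area$area_code,
                      seq_len(config$sites_per_area)),
    area_code = area$area_code, region = area$region, site_type = types,
    x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
}
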