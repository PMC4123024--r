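#' Define the true data-generating model of a synthetic study
#'
#' Ground truth for recovery tests: annual concentration at a site is
#' `intercept + background_weight * area_background + sum(beta * x) + noise`.
#'
#' @param intercept Intercept, ug/m3.
#' @param coefficients Named numeric vector of signed coefficients on
#'   predictor-table variables.
#' @param background_weight Coefficient on the area background level
#'   (dimensionless; 1 means the background passes through unattenuated).
#' @param noise_sd Site-level noise SD (ug/m3), or `NULL` to resolve it from
#'   the study configuration (`noise_sd`, `target_within_r2` or `target_r2`).
#' @return A `true_model` object.
#' @export
true_model <- function(intercept, coefficients, background_weight = 1,
                       noise_sd = NULL) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!is.null(noise_sd) && noise_sd < 0)
    stop_data("true_model: noise_sd must be >= 0")
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 background_weight = background_weight,
                 noise_sd = noise_sd),
            class = "true_model")
}

#' Build a true model with effect sizes given as concentration SDs
#'
#' Convenience constructor: each coefficient is chosen as
#' `sign * sd_target / sd(x)` on the realized predictor table, so `sd`
#' states each variable's marginal contribution in concentration units.
#' Signs follow the variables' declared directions.
#'
#' @param table A [predictor_table()].
#' @param sd Named numeric vector: target contribution SD (ug/m3) per
#'   variable.
#' @inheritParams true_model
#' @return A `true_model`.
#' @export
true_model_from_sd <- function(table, sd, intercept = 0,
                               background_weight = 1, noise_sd = NULL) {
  X <- predictor_matrix(table)
  miss <- setdiff(names(sd), colnames(X))
  if (length(miss))
    stop_data("true_model_from_sd: unknown variable(s): %s",
              paste(miss, collapse = ", "))
  beta <- vapply(names(sd), function(v) {
    s <- stats::sd(X[, v])
    if (s == 0) stop_data("true_model_from_sd: '%s' is constant", v)
    dir <- table$vars$direction[table$vars$name == v]
    (if (dir == "negative") -1 else 1) * sd[[v]] / s
  }, 0)
  true_model(intercept, beta, background_weight, noise_sd)
}

#' Simulate a monitoring campaign: annual truth, seasonal samples, reference
#'
#' Generates, for every site, the true annual average under `model` plus
#' site-level noise; three 2-week samples (one per season) equal to the
#' annual value plus an area-shared sinusoidal seasonal deviation plus
#' independent sampling noise; and a continuous (26-period) reference series
#' per area sharing the same seasonal deviations.
#'
#' Coefficient signs are checked against the variable definitions' declared
#' directions; a contradiction is a configuration error. When the study
#' config sets `variance_ratio`, the area background deviations are rescaled
#' so that the between-area variance of the annual signal equals
#' `variance_ratio` times the within-area variance.
#'
#' @param study A [generate_study()] result.
#' @param table A [predictor_table()] covering all sites.
#' @param model A [true_model()] whose coefficient names are table columns.
#' @return A `lur_campaign`: list with `annual` (site_id, value, true_value),
#'   `seasonal` (site_id, period, season, value), `reference` (area_code,
#'   period, value), `truth` (resolved true model incl. noise SD), and
#'   `background` (calibrated per-area background levels).
#' @export
generate_concentrations <- function(study, table, model) {
  stopifnot(inherits(study, "lur_study"), inherits(model, "true_model"))
  cfg <- study$config
  X <- predictor_matrix(table)
  vs <- table$vars
  miss <- setdiff(names(model$coefficients), colnames(X))
  if (length(miss))
    stop_data("generate_concentrations: model variable(s) not in table: %s",
              paste(miss, collapse = ", "))
  for (v in names(model$coefficients)) {
    dir <- vs$direction[vs$name == v]
    b <- model$coefficients[[v]]
    if ((dir == "positive" && b < 0) || (dir == "negative" && b > 0))
      stop_data("coefficient of '%s' (%.3g) contradicts its declared %s direction",
                v, b, dir)
  }
  i <- match(table$values$site_id, study$sites$site_id)
  if (anyNA(i)) stop_data("predictor table does not cover the study sites")
  sites <- study$sites[i, , drop = FALSE]

  local <- drop(X[, names(model$coefficients), drop = FALSE] %*%
                  model$coefficients)
  area_of <- sites$area_code
  within_local_var <- mean(tapply(local, area_of, stats::var), na.rm = TRUE)
  if (!is.finite(within_local_var)) within_local_var <- 0

  bg0 <- study$areas$background[match(area_of, study$areas$area_code)]
  bw <- model$background_weight

  # resolve noise SD
  noise_sd <- model$noise_sd
  if (is.null(noise_sd)) {
    if (!is.null(cfg$noise_sd)) noise_sd <- cfg$noise_sd
    else if (!is.null(cfg$target_within_r2)) {
      r2 <- cfg$target_within_r2
      if (within_local_var <= 0)
        stop_data("target_within_r2 requires local predictor variance > 0")
      noise_sd <- sqrt(within_local_var * (1 - r2) / r2)
    } else if (!is.null(cfg$target_r2)) {
      r2 <- cfg$target_r2
      sig <- stats::var(bw * bg0 + local)
      noise_sd <- sqrt(sig * (1 - r2) / r2)
    } else noise_sd <- 0
  }

  # calibrate between-area spread to the configured variance ratio
  bg_area <- study$areas$background
  if (!is.null(cfg$variance_ratio) && bw != 0) {
    within_var <- within_local_var + noise_sd^2
    dev <- bg_area - mean(bg_area)
    s <- stats::sd(dev)
    if (s > 0) {
      scale <- sqrt(cfg$variance_ratio * within_var) / (bw * s)
      bg_area <- mean(bg_area) + dev * scale
    }
  }
  bg <- bg_area[match(area_of, study$areas$area_code)]

  true_annual <- model$intercept + bw * bg + local
  noise <- with_substream(cfg$seed, "noise",
                          stats::rnorm(length(true_annual), 0, noise_sd))
  annual_value <- true_annual + noise

  camp <- simulate_seasonal(cfg, sites, annual_value,
                            model$intercept + bw * bg_area, study$areas)

  truth <- model
  truth$noise_sd <- noise_sd
  structure(list(
    annual = data.frame(site_id = sites$site_id, value = annual_value,
                        true_value = true_annual, stringsAsFactors = FALSE),
    seasonal = camp$seasonal, reference = camp$reference,
    truth = truth,
    background = data.frame(area_code = study$areas$area_code,
                            background = bg_area, stringsAsFactors = FALSE)),
    class = "lur_campaign")
}

# season membership of the 26 biweekly periods
period_season <- function(p) {
  ifelse(p <= 4 | p >= 22, "cold", ifelse(p >= 11 & p <= 17, "warm",
                                          "intermediate"))
}

simulate_seasonal <- function(cfg, sites, annual_value, ref_level, areas) {
  periods <- 1:26
  n_areas <- nrow(areas)
  with_substream(cfg$seed, "seasonal", {
    phase <- stats::runif(n_areas, -2, 2)
    dev <- vapply(seq_len(n_areas), function(a)
      cfg$seasonal_amplitude * cos(2 * pi * (periods - 1 - phase[a]) / 26),
      numeric(length(periods)))                # periods x areas
    reference <- data.frame(
      area_code = rep(areas$area_code, each = length(periods)),
      period = rep(periods, n_areas),
      value = rep(ref_level, each = length(periods)) + as.vector(dev),
      stringsAsFactors = FALSE)
    # each site samples one period per season
    seas_sets <- split(periods, period_season(periods))
    n <- nrow(sites)
    pick <- cbind(sample(seas_sets$cold, n, replace = TRUE),
                  sample(seas_sets$intermediate, n, replace = TRUE),
                  sample(seas_sets$warm, n, replace = TRUE))
    ai <- match(sites$area_code, areas$area_code)
    seasonal <- data.frame(
      site_id = rep(sites$site_id, 3L),
      period = as.vector(pick),
      season = period_season(as.vector(pick)),
      value = rep(annual_value, 3L) + dev[cbind(as.vector(pick), rep(ai, 3L))] +
        stats::rnorm(3L * n, 0, cfg$sampling_noise_sd),
      stringsAsFactors = FALSE)
    list(reference = reference, seasonal = seasonal)
  })
}
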