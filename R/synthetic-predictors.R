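#' Generate a predictor table for a synthetic study
#'
#' In `"geometry"` mode predictors are extracted from the study's generated
#' road network and land-use rasters via the buffer operations (see
#' [extract_predictors()]). In `"tabular"` mode values are drawn from
#' log-normal marginals coupled through a Gaussian copula with a target
#' Spearman rank-correlation matrix; traffic-category variables are then
#' scaled by site type (street 1, urban background 0.3, regional background 0)
#' so that regional background locations carry no local-source signal, the
#' defining property of those sites.
#'
#' @param study A [generate_study()] result.
#' @param vars A [lur_variables()] table (variables of category
#'   `regional_background` are skipped; that column is computed from the
#'   measurements by the model builder).
#' @param mode `"geometry"` or `"tabular"`.
#' @param rank_cor Optional target rank-correlation matrix for tabular mode
#'   (identity by default). Must be positive definite.
#' @return A [predictor_table()].
#' @export
generate_predictor_table <- function(study, vars,
                                     mode = c("geometry", "tabular"),
                                     rank_cor = NULL) {
  stopifnot(inherits(study, "lur_study"))
  mode <- match.arg(mode)
  if (mode == "geometry") {
    if (is.null(study$roads))
      stop_data("geometry mode needs a study generated with geometry = TRUE")
    return(extract_predictors(study$sites, study$roads, study$rasters, vars))
  }
  tabular_predictors(study, vars[vars$category != "regional_background", ,
                                 drop = FALSE], rank_cor)
}

# local-source categories scaled by site type in tabular mode
traffic_categories <- function() {
  c("traffic_load", "road_length", "major_road_length",
    "nearest_road_intensity", "other_local")
}

tabular_predictors <- function(study, vars, rank_cor) {
  n <- nrow(study$sites)
  p <- nrow(vars)
  if (is.null(rank_cor)) rank_cor <- diag(p)
  if (!all(dim(rank_cor) == c(p, p)))
    stop_data("rank_cor must be %d x %d", p, p)
  # Spearman target -> Gaussian copula correlation
  rho <- 2 * sin(pi * rank_cor / 6)
  diag(rho) <- 1
  ch <- tryCatch(chol(rho), error = function(e)
    stop_data("rank_cor target is not positive definite"))
  vals <- with_substream(study$config$seed, "tabular", {
    z <- matrix(stats::rnorm(n * p), n, p) %*% ch
    u <- stats::pnorm(z)
    out <- matrix(0, n, p, dimnames = list(NULL, vars$name))
    for (j in seq_len(p)) {
      m <- if (is.na(vars$meanlog[j])) default_marginal(vars$category[j])
           else c(meanlog = vars$meanlog[j], sdlog = vars$sdlog[j])
      out[, j] <- stats::qlnorm(u[, j], m[["meanlog"]], m[["sdlog"]])
    }
    out
  })
  scale_by_type <- c(street = 1, urban_background = 0.3,
                     regional_background = 0)
  fac <- scale_by_type[study$sites$site_type]
  for (j in which(vars$category %in% traffic_categories()))
    vals[, j] <- vals[, j] * fac
  predictor_table(cbind(data.frame(site_id = study$sites$site_id,
                                   stringsAsFactors = FALSE),
                        as.data.frame(vals)),
                  vars)
}
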