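# Shared fixtures: small scenes and datasets built in code.

# a handful of road segments with known geometry
make_roads <- function(df) {
  df$segment_id <- df$segment_id %||% sprintf("S%03d", seq_len(nrow(df)))
  df$intensity <- df$intensity %||% rep(1000, nrow(df))
  df$is_major <- df$is_major %||% rep(FALSE, nrow(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_roads <- function(n, extent = 2000) {
  data.frame(
    segment_id = sprintf("R%03d", seq_len(n)),
    x1 = runif(n, -extent, extent), y1 = runif(n, -extent, extent),
    x2 = runif(n, -extent, extent), y2 = runif(n, -extent, extent),
    intensity = rlnorm(n, log(2000), 1),
    is_major = runif(n) < 0.3,
    stringsAsFactors = FALSE)
}

# small tabular study + campaign, the workhorse of builder/evaluation tests
make_dataset <- function(seed = 1, n_areas = 6, sites_per_area = 15,
                         config_fn = pm25_like_config, vars = NULL,
                         true_sd = NULL, intercept = 2, noise_sd = NULL, ...) {
  cfg <- config_fn(n_areas = n_areas, sites_per_area = sites_per_area,
                   geometry = FALSE, seed = seed, ...)
  study <- generate_study(cfg)
  vars <- vars %||% default_variable_set()
  tab <- generate_predictor_table(study, vars, mode = "tabular")
  true_sd <- true_sd %||% c(traffic_load_50 = 2, road_length_1000 = 1.5,
                            natural_green_5000 = 1)
  tm <- true_model_from_sd(tab, true_sd, intercept = intercept,
                           noise_sd = noise_sd)
  camp <- generate_concentrations(study, tab, tm)
  list(study = study, table = tab, truth = camp$truth, campaign = camp,
       data = lur_data(study$sites, tab,
                       camp$annual[c("site_id", "value")]))
}
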