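test_that("study generation is deterministic and respects the configured design", {
  cfg <- study_config(n_areas = 17, sites_per_area = 20, geometry = FALSE,
                      seed = 5)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$sites), 340)  # 17 x 20 PM-design scale
  expect_equal(length(unique(s1$sites$area_code)), 17)
  # every area has at least one regional background site
  rb <- table(s1$sites$area_code[s1$sites$site_type == "regional_background"])
  expect_true(all(s1$areas$area_code %in% names(rb)))
  expect_true(all(rb >= 1))
  # invalid configurations are rejected
  expect_error(study_config(n_areas = 1), "n_areas")
  expect_error(study_config(site_type_mix = c(street = 0.5,
                                              urban_background = 0.5,
                                              regional_background = 0.5)),
               "sum")
})

test_that("geometry placement rules hold exhaustively", {
  cfg <- study_config(n_areas = 3, sites_per_area = 12, seed = 17)
  study <- generate_study(cfg)
  majors <- study$roads[study$roads$is_major, ]
  fast <- majors[majors$intensity >= cfg$street_min_intensity, ]
  for (i in seq_len(nrow(study$sites))) {
    s <- study$sites[i, ]
    if (s$site_type == "street") {
      d <- min(multilur:::point_segment_distance(
        c(s$x, s$y), fast[fast$area_code == s$area_code, ]))
      expect_lt(d, cfg$street_max_dist)
    }
    if (s$site_type == "regional_background") {
      d <- min(multilur:::point_segment_distance(c(s$x, s$y), majors))
      expect_gte(d, cfg$rb_min_major_dist)
    }
  }
})

test_that("all-regional-background mix puts every site far from major roads", {
  cfg <- study_config(n_areas = 2, sites_per_area = 8,
                      site_type_mix = c(street = 0, urban_background = 0,
                                        regional_background = 1),
                      seed = 9)
  study <- generate_study(cfg)
  expect_true(all(study$sites$site_type == "regional_background"))
  majors <- study$roads[study$roads$is_major, ]
  d <- vapply(seq_len(nrow(study$sites)), function(i)
    min(multilur:::point_segment_distance(
      c(study$sites$x[i], study$sites$y[i]), majors)), 0)
  expect_true(all(d >= 1000))
})

test_that("tabular predictors: deterministic, complete, near-zero rank correlations", {
  cfg <- study_config(n_areas = 2, sites_per_area = 5000,
                      site_type_mix = c(street = 0.99, urban_background = 0,
                                        regional_background = 0.01),
                      geometry = FALSE, seed = 21)
  study <- generate_study(cfg)
  vars <- default_variable_set()
  t1 <- generate_predictor_table(study, vars, mode = "tabular")
  t2 <- generate_predictor_table(study, vars, mode = "tabular")
  expect_identical(t1, t2)
  expect_false(anyNA(t1$values))
  # identity copula: pairwise Spearman correlations near 0 on street sites
  st <- study$sites$site_type == "street"
  M <- as.matrix(t1$values[st, vars$name])
  rc <- cor(M, method = "spearman")
  expect_lt(max(abs(rc[upper.tri(rc)])), 0.05)
  # non-positive-definite correlation target is rejected
  bad <- matrix(0.99, nrow(vars), nrow(vars)); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(generate_predictor_table(study, vars, mode = "tabular",
                                        rank_cor = bad),
               "positive definite")
})

test_that("a site with no road within the buffer gets zero traffic variables", {
  roads <- make_roads(data.frame(x1 = 5000, y1 = 0, x2 = 6000, y2 = 0,
                                 intensity = 20000, is_major = TRUE))
  sites <- data.frame(site_id = "s1", area_code = "A", region = "r",
                      site_type = "urban_background", x = 0, y = 0,
                      stringsAsFactors = FALSE)
  ras <- lur_raster(matrix(1L, 50, 50), -2500, -2500, 100)
  vars <- lur_variables(
    lur_variable("road_length_1000", "road_length", buffer_radius = 1000),
    lur_variable("traffic_load_1000", "traffic_load", buffer_radius = 1000))
  tab <- extract_predictors(sites, roads, ras, vars)
  expect_equal(tab$values$road_length_1000, 0)
  expect_equal(tab$values$traffic_load_1000, 0)
})

test_that("concentrations: noiseless seasonal means equal truth; sign contradictions error", {
  fx <- make_dataset(seed = 31, config_fn = function(...)
    study_config(..., noise_sd = 0, seasonal_amplitude = 0,
                 sampling_noise_sd = 0),
    n_areas = 3, sites_per_area = 10)
  camp <- fx$campaign
  m3 <- tapply(camp$seasonal$value, camp$seasonal$site_id, mean)
  expect_equal(as.numeric(m3[camp$annual$site_id]), camp$annual$value,
               tolerance = 1e-12)
  expect_equal(camp$annual$value, camp$annual$true_value)
  # a positive-direction variable with negative coefficient is rejected
  bad <- true_model(0, c(traffic_load_50 = -1))
  expect_error(generate_concentrations(fx$study, fx$table, bad),
               "contradicts")
})

test_that("site-type concentration medians are ordered street > urban > regional", {
  fx <- make_dataset(seed = 37, n_areas = 8, sites_per_area = 30,
                     config_fn = function(...)
                       study_config(..., target_within_r2 = 0.9))
  med <- tapply(fx$campaign$annual$value, fx$study$sites$site_type, median)
  expect_gt(med[["street"]], med[["urban_background"]])
  expect_gt(med[["urban_background"]], med[["regional_background"]])
})

test_that("variance calibration hits the configured between:within ratio", {
  ratios <- vapply(1:50, function(s) {
    fx <- make_dataset(seed = s, n_areas = 10, sites_per_area = 12,
                       config_fn = pm25_like_config)
    v <- fx$campaign$annual$value
    a <- fx$study$sites$area_code
    means <- tapply(v, a, mean)
    between <- var(means[a])  # per-site between-area component
    within <- mean(tapply(v, a, var))
    between / within
  }, 0)
  expect_lt(abs(mean(ratios) - 3) / 3, 0.25)
  # PM2.5-like: between-area share of total variance dominates.
  # At a between:within SD ratio of 3 the between share must exceed 0.6.
  shares <- vapply(1:50, function(s) {
    fx <- make_dataset(seed = s + 500, n_areas = 10, sites_per_area = 12,
                       config_fn = function(...)
                         pm25_like_config(..., variance_ratio = 9))
    v <- fx$campaign$annual$value
    a <- fx$study$sites$area_code
    means <- tapply(v, a, mean)
    var(means[a]) / var(v)
  }, 0)
  expect_gt(mean(shares), 0.6)
})

test_that("study artifacts round-trip through the plain-text writers", {
  fx <- make_dataset(seed = 3, n_areas = 3, sites_per_area = 8)
  dir <- withr::local_tempdir()
  write_study(fx$study, fx$campaign, dir)
  st <- read_site_table(file.path(dir, "sites.csv"))
  expect_equal(st$sites, fx$study$sites, ignore_attr = TRUE)
  ref <- read_reference(file.path(dir, "reference.csv"))
  expect_equal(ref$value, fx$campaign$reference$value, tolerance = 1e-12)
  # geometry study also writes roads and rasters
  cfg <- study_config(n_areas = 2, sites_per_area = 8, seed = 4)
  study <- generate_study(cfg)
  tab <- generate_predictor_table(study, default_variable_set(), "geometry")
  tm <- true_model_from_sd(tab, c(road_length_1000 = 1), intercept = 1)
  camp <- generate_concentrations(study, tab, tm)
  dir2 <- withr::local_tempdir()
  write_study(study, camp, dir2)
  roads <- read_roads(file.path(dir2, "roads.csv"))
  expect_equal(nrow(roads), nrow(study$roads))
  expect_equal(roads$intensity, study$roads$intensity, tolerance = 1e-10)
  ras <- read_raster(file.path(dir2, "raster_A01.txt"))
  expect_identical(ras$codes, study$rasters[["A01"]]$codes)
  expect_equal(ras$cell_size, study$rasters[["A01"]]$cell_size)
})
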