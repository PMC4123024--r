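# multilur

Multi-area land use regression (LUR) models for air pollution exposure
assessment, with the full validation and transferability machinery used for
combined multi-city monitoring campaigns.

LUR regresses measured pollutant concentrations (NO2, PM2.5, PM2.5
absorbance) on GIS-derived predictors — traffic load and road length in
circular buffers, land-use areas, nearest-road traffic intensity — to
produce exposure surfaces for epidemiological studies. When many
standardized study areas are combined into one model, an area-level
*regional background concentration* (the mean of measurements at each
area's regional background sites) is forced in first, and the model is
completed by supervised forward stepwise selection:

- candidates enter only with the a-priori direction of effect (positive for
  traffic variables, negative for green space) and may not flip the sign of
  any term already in the model;
- the eligible candidate with the largest adjusted-R² gain is admitted if
  it improves the model by at least 1% (absolute adjusted R²);
- afterwards, terms with p > 0.1 are pruned (backward, refitting) and
  variables are dropped until every variance inflation factor is below 3.

The package provides that builder together with: exact line-in-disc buffer
geometry for road networks and cell-center raster summaries for land use;
reference-site temporal adjustment of seasonal 2-week samples (difference
method); three evaluation layers — within-area fit (Model_intra R²),
leave-one-area-out cross-validation, and hold-out validation with predictor
truncation — plus the area-exclusion transferability analysis (TRANS_intra
R²); and a synthetic multi-area campaign generator with known ground truth
(street / urban background / regional background site placement on
generated road networks, seasonal sampling against a continuous reference
series, configurable between-area vs within-area variance structure).

## Worked example

A between-dominated (PM2.5-like) synthetic campaign: 8 areas, 20 sites
each, predictors extracted geometrically from the generated road network
and land-use rasters, seasonal samples adjusted via each area's reference
series, then the combined model with all evaluation layers.

```r
library(multilur)

cfg      <- pm25_like_config(n_areas = 8, sites_per_area = 20, seed = 2024)
study    <- generate_study(cfg)
vars     <- default_variable_set()
table    <- generate_predictor_table(study, vars, mode = "geometry")
truth    <- true_model_from_sd(table, c(traffic_load_50 = 1.5,
                                        traffic_load_50_1000 = 1,
                                        road_length_100 = 0.8), intercept = 1)
campaign <- generate_concentrations(study, table, truth)
annual   <- adjust_measurements(campaign$seasonal, campaign$reference, study$sites)
data     <- lur_data(study$sites, table, annual)

model <- supervised_stepwise(data)
model
#> LUR model: n = 160, R2 = 0.810 (adj 0.806)
#>   intercept -4.147
#>   regional_background          beta       1.207  cumR2 0.653  p 1.37e-52  (forced)
#>   traffic_load_50              beta   2.334e-06  cumR2 0.798  p 4.65e-07
#>   traffic_load_50_1000         beta   3.573e-08  cumR2 0.810  p 0.00256

loaocv(data)
#> leave-one-area-out CV: overall R2 0.566, RMSE 5.892 (n = 160)
#>   per-area R2 median 0.497 (IQR 0.143), slope median 0.519
#>   43 predictor cell(s) truncated to training range

transfer_excluding_each_area(data)
#> transferability: 8 area-exclusion refits
#>   model R2       median 0.820 (IQR 0.012)
#>   Model_intra R2 median 0.527 (IQR 0.017)
#>   TRANS_intra R2 median 0.497 (IQR 0.143)
#>   RMSE           median 4.163 (IQR 1.171)
```

Reading the output: the forced regional background alone explains 65% of
the pooled variance (the `cumR2` column is the cumulative model R² along
the entry path); two traffic terms bring the model to R² 0.81. The
within-area story is different — the median Model_intra R² is ~0.53 —
because in a between-dominated pollutant most of what the combined model
explains is the contrast *between* areas. Models transferred to an excluded
area recover a median 0.50 of its within-area variance (TRANS_intra), and
per-area slopes around 0.5 show the transferred predictions compress local
contrasts. A within-dominated (NO2-like) configuration,
`no2_like_config()`, shows the opposite pattern: Model_intra ≈ overall R².

`run_pipeline()` wires the same steps into one call (simulation or CSV
inputs, model JSON, evaluation reports, and an md5 manifest for
reproducibility), and `read_site_table()` / `read_roads()` /
`read_raster()` / `read_model()` ingest the plain-text formats written by
the package.

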