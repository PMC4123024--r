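Package: multilur
Title: Multi-Area Land Use Regression Models for Air Pollution Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates multi-area land use regression (LUR) models
    for air pollutants such as NO2 and PM2.5 from standardized monitoring
    campaigns. Implements supervised forward stepwise selection with a-priori
    sign constraints, an adjusted R-squared gain threshold, p-value pruning and
    variance-inflation-factor control; buffer-based GIS predictor extraction
    from road networks and land-use rasters; temporal adjustment of seasonal
    two-week samples against a continuous reference site; hold-out validation
    with predictor truncation; leave-one-area-out cross-validation; and an
    area-exclusion transferability analysis. Includes a synthetic multi-area
    campaign generator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
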