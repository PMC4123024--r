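test_that("fit_ols agrees with the normal-equations oracle", {
  # exact line
  x <- 1:10
  f <- fit_ols(2 * x, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(unname(f$coef[["x"]]), 2)
  expect_equal(f$r2, 1)
  expect_equal(unname(f$p_values[["x"]]), 0)
  # orthogonal predictor
  y0 <- rep(c(-1, 1), 5)
  f0 <- fit_ols(y0, matrix(rep(c(1, 1, 2, 2), length.out = 10), ncol = 1,
                           dimnames = list(NULL, "x")))
  expect_lt(abs(f0$coef[["x"]]), 1e-10)
  expect_lt(f0$r2, 1e-10)
  # 6-point fixed dataset vs explicit (X'X)^-1 X'y
  X <- cbind(a = c(1, 2, 3, 5, 8, 13), b = c(2, 1, 4, 3, 6, 5))
  y <- c(3.1, 2.9, 7.5, 8.2, 13.9, 17.0)
  f6 <- fit_ols(y, X)
  Xm <- cbind(1, X)
  beta <- solve(t(Xm) %*% Xm) %*% t(Xm) %*% y
  expect_equal(unname(f6$coef), unname(drop(beta)), tolerance = 1e-10)
  # rank deficiency flagged, not an error
  fd <- fit_ols(y, cbind(a = X[, 1], b = 2 * X[, 1]))
  expect_false(fd$rank_ok)
})

test_that("adjusted R2 follows the closed form", {
  expect_equal(adjusted_r2(1, 20, 3), 1)
  expect_equal(adjusted_r2(0.5, 20, 3), 0.40625)
  withr::with_seed(6, {
    for (k in 1:20) {
      r2 <- runif(1); n <- sample(10:200, 1); p <- sample(1:5, 1)
      expect_equal(adjusted_r2(r2, n, p),
                   1 - (1 - r2) * (n - 1) / (n - p - 1))
    }
  })
  expect_error(adjusted_r2(0.5, 4, 3), "n > p")
})

test_that("vif: orthogonal, closed-form correlated, and collinear cases", {
  n <- 400
  withr::with_seed(10, {
    a <- rnorm(n); b <- rnorm(n)
    v0 <- vif(cbind(a = a, b = b))
    expect_equal(unname(v0), c(1, 1), tolerance = 0.05)
    # two columns with correlation r have VIF 1/(1-r^2)
    r <- 0.8
    b2 <- r * scale(a)[, 1] + sqrt(1 - r^2) * scale(b)[, 1]
    v <- vif(cbind(a = scale(a)[, 1], b = b2))
    r_emp <- cor(scale(a)[, 1], b2)
    expect_equal(unname(v), rep(1 / (1 - r_emp^2), 2), tolerance = 1e-10)
    # duplicated column reports the infinity sentinel
    expect_true(all(is.infinite(vif(cbind(a = a, b = a)))))
  })
  expect_error(vif(matrix(1:5)), "2 columns")
})

test_that("regional background variable is the area mean of background sites", {
  sites <- data.frame(
    site_id = sprintf("s%d", 1:7),
    area_code = c("A", "A", "A", "B", "B", "B", "B"),
    region = "r", site_type = c("regional_background", "street", "street",
                                "regional_background", "regional_background",
                                "urban_background", "street"),
    x = 0, y = 0, stringsAsFactors = FALSE)
  annual <- data.frame(site_id = sites$site_id,
                       value = c(12, 30, 40, 10, 14, 20, 33))
  bg <- regional_background_variable(annual, sites)
  expect_equal(bg, c(12, 12, 12, 12, 12, 12, 12))
  annual$value[4:5] <- c(10, 14)
  bg <- regional_background_variable(annual, sites)
  expect_equal(bg[4:7], rep(12, 4))
  # constant within every area, exhaustively
  fx <- make_dataset(seed = 12, n_areas = 5, sites_per_area = 10)
  bg2 <- regional_background_variable(fx$data$annual, fx$data$sites)
  expect_true(all(tapply(bg2, fx$data$sites$area_code,
                         function(v) length(unique(v))) == 1))
  # an area without background sites is a named data error
  sites2 <- sites; sites2$site_type[c(1, 4, 5)] <- "street"
  expect_error(regional_background_variable(annual, sites2), "A, B")
})

test_that("stepwise stopping and sign rules behave at the boundaries", {
  inst <- make_stepwise_instance(101)
  d <- instance_data(inst)
  opts <- lur_options(force_background = FALSE)
  # gain threshold of 1 admits nothing: forced-only model
  m0 <- supervised_stepwise(d, utils::modifyList(opts, list(gain = 1)))
  expect_equal(m0$terms$name, "forced_v")
  expect_true(m0$terms$forced)
  # a candidate whose best-fit coefficient contradicts its direction is
  # never admitted even when it has the largest gain
  withr::with_seed(77, {
    n <- 80
    x <- rlnorm(n)
    y <- 10 - 3 * x + rnorm(n, 0, 0.5)  # strongly negative effect
    sites <- data.frame(site_id = sprintf("s%d", 1:n), area_code = "A",
                        region = "r", site_type = "street", x = 1, y = 1,
                        stringsAsFactors = FALSE)
    defs <- lur_variables(
      lur_variable("xvar", "other_local", direction = "positive"))
    dd <- lur_data(sites, predictor_table(
      data.frame(site_id = sites$site_id, xvar = x), defs),
      data.frame(site_id = sites$site_id, value = y))
    m <- supervised_stepwise(dd, lur_options(force_background = FALSE))
    expect_false("xvar" %in% m$terms$name)
    expect_equal(nrow(m$terms), 0)  # intercept-only: all candidates ineligible
  })
})

test_that("stepwise selection path matches the exhaustive greedy oracle", {
  for (seed in c(201, 202, 203, 204, 205)) {
    inst <- make_stepwise_instance(seed)
    d <- instance_data(inst)
    m <- supervised_stepwise(d, lur_options(force_background = FALSE))
    df <- data.frame(y = inst$y, forced_v = inst$forced_col, inst$X)
    dirs <- c(stats::setNames(inst$directions, colnames(inst$X)),
              forced_v = "positive")
    oracle <- oracle_stepwise_path(df, "y", "forced_v", dirs)
    expect_identical(m$selection_path, oracle)
  }
})

test_that("p-value pruning removes pure-noise terms and spares forced ones", {
  # null retention: a noise term at n = 500 survives with prob ~ alpha
  kept <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      n <- 500
      x1 <- rnorm(n); x2 <- rnorm(n)
      y <- 2 + x1 + rnorm(n)
      f <- fit_ols(y, cbind(x1 = x1, x2 = x2))
      f$p_values[["x2"]] <= 0.1
    })
  }, TRUE)
  expect_lt(mean(kept), 0.2)   # ~0.1 expected under the null
  expect_gt(mean(kept), 0.02)
  # pruning a fitted model: forced membership never changes
  fx <- make_dataset(seed = 61)
  m <- supervised_stepwise(fx$data)
  pruned <- prune_by_pvalue(m, fx$data, alpha = 0.1)
  expect_true("regional_background" %in% pruned$terms$name)
  expect_identical(pruned$terms$name, m$terms$name)  # already pruned at build
  # with alpha = 0 everything non-forced is dropped (p-values exceed 0)
  all_dropped <- prune_by_pvalue(m, fx$data, alpha = 0)
  expect_equal(all_dropped$terms$name, "regional_background")
})

test_that("VIF enforcement drops near-duplicate terms and leaves clean models alone", {
  withr::with_seed(90, {
    n <- 150
    sites <- data.frame(site_id = sprintf("s%d", 1:n), area_code = "A",
                        region = "r", site_type = "street", x = 1, y = 1,
                        stringsAsFactors = FALSE)
    base <- rlnorm(n, 0, 1)
    near_dup <- base * (1 + rnorm(n, 0, 0.02))     # VIF far above 3
    indep <- rlnorm(n, 0, 1)
    y <- 5 + 2 * base + 1.5 * indep + rnorm(n, 0, 0.4)
    defs <- lur_variables(
      lur_variable("t1", "other_local"),
      lur_variable("t2", "other_local"),
      lur_variable("u1", "other_local"))
    dd <- lur_data(sites, predictor_table(
      data.frame(site_id = sites$site_id, t1 = base, t2 = near_dup,
                 u1 = indep), defs),
      data.frame(site_id = sites$site_id, value = y))
    m <- supervised_stepwise(dd, lur_options(force_background = FALSE))
    expect_true(xor("t1" %in% m$terms$name, "t2" %in% m$terms$name))
    expect_lt(max(m$terms$vif), 3)
    # an orthogonal design passes through enforce_vif unchanged
    m2 <- enforce_vif(m, dd, vif_max = 3)
    expect_identical(m2$terms$name, m$terms$name)
  })
})

test_that("prediction honors truncation semantics and the refit identity", {
  fx <- make_dataset(seed = 71)
  m <- supervised_stepwise(fx$data)
  # training data predicted by its own model reproduces the model R2
  p_train <- predict(m, fx$data, truncate = TRUE)
  expect_equal(attr(p_train, "truncated"), 0L)  # training inside its own hull
  expect_equal(pearson_r2(p_train, fx$data$annual$value), m$r2,
               tolerance = 1e-9)
  # values above the training max predict like the max
  frame <- as.data.frame(multilur:::predictor_matrix(fx$data$predictors))
  frame$regional_background <-
    regional_background_variable(fx$data$annual, fx$data$sites)
  hi <- frame[1, , drop = FALSE]
  v1 <- m$terms$name[!m$terms$forced][1]
  hi[[v1]] <- m$ranges$max[m$ranges$name == v1] * 10
  at_max <- hi; at_max[[v1]] <- m$ranges$max[m$ranges$name == v1]
  expect_equal(as.numeric(predict(m, hi, truncate = TRUE)),
               as.numeric(predict(m, at_max, truncate = FALSE)))
  expect_equal(attr(predict(m, hi, truncate = TRUE), "truncated"), 1L)
  # all-inside data: flag has no effect
  expect_equal(unname(predict(m, frame, truncate = TRUE)),
               unname(predict(m, frame, truncate = FALSE)))
  # missing column is a data error
  expect_error(predict(m, frame[setdiff(names(frame), v1)]), "missing")
})

test_that("model JSON round-trips at full precision and validates schema", {
  fx <- make_dataset(seed = 81)
  m <- supervised_stepwise(fx$data)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$terms$beta, m$terms$beta)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$ranges$min, m$ranges$min)
  expect_identical(m2$selection_path, m$selection_path)
  # predictions from the restored model are identical
  frame <- as.data.frame(multilur:::predictor_matrix(fx$data$predictors))
  frame$regional_background <-
    regional_background_variable(fx$data$annual, fx$data$sites)
  expect_identical(unname(predict(m2, frame)), unname(predict(m, frame)))
  # a hand-edited coefficient shows up in predictions
  m3 <- m2
  m3$terms$beta[1] <- m3$terms$beta[1] * 2
  expect_false(isTRUE(all.equal(unname(predict(m3, frame)),
                                unname(predict(m2, frame)))))
  # schema mismatch and missing ranges are explicit errors
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$schema_version <- "999"
  bad1 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(p, bad1, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(bad1), "schema version")
  p2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  p2$ranges <- NULL
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(p2, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(bad2), "ranges")
})
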