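# Independent brute-force oracles, deliberately written against different
# primitives (lm() formulas, exhaustive scans) than the implementation.

# greedy supervised stepwise oracle: exhaustively refits every augmented
# model at each step with lm(), applying the same sign-eligibility rules
oracle_stepwise_path <- function(df, yname, forced, directions,
                                 gain = 0.01, alpha = 0.1) {
  candidates <- sort(setdiff(names(directions), c(forced, yname)))
  terms <- forced
  adj_of <- function(tms) {
    if (!length(tms)) return(0)
    f <- lm(stats::reformulate(tms, response = yname), data = df)
    summary(f)$adj.r.squared
  }
  cur <- adj_of(terms)
  path <- character(0)
  repeat {
    remaining <- setdiff(candidates, terms)
    if (!length(remaining)) break
    gains <- rep(-Inf, length(remaining))
    names(gains) <- remaining
    for (v in remaining) {
      f <- lm(stats::reformulate(c(terms, v), response = yname), data = df)
      co <- coef(f)
      if (anyNA(co)) next
      ok <- TRUE
      for (tm in c(terms, v)) {
        d <- directions[[tm]]
        if (is.null(d) || is.na(d)) next
        if ((d == "positive" && co[[tm]] <= 0) ||
            (d == "negative" && co[[tm]] >= 0)) { ok <- FALSE; break }
      }
      if (ok) gains[v] <- summary(f)$adj.r.squared - cur
    }
    if (all(gains == -Inf) || max(gains) < gain) break
    best <- names(gains)[which.max(gains)]  # which.max: first max = smallest name
    terms <- c(terms, best)
    path <- c(path, best)
    cur <- adj_of(terms)
  }
  c(forced, path)
}

# random stepwise problem instance shared by implementation and oracle
make_stepwise_instance <- function(seed, n = 60, p = 8, beta_active = 3) {
  withr::with_seed(seed, {
    X <- matrix(rlnorm(n * p, 0, 0.8), n, p)
    # mild collinearity between neighbours
    for (j in 2:p) X[, j] <- X[, j] + 0.4 * X[, j - 1]
    colnames(X) <- sprintf("v%02d", seq_len(p))
    dirs <- sample(c("positive", "negative"), p, replace = TRUE)
    active <- sample(p, beta_active)
    beta <- numeric(p)
    beta[active] <- ifelse(dirs[active] == "negative", -1, 1) *
      runif(beta_active, 0.5, 1.5)
    forced_col <- rlnorm(n, 1, 0.5)
    y <- 3 + 0.8 * forced_col + drop(X %*% beta) + rnorm(n, 0, 1)
    list(X = X, y = y, forced_col = forced_col, directions = dirs)
  })
}

# wrap an instance into a lur_data with a forced variable
instance_data <- function(inst) {
  n <- length(inst$y)
  p <- ncol(inst$X)
  n_areas <- 4L
  sites <- data.frame(
    site_id = sprintf("s%03d", seq_len(n)),
    area_code = rep(sprintf("A%d", seq_len(n_areas)), length.out = n),
    region = "r1",
    site_type = rep(c("regional_background", "street", "urban_background"),
                    length.out = n),
    x = seq_len(n), y = seq_len(n), stringsAsFactors = FALSE)
  defs <- do.call(lur_variables, c(
    list(lur_variable("forced_v", "other_local", direction = "positive",
                      forced = TRUE)),
    lapply(seq_len(p), function(j)
      lur_variable(colnames(inst$X)[j], "other_local",
                   direction = inst$directions[j]))))
  vals <- cbind(data.frame(site_id = sites$site_id,
                           forced_v = inst$forced_col),
                as.data.frame(inst$X))
  lur_data(sites, predictor_table(vals, defs),
           data.frame(site_id = sites$site_id, value = inst$y))
}

# brute-force per-area group-by metrics
oracle_group_metrics <- function(pred, obs, area) {
  sp <- split(seq_along(pred), area)
  r2 <- sapply(sp, function(i) cor(pred[i], obs[i])^2)
  slope <- sapply(sp, function(i) coef(lm(pred[i] ~ obs[i]))[[2]])
  list(r2 = r2, slope = slope)
}
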