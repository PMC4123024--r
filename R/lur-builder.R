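#' Ordinary least squares with diagnostics
#'
#' The least-squares engine beneath the stepwise procedure: fits
#' `y ~ 1 + X`, returning coefficients, two-sided t-test p-values, R-squared
#' and adjusted R-squared. Rank-deficient fits are flagged (`rank_ok =
#' FALSE`) rather than erroring, so the selection loop can treat such
#' candidates as ineligible.
#'
#' @param y Numeric response vector.
#' @param X Numeric predictor matrix (no intercept column); may have zero
#'   columns for the intercept-only model.
#' @return An `ols_fit`: list with `coef` (named, intercept first), `se`,
#'   `p_values`, `r2`, `adj_r2`, `sigma`, `n`, `df`, `rank_ok`.
#' @export
fit_ols <- function(y, X) {
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) && nrow(X) != n) stop_data("fit_ols: nrow(X) != length(y)")
  Xm <- cbind("(Intercept)" = rep(1, n), X)
  p <- ncol(Xm) - 1L
  if (n <= p + 1L) stop_data("fit_ols: need n > p + 1 (n=%d, p=%d)", n, p)
  fit <- stats::lm.fit(Xm, y)
  rank_ok <- fit$rank == ncol(Xm) && !anyNA(fit$coefficients)
  coef <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop_data("fit_ols: response is constant")
  r2 <- 1 - sse / sst
  df <- n - fit$rank
  se <- rep(NA_real_, length(coef))
  pv <- rep(NA_real_, length(coef))
  if (rank_ok && df > 0L) {
    R <- qr.R(fit$qr)
    cov_unscaled <- chol2inv(R)
    piv <- fit$qr$pivot
    sigma2 <- sse / df
    se[piv] <- sqrt(diag(cov_unscaled) * sigma2)
    if (sse <= 1e-12 * sst) {
      pv[] <- 0  # numerically perfect fit: every term is certain
    } else {
      tt <- coef / se
      pv <- 2 * stats::pt(-abs(tt), df)
    }
  }
  names(se) <- names(pv) <- names(coef)
  structure(list(coef = coef, se = se, p_values = pv, r2 = r2,
                 adj_r2 = if (n > p + 1L) adjusted_r2(r2, n, p) else NA_real_,
                 sigma = sqrt(sse / max(df, 1L)), n = n, df = df,
                 rank_ok = rank_ok),
            class = "ols_fit")
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop_data("adjusted_r2: need n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variance inflation factors
#'
#' For each column `j`, `1 / (1 - R2_j)` with `R2_j` from regressing column
#' `j` on all other columns (with intercept). A perfectly collinear column is
#' reported as `Inf`.
#'
#' @param X Numeric matrix with at least 2 columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop_data("vif: need at least 2 columns")
  vapply(seq_len(ncol(X)), function(j) {
    f <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (sst <= 0) return(Inf)
    r2j <- 1 - sum(f$residuals^2) / sst
    if (1 - r2j <= 1e-12) Inf else 1 / (1 - r2j)
  }, 0, USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Regional background concentration variable
#'
#' Each site's value is the mean annual observation over the regional
#' background sites of the site's own area, so the column is constant within
#' every area. Because the value depends only on the area's own background
#' sites, the column is identical whether computed on the full dataset or on
#' any area subset.
#'
#' @param annual Data frame `site_id`, `value`.
#' @param sites Site table with `site_id`, `area_code`, `site_type`.
#' @return Numeric vector aligned with `sites` rows.
#' @export
regional_background_variable <- function(annual, sites) {
  v <- annual$value[match(sites$site_id, annual$site_id)]
  rb <- sites$site_type == "regional_background"
  means <- tapply(v[rb], sites$area_code[rb], mean)
  out <- as.numeric(means[sites$area_code])
  missing_areas <- setdiff(unique(sites$area_code), names(means))
  if (length(missing_areas) || anyNA(out))
    stop_data("no regional background site with an observation in area(s): %s",
              paste(unique(c(missing_areas,
                             sites$area_code[is.na(out)])), collapse = ", "))
  out
}

#' Options for supervised stepwise model building
#'
#' @param gain Minimum absolute adjusted-R-squared gain for a candidate to
#'   enter (default 0.01, i.e. "at least 1%").
#' @param alpha p-value threshold above which non-forced terms are pruned
#'   (default 0.1).
#' @param vif_max Variance-inflation-factor bound; final models satisfy
#'   max VIF `< vif_max` (default 3).
#' @param force_background If `TRUE` (combined multi-area models), the
#'   regional background variable is computed from the data and forced into
#'   the model first. Set `FALSE` for city-specific models.
#' @return A list of options.
#' @export
lur_options <- function(gain = 0.01, alpha = 0.1, vif_max = 3,
                        force_background = TRUE) {
  list(gain = gain, alpha = alpha, vif_max = vif_max,
       force_background = force_background)
}

# candidate's own sign and all previously entered directed signs must hold
signs_ok <- function(coef, terms, directions) {
  for (tm in terms) {
    d <- directions[[tm]]
    if (is.na(d)) next
    b <- coef[[tm]]
    if ((d == "positive" && b <= 0) || (d == "negative" && b >= 0))
      return(FALSE)
  }
  TRUE
}

#' Supervised stepwise LUR model building
#'
#' The combined-model algorithm: (1) force the regional background variable
#' (and any variables flagged `forced`); (2) repeatedly refit the current
#' model augmented with each remaining candidate alone, keep only candidates
#' whose fitted coefficient matches the a-priori direction and that flip no
#' already-entered term's required sign, and admit the one with the largest
#' adjusted-R-squared gain provided the gain is at least `options$gain`;
#' (3) stop when no eligible candidate clears the gain threshold; (4) prune
#' non-forced terms with p-value above `options$alpha` (backward,
#' largest-first, refitting after each removal); (5) drop non-forced terms
#' until the maximum VIF is below `options$vif_max`; (6) re-check direction
#' constraints and record the cumulative partial-R-squared path and the
#' per-variable training ranges used later for prediction truncation.
#' Exact gain ties are broken by lexicographic variable name; constant or
#' rank-deficient candidates are silently ineligible.
#'
#' @param data A [lur_data()] dataset.
#' @param options [lur_options()].
#' @return A `lur_model`; see [predict.lur_model()] for prediction.
#' @export
supervised_stepwise <- function(data, options = lur_options()) {
  stopifnot(inherits(data, "lur_data"))
  env <- builder_env(data, options)
  X <- env$X
  directions <- env$directions
  forced <- env$forced
  y <- env$y

  candidates <- setdiff(colnames(X), forced)
  if (!length(forced) && !length(candidates))
    stop_data("supervised_stepwise: no forced variable and no candidates")
  # constant columns can never be admitted
  candidates <- candidates[apply(X[, candidates, drop = FALSE], 2L,
                                 stats::sd) > 0]
  candidates <- sort(candidates)

  terms <- forced
  cur <- fit_ols(y, X[, terms, drop = FALSE])
  cur_adj <- if (length(terms)) cur$adj_r2 else 0
  path <- character(0)

  repeat {
    remaining <- setdiff(candidates, terms)
    if (!length(remaining)) break
    best <- NULL; best_gain <- -Inf
    for (v in remaining) {            # remaining is sorted: ties -> first name
      f <- fit_ols(y, X[, c(terms, v), drop = FALSE])
      if (!f$rank_ok) next
      if (!signs_ok(f$coef, c(terms, v), directions)) next
      g <- f$adj_r2 - cur_adj
      if (g > best_gain + 0) { best <- v; best_gain <- g }
    }
    if (is.null(best) || best_gain < options$gain) break
    terms <- c(terms, best)
    path <- c(path, best)
    cur_adj <- fit_ols(y, X[, terms, drop = FALSE])$adj_r2
  }

  selection_path <- c(forced, path)
  terms <- finalize_terms(y, X, terms, forced, directions, options)
  build_lur_model(data, env, terms, selection_path, options)
}

# shared builder state: design matrix incl. forced regional background
builder_env <- function(data, options) {
  X <- predictor_matrix(data$predictors)
  vars <- data$predictors$vars
  forced <- vars$name[vars$forced]
  directions <- stats::setNames(vars$direction, vars$name)
  if (options$force_background &&
      !"regional_background" %in% colnames(X)) {
    bg <- regional_background_variable(data$annual, data$sites)
    X <- cbind(X, regional_background = bg)
    forced <- c("regional_background", forced)
    directions <- c(directions, regional_background = "positive")
  }
  y <- data$annual$value
  n_min <- length(forced) + 2L
  if (length(y) <= n_min)
    stop_data("supervised_stepwise: too few observations (n=%d)", length(y))
  list(X = X, y = y, forced = forced, directions = directions)
}

# pruning, VIF enforcement and final sign check, iterated to a fixed point
finalize_terms <- function(y, X, terms, forced, directions, options) {
  for (iter in 1:50) {
    before <- terms
    terms <- prune_terms(y, X, terms, forced, options$alpha)
    terms <- vif_terms(y, X, terms, forced, options$alpha, options$vif_max)
    # direction constraints can be broken by a removal; drop violators
    if (length(terms)) {
      f <- fit_ols(y, X[, terms, drop = FALSE])
      viol <- vapply(setdiff(terms, forced), function(tm) {
        d <- directions[[tm]]
        !is.na(d) && ((d == "positive" && f$coef[[tm]] <= 0) ||
                      (d == "negative" && f$coef[[tm]] >= 0))
      }, TRUE)
      if (any(viol)) {
        bad <- setdiff(terms, forced)[viol]
        worst <- bad[which.max(f$p_values[bad])]
        terms <- setdiff(terms, worst)
      }
    }
    if (identical(terms, before)) break
  }
  terms
}

prune_terms <- function(y, X, terms, forced, alpha) {
  repeat {
    if (!length(setdiff(terms, forced))) return(terms)
    f <- fit_ols(y, X[, terms, drop = FALSE])
    p <- f$p_values[setdiff(terms, forced)]
    if (all(p <= alpha, na.rm = TRUE) && !anyNA(p)) return(terms)
    p[is.na(p)] <- Inf
    terms <- setdiff(terms, names(p)[which.max(p)])
  }
}

vif_terms <- function(y, X, terms, forced, alpha, vif_max) {
  repeat {
    if (length(terms) < 2L) return(terms)
    v <- vif(X[, terms, drop = FALSE])
    if (max(v) < vif_max) return(terms)
    droppable <- setdiff(terms, forced)
    if (!length(droppable))
      stop_data("enforce_vif: forced terms are collinear (max VIF %.2f)",
                max(v))
    worst <- droppable[which.max(v[droppable])]
    terms <- setdiff(terms, worst)
    terms <- prune_terms(y, X, terms, forced, alpha)
  }
}

build_lur_model <- function(data, env, terms, selection_path, options) {
  y <- env$y; X <- env$X
  f <- if (length(terms)) fit_ols(y, X[, terms, drop = FALSE])
       else fit_ols(y, X[, 0, drop = FALSE])
  # cumulative R2 path over the final terms in entry order
  r2_path <- adj_path <- numeric(length(terms))
  for (k in seq_along(terms)) {
    fk <- fit_ols(y, X[, terms[seq_len(k)], drop = FALSE])
    r2_path[k] <- fk$r2; adj_path[k] <- fk$adj_r2
  }
  vifs <- if (length(terms) >= 2L) vif(X[, terms, drop = FALSE])
          else stats::setNames(rep(1, length(terms)), terms)
  term_df <- data.frame(
    name = terms,
    beta = unname(f$coef[terms]),
    p_value = unname(f$p_values[terms]),
    vif = unname(vifs[terms]),
    r2_at_entry = r2_path,
    adj_r2_at_entry = adj_path,
    forced = terms %in% env$forced,
    direction = unname(env$directions[terms]),
    stringsAsFactors = FALSE)
  ranges <- data.frame(
    name = terms,
    min = if (length(terms)) apply(X[, terms, drop = FALSE], 2L, min)
          else numeric(0),
    max = if (length(terms)) apply(X[, terms, drop = FALSE], 2L, max)
          else numeric(0),
    stringsAsFactors = FALSE)
  rownames(ranges) <- NULL
  structure(list(
    intercept = unname(f$coef[["(Intercept)"]]),
    terms = term_df, ranges = ranges,
    r2 = f$r2, adj_r2 = f$adj_r2, n = f$n, sigma = f$sigma,
    selection_path = selection_path,
    options = options,
    provenance = list(
      excluded_areas = attr(data, "excluded_areas") %||% character(0),
      areas = sort(unique(data$sites$area_code)),
      n_sites = nrow(data$sites))),
    class = "lur_model")
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("LUR model: n = %d, R2 = %.3f (adj %.3f)\n", x$n, x$r2,
              x$adj_r2))
  cat(sprintf("  intercept %.4g\n", x$intercept))
  if (nrow(x$terms))
    for (i in seq_len(nrow(x$terms)))
      cat(sprintf("  %-28s beta %11.4g  cumR2 %.3f  p %.3g%s\n",
                  x$terms$name[i], x$terms$beta[i], x$terms$r2_at_entry[i],
                  x$terms$p_value[i],
                  if (x$terms$forced[i]) "  (forced)" else ""))
  invisible(x)
}

#' Prune model terms by p-value
#'
#' Iteratively removes the non-forced term with the largest p-value above
#' `alpha`, refitting after each removal. Forced terms are exempt.
#'
#' @param model A `lur_model`.
#' @param data The [lur_data()] the model was fitted on (needed to refit).
#' @param alpha p-value threshold (default 0.1).
#' @return A refitted `lur_model`.
#' @export
prune_by_pvalue <- function(model, data, alpha = 0.1) {
  env <- builder_env(data, model$options)
  forced <- model$terms$name[model$terms$forced]
  terms <- prune_terms(env$y, env$X, model$terms$name, forced, alpha)
  keep_path <- model$selection_path[model$selection_path %in% terms]
  build_lur_model(data, env, model$terms$name[model$terms$name %in% terms],
                  keep_path, model$options)
}

#' Enforce the VIF bound on a fitted model
#'
#' While the maximum VIF is at or above `vif_max`, drops the non-forced term
#' with the largest VIF, refits, and re-runs the p-value pruning.
#'
#' @inheritParams prune_by_pvalue
#' @param vif_max VIF bound (default 3).
#' @return A refitted `lur_model` with max VIF `< vif_max`.
#' @export
enforce_vif <- function(model, data, vif_max = 3) {
  env <- builder_env(data, model$options)
  forced <- model$terms$name[model$terms$forced]
  terms <- vif_terms(env$y, env$X, model$terms$name, forced,
                     model$options$alpha, vif_max)
  keep_path <- model$selection_path[model$selection_path %in% terms]
  build_lur_model(data, env, model$terms$name[model$terms$name %in% terms],
                  keep_path, model$options)
}

#' Predict concentrations from a LUR model
#'
#' Linear prediction with optional predictor truncation: with
#' `truncate = TRUE` every predictor value is clamped to the model's stored
#' training range before the linear combination, preventing extrapolation
#' beyond the conditions the model was developed under. The number of clamped
#' cells is attached as attribute `"truncated"`.
#'
#' @param object A `lur_model`.
#' @param newdata A [lur_data()], a [predictor_table()], or a data frame
#'   containing all model variable columns (including `regional_background`
#'   where the model uses it).
#' @param truncate Clamp predictors to training ranges (default `TRUE`).
#' @param ... Unused.
#' @return Named numeric vector of predictions (ug/m3) with attribute
#'   `"truncated"` = number of clamped predictor cells.
#' @export
predict.lur_model <- function(object, newdata, truncate = TRUE, ...) {
  frame <- prediction_frame(newdata)
  miss <- setdiff(object$terms$name, colnames(frame))
  if (length(miss))
    stop_data("predict: missing variable column(s): %s",
              paste(miss, collapse = ", "))
  M <- frame[, object$terms$name, drop = FALSE]
  truncated <- 0L
  if (truncate && nrow(object$ranges)) {
    for (k in seq_len(nrow(object$ranges))) {
      v <- object$ranges$name[k]
      lo <- object$ranges$min[k]; hi <- object$ranges$max[k]
      out <- M[, v] < lo | M[, v] > hi
      truncated <- truncated + sum(out)
      M[, v] <- pmin(pmax(M[, v], lo), hi)
    }
  }
  pred <- object$intercept +
    drop(as.matrix(M) %*% object$terms$beta)
  names(pred) <- rownames(frame)
  attr(pred, "truncated") <- truncated
  pred
}

# assemble a plain prediction frame (rows named by site_id where available)
prediction_frame <- function(newdata) {
  if (inherits(newdata, "lur_data")) {
    X <- predictor_matrix(newdata$predictors)
    if (!"regional_background" %in% colnames(X)) {
      ok <- any(newdata$sites$site_type == "regional_background")
      if (ok) {
        bg <- regional_background_variable(newdata$annual, newdata$sites)
        X <- cbind(X, regional_background = bg)
      }
    }
    return(as.data.frame(X))
  }
  if (inherits(newdata, "predictor_table")) {
    X <- predictor_matrix(newdata)
    return(as.data.frame(X))
  }
  as.data.frame(newdata)
}
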