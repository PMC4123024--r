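# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(sprintf(...), call. = FALSE)

#' @importFrom withr with_seed
NULL

# Derive a reproducible substream seed from a top-level seed and a stream name.
# All generator randomness flows through this, so individual artifacts (sites,
# roads, noise, ...) can be regenerated independently of one another.
# Kept strictly below 2^31 so it is a valid R integer seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# IQR as 75th - 25th percentile with linear-interpolation quantiles
iqr_linear <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
}

median_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}
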