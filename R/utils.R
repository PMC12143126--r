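# internal argument checks ----------------------------------------------------

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_config("`%s` must be a finite scalar in [%s, %s]", name, lo, hi)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_config("`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

# greatest common divisor, for rational resampling ratios
gcd <- function(a, b) {
  while (b > 0L) { tmp <- a %% b; a <- b; b <- tmp }
  a
}

# z-score columns by given centre/scale
zscore_apply <- function(x, centre, scale) {
  sweep(sweep(x, 2L, centre, "-"), 2L, scale, "/")
}

# type-7 (linear interpolation) 95th percentile
percentile95 <- function(x) as.numeric(stats::quantile(x, 0.95, type = 7, names = FALSE))
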