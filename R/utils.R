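#' @useDynLib circanuc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm coef vcov pt sd median quantile cor cor.test t.test
#'   fft rnorm runif rpois rgeom qnorm complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

MINUTES_PER_DAY <- 1440L

#' Parse a clock time to minutes since midnight
#'
#' Accepts `"HH:MM"` strings or numeric minutes; values are reduced modulo
#' 24 h.
#'
#' @param x character `"HH:MM"` vector or numeric minutes since midnight.
#' @return numeric minutes in `[0, 1440)`.
#' @export
clock_to_minutes <- function(x) {
  if (is.numeric(x)) return(x %% MINUTES_PER_DAY)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("clock times must be 'HH:MM', got: ", x[bad][1])
  vapply(parts, function(p) {
    (as.numeric(p[1]) * 60 + as.numeric(p[2])) %% MINUTES_PER_DAY
  }, numeric(1))
}

#' Format hours-of-day as "HH:MM"
#'
#' @param hours numeric clock hours in `[0, 24)`; reduced modulo 24.
#' @return character vector.
#' @export
format_clock <- function(hours) {
  m <- round((hours %% 24) * 60)
  m <- m %% MINUTES_PER_DAY
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

## --- circular statistics on a 24-h clock (hours) -------------------------

circ_mean_hours <- function(h, w = NULL, period = 24) {
  ang <- 2 * pi * h / period
  if (is.null(w)) w <- rep(1, length(h))
  s <- sum(w * sin(ang)); c <- sum(w * cos(ang))
  if (abs(s) < 1e-12 && abs(c) < 1e-12) return(NA_real_)
  (atan2(s, c) * period / (2 * pi)) %% period
}

circ_dist_hours <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# Circular median: the sample point (or circular mean of tied points)
# minimizing total arc distance to all observations.
circ_median_hours <- function(h, period = 24) {
  h <- h[!is.na(h)]
  if (!length(h)) return(NA_real_)
  tot <- vapply(h, function(c0) sum(circ_dist_hours(h, c0, period)), numeric(1))
  best <- h[tot <= min(tot) + 1e-9]
  circ_mean_hours(unique(best), period = period)
}

# Quantiles of clock hours computed on the line after centering at the
# circular median (wrapped to +/- period/2), then mapped back.
circ_quantile_hours <- function(h, probs, period = 24) {
  h <- h[!is.na(h)]
  if (!length(h)) return(rep(NA_real_, length(probs)))
  ctr <- circ_median_hours(h, period)
  dev <- ((h - ctr + period / 2) %% period) - period / 2
  (ctr + quantile(dev, probs, names = FALSE, type = 7)) %% period
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open = TRUE) {
  ok <- if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) stop_param(name, " must lie in ", if (open) "(0,1)" else "[0,1]")
}
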