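## Non-HMM rest-activity indices: dichotomy index I<O, 24-h autocorrelation
## r24, dominant period by a resampled smoothed periodogram, and the 24-h
## activity cosinor.

#' Dichotomy index I<O
#'
#' Percentage of in-bed epochs whose activity count is strictly less than the
#' median out-of-bed count. In-bed/out-of-bed status comes from the diary,
#' not from the HMM; epochs are pooled over the whole recording and the
#' out-of-bed median is computed once on the pooled out-of-bed epochs.
#' Values near 100\% indicate a robust rest-activity rhythm.
#'
#' @param series an [actigraphy_series()] with diary intervals.
#' @return percentage in \[0, 100\].
#' @export
dichotomy_index <- function(series) {
  stopifnot(inherits(series, "actigraphy_series"))
  if (is.null(series$diary))
    stop_param("dichotomy index requires diary in-bed intervals")
  inbed <- in_bed_epochs(series)
  if (!any(inbed)) stop_param("no in-bed epochs fall inside the recording")
  if (all(inbed)) stop_param("no out-of-bed epochs fall inside the recording")
  o_med <- median(series$counts[!inbed])
  100 * mean(series$counts[inbed] < o_med)
}

#' 24-h autocorrelation r24
#'
#' Pearson correlation of the count series with itself at a 24-h lag, over
#' all overlapping pairs: a measure of day-to-day regularity of the
#' rest-activity pattern.
#'
#' @param series an [actigraphy_series()] of at least 48 h.
#' @return correlation in \[-1, 1\], or `NA` for a constant series.
#' @export
autocorr24 <- function(series) {
  stopifnot(inherits(series, "actigraphy_series"))
  lag <- MINUTES_PER_DAY %/% series$epoch_minutes
  n <- length(series$counts)
  if (n <= lag) stop_param("r24 requires at least 48 h of data")
  x <- series$counts[seq_len(n - lag)]
  y <- series$counts[seq_len(n - lag) + lag]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# Smoothed zero-padded periodogram peak in a period band (hours).
.periodogram_peak <- function(counts, epoch_minutes, band = c(16, 32),
                              pad_factor = 8L, span = 5L) {
  x <- counts - mean(counts)
  n <- length(x)
  nfft <- 2^ceiling(log2(pad_factor * n))
  p <- Mod(fft(c(x, numeric(nfft - n))))^2 / n
  k <- seq_len(nfft %/% 2)              # positive frequencies
  period_h <- (nfft / k) * epoch_minutes / 60
  ## light Daniell smoothing (Welch-type) over the padded grid
  if (span > 1L) {
    ker <- rep(1 / span, span)
    ps <- stats::filter(p[k + 1], ker, sides = 2)
  } else ps <- p[k + 1]
  sel <- which(period_h >= band[1] & period_h <= band[2] & !is.na(ps))
  if (!length(sel)) stop_param("no periodogram frequencies in the search band")
  i <- sel[which.max(ps[sel])]
  ## quadratic interpolation of the peak on the frequency axis
  if (i > 1 && i < length(ps) && !is.na(ps[i - 1]) && !is.na(ps[i + 1])) {
    y1 <- ps[i - 1]; y2 <- ps[i]; y3 <- ps[i + 1]
    den <- y1 - 2 * y2 + y3
    delta <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
    delta <- max(min(delta, 0.5), -0.5)
    kk <- i + delta
  } else kk <- i
  (nfft / kk) * epoch_minutes / 60
}

#' Dominant period with a resampling confidence interval
#'
#' Point estimate: the period of maximum smoothed, zero-padded periodogram
#' power in a 16-32 h search band. Uncertainty: the recording is split into
#' whole days, day-blocks are resampled with replacement, and the peak
#' period is re-estimated on each resample; the CI is the 2.5\%/97.5\%
#' quantile of the resampled estimates.
#'
#' @param series an [actigraphy_series()] of at least 3 days.
#' @param n_resamples number of day-block resamples (default 100).
#' @param seed integer seed for the resampling.
#' @param band search band in hours (default `c(16, 32)`).
#' @return list: `period_h`, `ci` (length-2), `resamples`.
#' @export
dominant_period <- function(series, n_resamples = 100L, seed = 1L,
                            band = c(16, 32)) {
  stopifnot(inherits(series, "actigraphy_series"))
  if (series_hours(series) < 72)
    stop_param("dominant period requires at least 3 days of data")
  if (band[1] >= band[2]) stop_param("empty search band")
  est <- .periodogram_peak(series$counts, series$epoch_minutes, band)
  per_day <- MINUTES_PER_DAY %/% series$epoch_minutes
  n_days <- length(series$counts) %/% per_day
  blocks <- split(series$counts[seq_len(n_days * per_day)],
                  rep(seq_len(n_days), each = per_day))
  set.seed(as.integer(seed))
  res <- vapply(seq_len(n_resamples), function(b) {
    xs <- unlist(blocks[sample.int(n_days, n_days, replace = TRUE)],
                 use.names = FALSE)
    .periodogram_peak(xs, series$epoch_minutes, band)
  }, numeric(1))
  list(period_h = est,
       ci = quantile(res, c(0.025, 0.975), names = FALSE),
       resamples = res)
}

#' Single-component 24-h cosinor of the activity counts
#'
#' Least-squares fit of `counts = M + A cos(2 pi t / 24 + theta)` on the raw
#' count scale; the acrophase is reported as the clock time of the fitted
#' peak.
#'
#' @param series an [actigraphy_series()].
#' @return list: `mesor`, `amplitude`, `acrophase_h` (clock hours of peak),
#'   `p_value` (amplitude t-test, df = n - 3).
#' @export
activity_cosinor <- function(series) {
  stopifnot(inherits(series, "actigraphy_series"))
  t_h <- epoch_start_minutes(series) / 60
  h <- .harmonic_lm(t_h, series$counts, periods = 24)
  list(mesor = h$M, amplitude = h$A[1],
       acrophase_h = (-h$theta[1] * 24 / (2 * pi)) %% 24,
       p_value = h$p[1])
}

#' All rest-activity indices for one recording
#'
#' Convenience wrapper running [fit_hmm()], [fingerprint()],
#' [hmm_indices()], [dichotomy_index()], [autocorr24()],
#' [dominant_period()] and [activity_cosinor()].
#'
#' @param series an [actigraphy_series()] with diary.
#' @param n_restarts,seed,n_resamples passed to the component fits.
#' @return one-row data.frame of all indices.
#' @export
rest_activity_indices <- function(series, n_restarts = 50L, seed = 1L,
                                  n_resamples = 100L) {
  model <- fit_hmm(series, n_restarts = n_restarts, seed = seed)
  fp <- fingerprint(series, model)
  idx <- hmm_indices(fp, model, series)
  dp <- dominant_period(series, n_resamples = n_resamples, seed = seed)
  ac <- activity_cosinor(series)
  cbind(data.frame(i_lt_o = dichotomy_index(series),
                   r24 = autocorr24(series)),
        idx,
        data.frame(dominant_period_h = dp$period_h,
                   dominant_period_lo = dp$ci[1],
                   dominant_period_hi = dp$ci[2],
                   activity_amplitude = ac$amplitude,
                   activity_acrophase_h = ac$acrophase_h))
}
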