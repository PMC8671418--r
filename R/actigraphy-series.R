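#' Construct an actigraphy time series
#'
#' Container for uniformly spaced, non-negative wrist-activity counts with a
#' per-night diary of in-bed intervals. Time is handled as timezone-naive
#' local clock time: epoch `i` starts at `start_min + (i-1) * epoch_minutes`
#' minutes after midnight of study day 0, on a half-open interval
#' `[t, t + epoch)`.
#'
#' @param counts non-negative numeric vector, one value per epoch.
#' @param epoch_minutes positive integer epoch length (default 1 min).
#' @param start_min clock minutes after midnight of day 0 at which the
#'   recording starts (default 0).
#' @param diary `NULL` or a data.frame with columns `day` (integer night
#'   index; the night of day `d` begins on day `d`), `bed_start`, `bed_end`
#'   (clock minutes or `"HH:MM"`). Intervals may wrap midnight, in which case
#'   the in-bed window extends into day `d + 1`.
#' @return an object of class `actigraphy_series`.
#' @export
actigraphy_series <- function(counts, epoch_minutes = 1L, start_min = 0,
                              diary = NULL) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts))) stop_param("activity counts must be finite")
  if (any(counts < 0)) stop_param("activity counts must be non-negative")
  epoch_minutes <- as.integer(epoch_minutes)
  if (epoch_minutes < 1L) stop_param("epoch_minutes must be a positive integer")
  if (!is.null(diary)) {
    need <- c("day", "bed_start", "bed_end")
    if (!all(need %in% names(diary)))
      stop_param("diary needs columns: ", paste(need, collapse = ", "))
    diary <- data.frame(day = as.integer(diary$day),
                        bed_start = clock_to_minutes(diary$bed_start),
                        bed_end = clock_to_minutes(diary$bed_end))
    if (any((diary$bed_end - diary$bed_start) %% MINUTES_PER_DAY == 0))
      stop_param("diary bed interval is degenerate (start == end)")
  }
  structure(list(counts = counts, epoch_minutes = epoch_minutes,
                 start_min = as.numeric(start_min), diary = diary),
            class = "actigraphy_series")
}

# Absolute start minute (since midnight of day 0) of each epoch.
epoch_start_minutes <- function(series) {
  series$start_min +
    (seq_along(series$counts) - 1) * series$epoch_minutes
}

# Clock minute-of-day of each epoch start.
epoch_clock_minutes <- function(series) {
  epoch_start_minutes(series) %% MINUTES_PER_DAY
}

series_hours <- function(series) {
  length(series$counts) * series$epoch_minutes / 60
}

# Logical vector: epoch lies inside a diary in-bed interval.
in_bed_epochs <- function(series) {
  if (is.null(series$diary)) stop_param("series has no diary in-bed intervals")
  t0 <- epoch_start_minutes(series)
  inbed <- logical(length(t0))
  for (k in seq_len(nrow(series$diary))) {
    d <- series$diary$day[k]
    s <- series$diary$bed_start[k]
    e <- series$diary$bed_end[k]
    dur <- (e - s) %% MINUTES_PER_DAY
    a <- d * MINUTES_PER_DAY + s
    inbed <- inbed | (t0 >= a & t0 < a + dur)
  }
  inbed
}

#' @export
print.actigraphy_series <- function(x, ...) {
  cat(sprintf("<actigraphy_series> %d epochs of %d min (%.1f days)\n",
              length(x$counts), x$epoch_minutes,
              series_hours(x) / 24))
  if (!is.null(x$diary))
    cat(sprintf("  diary: %d in-bed intervals\n", nrow(x$diary)))
  invisible(x)
}
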