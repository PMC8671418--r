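# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Two-day series (2880 min) with a flat diary window and fully controlled
# counts: `inbed_value` inside 00:00-08:00 each day, `out_value` outside.
toy_series <- function(inbed_value = 0, out_value = 50, n_days = 2) {
  clock <- rep(seq_len(n_days * 1440) - 1, 1) %% 1440
  counts <- ifelse(clock < 480, inbed_value, out_value)
  actigraphy_series(counts,
                    diary = data.frame(day = 0:(n_days - 1),
                                       bed_start = 0, bed_end = 480))
}

# Sinusoidal count series: mesor + amp * cos(2 pi (t - peak_h)/period_h).
sine_series <- function(period_h = 24, n_days = 5, mesor = 50, amp = 20,
                        peak_h = 15, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t_h <- (seq_len(n_days * 1440) - 1) / 60
  counts <- mesor + amp * cos(2 * pi * (t_h - peak_h) / period_h) +
    rnorm(length(t_h), 0, noise_sd)
  actigraphy_series(pmax(counts, 0))
}

# A well-separated actigraphy parameter set used for state-recovery checks.
separated_params <- function(...) {
  args <- list(emission_means = c(0.3, 3.3, 5.3),
               emission_sds = c(0.35, 0.5, 0.45),
               bedtime_jitter_sd = 5, night_interruption_rate = 0.5)
  over <- list(...)
  args[names(over)] <- over
  do.call(actigraphy_params, args)
}

# Brute-force cosinor oracle: profile the two phases over a grid, solving
# the conditional linear least-squares (M, A12, A24) at each phase pair.
# Independent of the package's linearized cos/sin fit.
grid_cosinor_oracle <- function(t_h, y_log, n_grid = 72) {
  phis <- seq(-pi, pi, length.out = n_grid + 1)[-(n_grid + 1)]
  best <- NULL
  for (p12 in phis) {
    x12 <- cos(2 * pi * t_h / 12 + p12)
    for (p24 in phis) {
      x24 <- cos(2 * pi * t_h / 24 + p24)
      X <- cbind(1, x12, x24)
      b <- qr.coef(qr(X), y_log)
      sse <- sum((y_log - X %*% b)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(sse = sse, M = b[1], A12 = b[2], A24 = b[3],
                     phase12 = p12, phase24 = p24)
      }
    }
  }
  ## canonicalize negative amplitudes (A cos(wt+phi) = -A cos(wt+phi+pi))
  for (k in c("12", "24")) {
    a <- best[[paste0("A", k)]]
    if (a < 0) {
      best[[paste0("A", k)]] <- -a
      ph <- best[[paste0("phase", k)]] + pi
      best[[paste0("phase", k)]] <- ((ph + pi) %% (2 * pi)) - pi
    }
  }
  best
}

# Circular absolute difference in hours on a `period`-hour clock.
circ_abs_h <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
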