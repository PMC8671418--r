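## Three-state hidden Markov segmentation of actigraphy.
##
## Activity counts are log1p-transformed and modelled as a homogeneous
## Gaussian HMM with states labelled, in order of emission mean, IA
## (inactive/rest), MA (moderately active) and HA (highly active). The fit
## thresholds the recording into the three states probabilistically; the
## per-clock-time posterior of IA ("state fingerprint") drives the rest
## duration, center of rest and Rhythm Index summaries.

#' Fit the 3-state Gaussian HMM to an actigraphy series
#'
#' Baum-Welch (EM) maximum likelihood on `log1p(counts)`, restarted from
#' perturbed quantile-based initializations; the restart with the highest
#' log-likelihood is kept and its states are relabelled so that emission
#' means are increasing (IA lowest).
#'
#' @param series an [actigraphy_series()] of at least 24 h.
#' @param n_restarts number of EM restarts (default 50).
#' @param seed integer seed controlling the restart initializations.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change falls below `tol` (default `1e-8`) or after
#'   `max_iter` (default 500) iterations. Non-convergence is recorded in the
#'   returned object, not silently ignored.
#' @param sd_floor lower bound on the emission SDs (log1p scale, default
#'   0.2). Counts are integers, so low-activity epochs concentrate on a few
#'   discrete values; without a floor on the natural scale of log1p counts,
#'   EM collapses a state onto the zero-count spike.
#' @return an `hmm_model`: `means`, `sds` (log1p scale), `trans` (3x3
#'   row-stochastic), `init`, `loglik`, `converged`, `n_iter`, `states`
#'   (Viterbi path, 1 = IA, 2 = MA, 3 = HA).
#' @export
fit_hmm <- function(series, n_restarts = 50L, seed = 1L,
                    max_iter = 500L, tol = 1e-8, sd_floor = 0.2) {
  stopifnot(inherits(series, "actigraphy_series"))
  if (series_hours(series) < 24)
    stop_param("insufficient data: need at least 24 h of actigraphy")
  y <- log1p(series$counts)
  if (any(!is.finite(y))) stop_param("counts must be finite")
  if (length(unique(y)) < 3L)
    stop_param("degenerate series: fewer than 3 distinct activity levels, ",
               "no 3-state model is identifiable")

  set.seed(as.integer(seed))
  base_q <- c(1, 3, 5) / 6
  sd0 <- max(sd(y) / 2, 1e-2)
  best <- NULL
  for (r in seq_len(max(1L, as.integer(n_restarts)))) {
    probs <- if (r == 1L) base_q else sort(runif(3, 0.02, 0.98))
    mu0 <- as.numeric(quantile(y, probs, names = FALSE))
    mu0 <- mu0 + c(-1e-3, 0, 1e-3) * (r > 1L)   # break exact ties
    trans0 <- matrix(0.05, 3, 3); diag(trans0) <- 0.9
    fit <- .hmm_em_cpp(y, mu0, rep(max(sd0, sd_floor), 3), trans0,
                       rep(1 / 3, 3), as.integer(max_iter), tol, sd_floor)
    if (is.finite(fit$loglik) &&
        (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop_param("EM failed on every restart")

  perm <- order(best$means)
  model <- structure(list(
    n_states = 3L,
    state_labels = c("IA", "MA", "HA"),
    means = best$means[perm], sds = best$sds[perm],
    trans = best$trans[perm, perm, drop = FALSE],
    init = best$init[perm],
    loglik = best$loglik, converged = best$converged,
    n_iter = best$n_iter, transform = "log1p"), class = "hmm_model")
  if (!model$converged)
    warning("EM did not reach the tolerance within max_iter; ",
            "result flagged non-converged", call. = FALSE)
  model$states <- viterbi_states(series, model)
  model
}

#' Most likely (Viterbi) state path
#'
#' @param series an [actigraphy_series()].
#' @param model a fitted [fit_hmm()] model.
#' @return integer vector of states (1 = IA, 2 = MA, 3 = HA).
#' @export
viterbi_states <- function(series, model) {
  .hmm_viterbi_cpp(log1p(series$counts), model$means, model$sds,
                   model$trans, model$init)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model> 3-state Gaussian HMM on log1p counts\n")
  cat("  emission means:", sprintf("%.3f", x$means), "\n")
  cat(sprintf("  p1-1 (IA self-transition): %.4f  loglik: %.1f (%s)\n",
              x$trans[1, 1], x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' 24-h state-probability fingerprint
#'
#' Forward-backward posterior state probabilities, averaged over recording
#' days within clock-time bins. The result summarizes the individual's
#' typical daily rest-activity behaviour: for a regular sleeper the IA
#' probability is near 1 inside the habitual rest window and near 0 outside.
#'
#' @param series an [actigraphy_series()].
#' @param model a fitted [fit_hmm()] model.
#' @param bin_minutes clock-time bin width (default 10 min).
#' @return a `state_fingerprint` data.frame with `time_min` (bin start,
#'   minutes after midnight), `p_IA`, `p_MA`, `p_HA`; rows sum to 1.
#' @export
fingerprint <- function(series, model, bin_minutes = 10L) {
  stopifnot(inherits(model, "hmm_model"))
  post <- .hmm_posterior_cpp(log1p(series$counts), model$means, model$sds,
                             model$trans, model$init)$gamma
  bin <- (epoch_clock_minutes(series) %/% bin_minutes) * bin_minutes
  agg <- rowsum(post, bin)
  cnt <- rowsum(rep(1, length(bin)), bin)
  agg <- agg / as.vector(cnt)
  out <- data.frame(time_min = as.numeric(rownames(agg)),
                    p_IA = agg[, 1], p_MA = agg[, 2], p_HA = agg[, 3])
  rownames(out) <- NULL
  structure(out[order(out$time_min), ],
            class = c("state_fingerprint", "data.frame"),
            bin_minutes = as.numeric(bin_minutes))
}

#' Build a fingerprint from an explicit IA-probability profile
#'
#' Utility for constructing reference fingerprints (square waves, flat
#' profiles) when studying the limit behaviour of the indices.
#'
#' @param p_ia IA probability per bin over 24 h.
#' @param bin_minutes bin width; `length(p_ia) * bin_minutes` must be 1440.
#' @param p_ma MA probability per bin (remainder goes to HA).
#' @return a `state_fingerprint`.
#' @export
fingerprint_from_profile <- function(p_ia, bin_minutes = 10L, p_ma = NULL) {
  if (length(p_ia) * bin_minutes != MINUTES_PER_DAY)
    stop_param("profile must tile 24 h: length(p_ia) * bin_minutes == 1440")
  check_prob(p_ia, "p_ia", open = FALSE)
  if (is.null(p_ma)) p_ma <- (1 - p_ia) / 2
  structure(data.frame(time_min = (seq_along(p_ia) - 1) * bin_minutes,
                       p_IA = p_ia, p_MA = p_ma, p_HA = 1 - p_ia - p_ma),
            class = c("state_fingerprint", "data.frame"),
            bin_minutes = as.numeric(bin_minutes))
}

# Integral of the fingerprint IA profile (hours) over an arbitrary clock
# window [from, to) given in hours (may wrap); exact for the step profile.
.ia_integral <- function(fp, from = 0, to = 24) {
  w <- attr(fp, "bin_minutes") / 60
  starts <- fp$time_min / 60
  len <- (to - from) %% 24
  if (len == 0) len <- 24
  segs <- if (from %% 24 + len <= 24) {
    list(c(from %% 24, from %% 24 + len))
  } else {
    list(c(from %% 24, 24), c(0, (from + len) %% 24))
  }
  total <- 0
  for (s in segs) {
    overlap <- pmax(0, pmin(starts + w, s[2]) - pmax(starts, s[1]))
    total <- total + sum(fp$p_IA * overlap)
  }
  total
}

#' Rest-activity indices derived from the HMM fit
#'
#' Computes the rest duration `a` (integral of the IA probability profile
#' over 24 h), the center of rest `c` (circular gravity center of clock time
#' weighted by IA probability), the Rhythm Index, the IA self-transition
#' probability p1-1, and the median activity count in the HA state.
#'
#' The Rhythm Index is `100 * (W - a^2/24) / (a - a^2/24)` clipped to
#' \[0, 100\], where `W` is the IA integral over the `a`-hour window centered
#' at `c`. It equals 100\% when all rest probability mass falls in a single
#' regular daily window (square-wave profile) and 0\% when the IA profile is
#' uniform over the 24 h (no circadian regulation of rest); it is undefined
#' (`NA`) when `a` is 0 or 24.
#'
#' @param fp a [fingerprint()] (or [fingerprint_from_profile()]).
#' @param model optional fitted [fit_hmm()] model (for `p11`, `median_ha`).
#' @param series optional matching series (for `median_ha`).
#' @return a one-row data.frame: `p11`, `median_ha`, `rest_duration_a`
#'   (hours), `center_of_rest_c` (clock hours), `rhythm_index` (percent).
#' @export
hmm_indices <- function(fp, model = NULL, series = NULL) {
  stopifnot(inherits(fp, "state_fingerprint"))
  w <- attr(fp, "bin_minutes") / 60
  a <- sum(fp$p_IA * w)
  mid_h <- (fp$time_min / 60) + w / 2
  c_h <- circ_mean_hours(mid_h, w = fp$p_IA * w)
  ri <- NA_real_
  if (a > 1e-9 && a < 24 - 1e-9) {
    ## an exactly uniform profile has no circular center; any window
    ## placement then gives W = a^2/24, i.e. RI = 0
    c_ri <- if (is.na(c_h)) 0 else c_h
    W <- .ia_integral(fp, from = c_ri - a / 2, to = c_ri + a / 2)
    ri <- 100 * (W - a^2 / 24) / (a - a^2 / 24)
    ri <- min(max(ri, 0), 100)
  }
  p11 <- if (!is.null(model)) model$trans[1, 1] else NA_real_
  med_ha <- NA_real_
  if (!is.null(model) && !is.null(series)) {
    st <- model$states %||% viterbi_states(series, model)
    ha <- series$counts[st == 3L]
    med_ha <- if (length(ha)) median(ha) else NA_real_
  }
  data.frame(p11 = p11, median_ha = med_ha, rest_duration_a = a,
             center_of_rest_c = c_h, rhythm_index = ri)
}
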