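## Multiple-component cosinor rhythmometry.
##
## The working model for a timed excretion series is
##   log y(t) = M + A12 cos(2 pi t / 12 + theta12)
##                + A24 cos(2 pi t / 24 + theta24) + e(t),
## with fixed periods of 12 and 24 h. Because the periods are fixed, the
## model is linear in (M, A cos(theta), -A sin(theta)) and is fitted exactly
## by least squares on cos/sin regressors, then converted to
## amplitude/phase; this avoids nonconvex nonlinear starts. A component is
## called rhythmic when its amplitude differs from zero by a t-test at a
## liberal threshold (default p <= 0.1, chosen for sparse 10-sample
## designs).

# Linear harmonic regression. Returns amplitudes/phases per period with
# delta-method standard errors; exact for the fixed-period cosinor model.
.harmonic_lm <- function(t_h, y, periods) {
  n <- length(y)
  X <- cbind(1, do.call(cbind, lapply(periods, function(Tp) {
    w <- 2 * pi * t_h / Tp
    cbind(cos(w), sin(w))
  })))
  colnames(X) <- c("M", as.vector(rbind(paste0("c", periods),
                                        paste0("s", periods))))
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop_param("singular cosinor design: sampling times do not separate ",
               "the harmonic components")
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - ncol(X)
  if (df < 1) stop_param("not enough samples for the requested components")
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))

  k <- length(periods)
  A <- theta <- se <- tval <- pval <- numeric(k)
  for (j in seq_len(k)) {
    ic <- 2 * j; is <- 2 * j + 1
    bc <- beta[ic]; bs <- beta[is]
    A[j] <- sqrt(bc^2 + bs^2)
    theta[j] <- atan2(-bs, bc)
    if (A[j] > 0 && sigma2 > 0) {
      g <- c(bc, bs) / A[j]
      V <- sigma2 * XtXinv[c(ic, is), c(ic, is)]
      se[j] <- sqrt(drop(t(g) %*% V %*% g))
    } else se[j] <- 0
    if (se[j] > 0) {
      tval[j] <- A[j] / se[j]
      ## zero-amplitude test: exact Wald/F test of the component's
      ## (cos, sin) coefficient pair; the naive t-test on the folded
      ## amplitude over-rejects badly at n = 10
      Vinv <- solve(sigma2 * XtXinv[c(ic, is), c(ic, is)])
      W <- drop(t(c(bc, bs)) %*% Vinv %*% c(bc, bs)) / 2
      pval[j] <- stats::pf(W, 2, df, lower.tail = FALSE)
    } else {
      ## perfect fit (or exactly-zero amplitude): decide by amplitude size
      tval[j] <- if (A[j] > 1e-10) Inf else 0
      pval[j] <- if (A[j] > 1e-10) 0 else 1
    }
  }
  list(M = unname(beta[1]), A = A, theta = theta, se = se, t = tval, p = pval,
       beta = unname(beta), residuals = res, fitted = fitted, df = df,
       sigma2 = sigma2, X = X, XtXinv = XtXinv, periods = periods)
}

#' Eligibility for cosinor analysis
#'
#' A patient's series enters the cosinor analysis only with at least
#' `min_samples` valid timed samples (finite time, finite strictly positive
#' concentration); sparser series are excluded to avoid over-fitting the
#' 5-parameter model.
#'
#' @param time_h sampling times (hours).
#' @param concentration concentrations (same length).
#' @param min_samples minimum number of valid samples (default 7).
#' @return list: `eligible`, `n_valid`, `n_total`.
#' @export
check_eligibility <- function(time_h, concentration, min_samples = 7L) {
  valid <- is.finite(time_h) & is.finite(concentration) & concentration > 0
  list(eligible = sum(valid) >= min_samples, n_valid = sum(valid),
       n_total = length(concentration))
}

#' Fit the two-component (12 h + 24 h) cosinor model
#'
#' Fits the cosinor model to the natural log of the concentrations and
#' back-transforms for reporting: the reported mesor is `exp(M)` and the
#' reported overall amplitude is half the max-min range of the exponentiated
#' fitted curve over a dense 24-h grid; the overall acrophase is the clock
#' time of that curve's maximum (earliest grid time on ties).
#'
#' @param time_h sampling times in hours from day-1 midnight (replicate
#'   clock times on day 2 enter at `t + 24`, equivalent under the 24-h
#'   periodic model). Must span at least 24 h.
#' @param concentration strictly positive concentrations (ug/g creatinine).
#' @param periods component periods in hours (default `c(12, 24)`).
#' @param alpha amplitude-test threshold for the rhythm flags (default 0.1).
#' @param patient_id,nucleoside optional labels carried into summaries.
#' @param grid_minutes resolution of the back-transform grid (default 1).
#' @return a `cosinor_fit` object. Log-scale parameters: `M`, `A12`, `A24`,
#'   `theta12`, `theta24` (radians), per-amplitude `se`/`p`; reported scale:
#'   `mesor`, `overall_A`, `relative_amplitude` (fraction of mesor),
#'   `overall_acrophase_h`; plus `residuals` (log scale), rhythm flags and
#'   `n_samples`.
#' @export
fit_multicomponent_cosinor <- function(time_h, concentration,
                                       periods = c(12, 24), alpha = 0.1,
                                       patient_id = NULL, nucleoside = NULL,
                                       grid_minutes = 1) {
  ok <- is.finite(time_h) & is.finite(concentration)
  if (any(concentration[ok] <= 0))
    stop_param("non-positive concentration: cosinor is fitted on log values")
  time_h <- time_h[ok]; concentration <- concentration[ok]
  n <- length(concentration)
  if (n < 7L)
    stop_param("eligibility: fewer than 7 valid timed samples (n = ", n, ")")
  if (diff(range(time_h)) < 24 - 1e-9)
    stop_param("sampling times must span at least 24 h")

  h <- .harmonic_lm(time_h, log(concentration), periods)
  fit <- structure(list(
    periods = periods, M = h$M, A = setNames(h$A, paste0("A", periods)),
    theta = setNames(h$theta, paste0("theta", periods)),
    se = setNames(h$se, paste0("A", periods)),
    t = h$t, p = setNames(h$p, paste0("A", periods)),
    residuals = h$residuals, fitted_log = h$fitted, df = h$df,
    sigma2 = h$sigma2, time_h = time_h, y_log = log(concentration),
    X = h$X, XtXinv = h$XtXinv,
    n_samples = n, patient_id = patient_id, nucleoside = nucleoside,
    grid_minutes = grid_minutes), class = "cosinor_fit")

  bt <- .cosinor_backtransform(h$beta, periods, grid_minutes)
  fit$mesor <- exp(h$M)
  fit$overall_A <- bt$overall_A
  fit$relative_amplitude <- bt$overall_A / fit$mesor
  fit$overall_acrophase_h <- bt$acrophase_h

  flags <- detect_rhythm(fit, alpha = alpha)
  fit[names(flags)] <- flags
  fit
}

# Dense-grid exponentiated fitted curve -> overall amplitude and acrophase.
.cosinor_backtransform <- function(beta, periods, grid_minutes = 1) {
  tg <- seq(0, 24 - grid_minutes / 60, by = grid_minutes / 60)
  Xg <- cbind(1, do.call(cbind, lapply(periods, function(Tp) {
    w <- 2 * pi * tg / Tp
    cbind(cos(w), sin(w))
  })))
  curve <- exp(drop(Xg %*% beta))
  list(overall_A = (max(curve) - min(curve)) / 2,
       acrophase_h = tg[which.max(curve)])
}

# Convenience accessors used throughout.
#' @export
`$.cosinor_fit` <- function(x, name) {
  if (name %in% c("A12", "A24")) {
    p <- sub("^A", "", name)
    v <- unclass(x)$A
    return(if (paste0("A", p) %in% names(v)) v[[paste0("A", p)]] else NULL)
  }
  if (name %in% c("theta12", "theta24")) {
    v <- unclass(x)$theta
    return(if (name %in% names(v)) v[[name]] else NULL)
  }
  unclass(x)[[name]]
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> n = %d samples, periods %s h\n", x$n_samples,
              paste(x$periods, collapse = "+")))
  cat(sprintf("  mesor %.3g, overall amplitude %.3g (%.2f of mesor), acrophase %s\n",
              x$mesor, x$overall_A, x$relative_amplitude,
              format_clock(x$overall_acrophase_h)))
  pv <- unclass(x)$p
  cat("  amplitude p-values:",
      paste(sprintf("%s = %.3g", names(pv), pv), collapse = ", "), "\n")
  cat(sprintf("  rhythmic (alpha = %.2g): %s\n", x$alpha,
              if (isTRUE(x$rhythmic_any)) "yes" else "no"))
  invisible(x)
}

#' Rhythm detection from a cosinor fit
#'
#' A component is rhythmic when its amplitude t-test (df = n - 5 for the
#' two-component model) gives p <= `alpha`; the series is rhythmic when any
#' component is. The default threshold of 0.1 is deliberately liberal for
#' 10-sample designs.
#'
#' @param fit a [fit_multicomponent_cosinor()] object.
#' @param alpha significance threshold in \[0, 1\].
#' @return list of flags `rhythmic_12h`, `rhythmic_24h` (for the default
#'   periods), `rhythmic_any`, with `alpha`.
#' @export
detect_rhythm <- function(fit, alpha = 0.1) {
  stopifnot(inherits(fit, "cosinor_fit"))
  se <- unclass(fit)$se
  if (is.null(se) || any(!is.finite(se)))
    stop_param("fit carries no valid amplitude standard errors")
  p <- unclass(fit)$p
  hit <- alpha > 0 & p <= alpha
  flags <- as.list(setNames(hit, paste0("rhythmic_", fit$periods, "h")))
  flags$rhythmic_any <- any(hit)
  flags$alpha <- alpha
  flags
}

#' Per-patient parameter table from a list of cosinor fits
#'
#' @param fits list of `cosinor_fit` objects.
#' @return data.frame with one row per fit.
#' @export
cosinor_parameter_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(patient_id = f$patient_id %||% NA_character_,
               nucleoside = f$nucleoside %||% NA_character_,
               n_samples = f$n_samples, mesor = f$mesor,
               amplitude = f$overall_A,
               relative_amplitude = f$relative_amplitude,
               acrophase_h = f$overall_acrophase_h,
               p_A12 = unclass(f)$p[[1]], p_A24 = unclass(f)$p[[2]],
               rhythmic_any = f$rhythmic_any,
               stringsAsFactors = FALSE)
  }))
}

#' Cohort-level rhythm summary
#'
#' Per nucleoside: number of patients, number with a significant rhythm,
#' mean and range plus median and quartiles of mesor, amplitude and relative
#' amplitude, the between-patient coefficient of variation of the mesor, and
#' circular summaries of the acrophase.
#'
#' @param fits non-empty list of `cosinor_fit` objects (with `nucleoside`
#'   labels; unlabelled fits are summarized together).
#' @return data.frame, one row per nucleoside.
#' @export
summarize_cohort <- function(fits) {
  if (!length(fits)) stop_param("no fits to summarize")
  tab <- cosinor_parameter_table(fits)
  tab$nucleoside[is.na(tab$nucleoside)] <- "unspecified"
  out <- lapply(split(tab, tab$nucleoside), function(d) {
    q5 <- function(x) c(mean(x), min(x), max(x),
                        quantile(x, c(0.5, 0.25, 0.75), names = FALSE))
    m <- q5(d$mesor); a <- q5(d$amplitude); r <- q5(d$relative_amplitude)
    acr <- d$acrophase_h
    data.frame(
      nucleoside = d$nucleoside[1], n = nrow(d),
      n_rhythmic = sum(d$rhythmic_any),
      mesor_mean = m[1], mesor_min = m[2], mesor_max = m[3],
      mesor_median = m[4], mesor_q1 = m[5], mesor_q3 = m[6],
      mesor_cv = 100 * sd(d$mesor) / mean(d$mesor),
      amplitude_mean = a[1], amplitude_min = a[2], amplitude_max = a[3],
      amplitude_median = a[4], amplitude_q1 = a[5], amplitude_q3 = a[6],
      rel_amplitude_mean = r[1], rel_amplitude_min = r[2],
      rel_amplitude_max = r[3], rel_amplitude_median = r[4],
      rel_amplitude_q1 = r[5], rel_amplitude_q3 = r[6],
      acrophase_mean_h = circ_mean_hours(acr),
      acrophase_median_h = circ_median_hours(acr),
      acrophase_q1_h = circ_quantile_hours(acr, 0.25),
      acrophase_q3_h = circ_quantile_hours(acr, 0.75),
      acrophase_min_h = min(acr), acrophase_max_h = max(acr),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
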