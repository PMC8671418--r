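## Correlation of rhythm parameters with rest-activity indices and
## covariates: Spearman rank correlations with figure-style significance
## tiers, a residual-resampling bootstrap uncertainty check for
## cosinor-derived parameters, stepwise-AIC covariate selection, and
## two-sample group comparisons.

# Spearman rho + two-sided p. Exact permutation null for n < 10 (ties
# permitting), t-approximation otherwise.
.spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n < 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

.signif_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else if (p <= 0.1) "^" else ""
}

#' Pairwise Spearman correlation grid
#'
#' Spearman rank correlations between all column pairs of a parameter table,
#' with pairwise deletion of missing values and significance tiers
#' (`***` p <= 0.001, `**` <= 0.01, `*` <= 0.05, `^` <= 0.1). Pairs with
#' fewer than 4 complete observations or a constant variable are returned
#' with `NA` coefficients.
#'
#' @param data data.frame of numeric variables.
#' @return data.frame: `var1`, `var2`, `rho`, `p`, `n`, `tier`.
#' @export
spearman_matrix <- function(data) {
  vars <- names(data)[vapply(data, is.numeric, TRUE)]
  if (length(vars) < 2) stop_param("need at least two numeric variables")
  pairs <- utils::combn(vars, 2)
  out <- apply(pairs, 2, function(pr) {
    s <- .spearman(data[[pr[1]]], data[[pr[2]]])
    data.frame(var1 = pr[1], var2 = pr[2], rho = s$rho, p = s$p, n = s$n,
               tier = .signif_tier(s$p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Fast refit of a cosinor model to a matrix of bootstrap responses
# (n x B), reusing the fit's fixed design. Returns a B-column matrix of
# derived parameters.
.cosinor_refit_param <- function(fit, Ystar, param, grid_minutes = 10) {
  qrx <- qr(fit$X)
  coefs <- qr.coef(qrx, Ystar)                      # 5 x B
  switch(param,
    mesor = exp(coefs[1, ]),
    {
      tg <- seq(0, 24 - grid_minutes / 60, by = grid_minutes / 60)
      Xg <- cbind(1, do.call(cbind, lapply(fit$periods, function(Tp) {
        w <- 2 * pi * tg / Tp
        cbind(cos(w), sin(w))
      })))
      curves <- exp(Xg %*% coefs)                   # G x B
      switch(param,
        amplitude = (apply(curves, 2, max) - apply(curves, 2, min)) / 2,
        relative_amplitude =
          (apply(curves, 2, max) - apply(curves, 2, min)) / 2 /
            exp(coefs[1, ]),
        acrophase = tg[apply(curves, 2, which.max)],
        stop_param("unknown bootstrap parameter: ", param))
    })
}

.extract_param <- function(fit, param) {
  switch(param,
         mesor = fit$mesor, amplitude = fit$overall_A,
         relative_amplitude = fit$relative_amplitude,
         acrophase = fit$overall_acrophase_h,
         stop_param("unknown bootstrap parameter: ", param))
}

#' Bootstrap uncertainty check of a Spearman correlation
#'
#' Cosinor-derived parameters carry substantial estimation uncertainty at 10
#' samples per patient. This check resamples each patient's own cosinor
#' residuals with replacement (`B` trials), rebuilds the log-concentration
#' series, refits the cosinor, recomputes the derived parameter and the
#' Spearman correlation p-value across patients. The correlation is flagged
#' significant only when the 90\% quantile of the `B` bootstrap p-values is
#' <= `alpha` — a deliberately conservative criterion.
#'
#' @param fits list of `cosinor_fit` objects, one per patient.
#' @param param derived parameter to bootstrap: `"relative_amplitude"`,
#'   `"amplitude"`, `"mesor"` or `"acrophase"`.
#' @param other numeric vector (same order as `fits`) to correlate against;
#'   ignored when `other_fits` is given.
#' @param other_fits,other_param optional second list of per-patient fits
#'   whose derived parameter is resampled jointly (for nucleoside-nucleoside
#'   correlations).
#' @param B bootstrap trials (default 1000; fewer than 100 triggers a
#'   warning).
#' @param seed integer RNG seed.
#' @param alpha significance threshold (default 0.1).
#' @param quantile_level quantile of bootstrap p-values compared to `alpha`
#'   (default 0.9).
#' @return list: `rho` and `p` (observed), `bootstrap_p_q90`,
#'   `bootstrap_significant`, `n_trials_used`, `n_trials_dropped`.
#' @export
bootstrap_correlation_check <- function(fits, param = "relative_amplitude",
                                        other = NULL, other_fits = NULL,
                                        other_param = param, B = 1000L,
                                        seed = 1L, alpha = 0.1,
                                        quantile_level = 0.9) {
  B <- as.integer(B)
  if (B < 100L)
    warning("B < 100 bootstrap trials gives an unstable quantile criterion",
            call. = FALSE)
  stopifnot(all(vapply(fits, inherits, TRUE, "cosinor_fit")))
  v1 <- vapply(fits, .extract_param, numeric(1), param = param)
  v2 <- if (is.null(other_fits)) {
    if (is.null(other) || length(other) != length(fits))
      stop_param("'other' must be a numeric vector aligned with 'fits'")
    as.numeric(other)
  } else vapply(other_fits, .extract_param, numeric(1), param = other_param)
  obs <- .spearman(v1, v2)

  set.seed(as.integer(seed))
  boot_param <- function(flist, par) {
    out <- matrix(NA_real_, length(flist), B)
    for (i in seq_along(flist)) {
      f <- flist[[i]]
      n <- f$n_samples
      R <- matrix(sample(f$residuals, n * B, replace = TRUE), n, B)
      out[i, ] <- .cosinor_refit_param(f, f$fitted_log + R, par)
    }
    out
  }
  M1 <- boot_param(fits, param)
  M2 <- if (is.null(other_fits)) matrix(v2, length(v2), B)
        else boot_param(other_fits, other_param)

  pb <- vapply(seq_len(B), function(b) {
    s <- try(.spearman(M1[, b], M2[, b]), silent = TRUE)
    if (inherits(s, "try-error")) NA_real_ else s$p
  }, numeric(1))
  dropped <- sum(is.na(pb))
  pb <- pb[!is.na(pb)]
  q90 <- quantile(pb, quantile_level, names = FALSE)
  list(param = param, rho = obs$rho, p = obs$p,
       bootstrap_p_q90 = q90,
       bootstrap_significant = is.finite(q90) && q90 <= alpha,
       n_trials_used = length(pb), n_trials_dropped = dropped)
}

#' Stepwise-AIC covariate model selection
#'
#' Bidirectional stepwise search (via [MASS::stepAIC()]) from the full
#' main-effects linear model of `response` on all covariates, down to the
#' intercept-only lower scope.
#'
#' @param response numeric response vector.
#' @param covariates data.frame of candidate covariates.
#' @return list: fitted `model`, `selected_terms`, `coefficients` (with
#'   per-term p-values), `aic_selected`, `aic_full` (both `extractAIC`
#'   values, directly comparable).
#' @export
stepwise_covariate_model <- function(response, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(response)
  if (n <= ncol(covariates) + 2)
    stop_param("need n > number of candidate covariates + 2")
  dat <- cbind(data.frame(.response = response), covariates)
  full <- lm(.response ~ ., data = dat)
  if (anyNA(coef(full))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop_param("rank-deficient design; aliased terms: ",
               paste(bad, collapse = ", "))
  }
  sel <- MASS::stepAIC(full, direction = "both", trace = 0,
                       scope = list(lower = ~1, upper = stats::formula(full)))
  list(model = sel,
       selected_terms = attr(stats::terms(sel), "term.labels"),
       coefficients = as.data.frame(summary(sel)$coefficients),
       aic_selected = stats::extractAIC(sel)[2],
       aic_full = stats::extractAIC(full)[2])
}

#' Two-sample group comparison
#'
#' Welch two-sample t-test (optionally on log-transformed values), used for
#' overnight-excretion contrasts between patient groups and for survival
#' contrasts between trend classes.
#'
#' @param values numeric vector.
#' @param grouping factor-like with exactly 2 levels, each with n >= 2.
#' @param log_transform take logs first (values must then be positive).
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return list: `t`, `p`, `df`, `group_means` (on the analysis scale).
#' @export
group_comparison <- function(values, grouping, log_transform = FALSE,
                             var_equal = FALSE) {
  grouping <- factor(grouping)
  if (nlevels(grouping) != 2)
    stop_param("grouping must have exactly two levels")
  if (any(table(grouping) < 2))
    stop_param("each group needs at least 2 observations")
  if (log_transform) {
    if (any(values <= 0)) stop_param("log transform requires positive values")
    values <- log(values)
  }
  tt <- t.test(values ~ grouping, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       group_means = setNames(as.vector(tapply(values, grouping, mean)),
                              levels(grouping)))
}
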