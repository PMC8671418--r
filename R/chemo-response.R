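## Post-chemotherapy response classification: log-linear excretion trends,
## +/-50% CEA change categories, the Freeman-Halton exact test of their
## association, and the survival contrast between trend classes.

#' Classify the excretion trend of a treatment course
#'
#' Ordinary least squares of log overnight excretion on day; the course is
#' classified `"increase"`/`"decrease"` by the slope sign when the slope
#' p-value is <= `alpha`, and `"no_change"` otherwise. The log scale makes
#' the classification invariant to multiplying all excretions by a positive
#' constant.
#'
#' @param day numeric day index (>= 5 points required).
#' @param concentration strictly positive daily excretions.
#' @param alpha slope-test threshold (default 0.05).
#' @return list: `slope` (per day, log scale), `p`, `category`.
#' @export
classify_trend <- function(day, concentration, alpha = 0.05) {
  ok <- is.finite(day) & is.finite(concentration)
  day <- day[ok]; concentration <- concentration[ok]
  if (length(day) < 5L) stop_param("trend fitting requires >= 5 daily points")
  if (any(concentration <= 0)) stop_param("excretions must be positive")
  y <- log(concentration)
  if (sd(y) == 0)
    return(list(slope = 0, p = 1, category = "no_change"))
  fit <- lm(y ~ day)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["day", "Estimate"]
  p <- sm["day", "Pr(>|t|)"]
  if (!is.finite(p)) p <- if (abs(slope) > 1e-12) 0 else 1
  category <- if (p <= alpha) {
    if (slope > 0) "increase" else "decrease"
  } else "no_change"
  list(slope = slope, p = p, category = category)
}

#' Classify the CEA change after a course
#'
#' Baseline: the last CEA value at or before course start (day 0).
#' Follow-up: the latest value in the 1-2 month window (days 30-60 by
#' default) after the course. Under the default multiplicative convention a
#' ratio > 1.5 is an `"increase"`, < 2/3 a `"decrease"`, and anything in
#' between `"no_change"` (a symmetric more-than-50\% change on the
#' multiplicative scale). `convention = "additive"` instead uses relative
#' change (follow-up - baseline)/baseline beyond +/-50\%.
#'
#' @param day numeric day offsets relative to course start.
#' @param cea CEA values (mg/L), aligned with `day`.
#' @param window follow-up window in days (default `c(30, 60)`).
#' @param convention `"multiplicative"` (default) or `"additive"`.
#' @return list: `category` (`"increase"`, `"decrease"`, `"no_change"`, or
#'   `NA` when the window has no value), `baseline`, `followup`, `ratio`.
#' @export
classify_cea_change <- function(day, cea, window = c(30, 60),
                                convention = c("multiplicative", "additive")) {
  convention <- match.arg(convention)
  ok <- is.finite(day) & is.finite(cea)
  day <- day[ok]; cea <- cea[ok]
  pre <- which(day <= 0)
  if (!length(pre)) stop_param("no baseline CEA at or before course start")
  b <- cea[pre[which.max(day[pre])]]
  post <- which(day >= window[1] & day <= window[2])
  if (!length(post))
    return(list(category = NA_character_, baseline = b, followup = NA_real_,
                ratio = NA_real_))
  f <- cea[post[which.max(day[post])]]
  ratio <- f / b
  category <- if (convention == "multiplicative") {
    if (ratio > 1.5) "increase" else if (ratio < 2 / 3) "decrease"
    else "no_change"
  } else {
    rel <- (f - b) / b
    if (rel > 0.5) "increase" else if (rel < -0.5) "decrease"
    else "no_change"
  }
  list(category = category, baseline = b, followup = f, ratio = ratio)
}

## --- Freeman-Halton exact test -------------------------------------------

# log multivariate hypergeometric probability of a table with fixed margins
.log_table_prob <- function(tab, lfact_margins, lfact_total) {
  lfact_margins - lfact_total - sum(lgamma(tab + 1))
}

# Enumerate all r x c tables with the given margins, calling fun(tab).
.enumerate_tables <- function(rs, cs, fun) {
  r <- length(rs); c <- length(cs)
  tab <- matrix(0L, r, c)
  rec_row <- function(i, cs_left) {
    if (i == r) {
      tab[r, ] <<- cs_left
      if (all(cs_left >= 0)) fun(tab)
      return(invisible())
    }
    rec_cell <- function(j, left) {
      if (j == c) {
        if (left <= cs_left[c]) {
          tab[i, c] <<- left
          rec_row(i + 1L, cs_left - tab[i, ])
          tab[i, c] <<- 0L
        }
        return(invisible())
      }
      hi <- min(left, cs_left[j])
      for (v in 0:hi) {
        tab[i, j] <<- v
        rec_cell(j + 1L, left - v)
      }
      tab[i, j] <<- 0L
    }
    rec_cell(1L, rs[i])
  }
  rec_row(1L, cs)
}

#' Freeman-Halton (Fisher r x c) exact test of independence
#'
#' Enumerates every table sharing the observed margins and sums the
#' multivariate hypergeometric probabilities of all tables no more probable
#' than the observed one (with a relative tolerance of 1e-12 for probability
#' ties). Rows/columns with a zero margin are dropped before enumeration; a
#' table left with fewer than 2 rows or columns is degenerate and returns
#' p = 1.
#'
#' @param table matrix of non-negative integer counts (e.g. trend class by
#'   CEA category).
#' @return list: `p` (exact p-value), `log_prob_observed`, `n_tables`
#'   enumerated.
#' @export
fisher_exact_rxc <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_param("counts must be non-negative integers")
  if (sum(tab) == 0) stop_param("table total must be positive")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p = 1, log_prob_observed = 0, n_tables = 1L))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  lfm <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1))
  lft <- lgamma(n + 1)
  lp_obs <- .log_table_prob(tab, lfm, lft)

  acc <- new.env(parent = emptyenv())
  acc$p <- 0; acc$total <- 0; acc$count <- 0L
  tol <- log1p(1e-12)
  .enumerate_tables(rs, cs, function(t2) {
    lp <- .log_table_prob(t2, lfm, lft)
    acc$count <- acc$count + 1L
    acc$total <- acc$total + exp(lp)
    if (lp <= lp_obs + tol) acc$p <- acc$p + exp(lp)
  })
  if (abs(acc$total - 1) > 1e-8)
    warning("enumeration probabilities sum to ", acc$total, call. = FALSE)
  list(p = min(acc$p, 1), log_prob_observed = lp_obs, n_tables = acc$count)
}

## --- course-level association --------------------------------------------

# Nucleosides whose post-course changes define a patient's trend status.
TREND_NUCLEOSIDES <- c("1-methylguanosine", "4-acetylcytidine", "adenosine",
                       "cytidine")

# Patient-level classification from a treatment_course. The excretion table
# may carry one series (columns day, concentration) or several (extra
# `nucleoside` column); a patient is "trend" when any monitored nucleoside
# shows a significant slope.
.course_trend_status <- function(course, nucleosides, alpha) {
  ex <- course$excretion
  if (!is.null(ex$nucleoside)) {
    ex <- ex[ex$nucleoside %in% nucleosides, , drop = FALSE]
    cats <- vapply(split(ex, ex$nucleoside), function(d) {
      classify_trend(d$day, d$concentration, alpha)$category
    }, character(1))
  } else {
    cats <- classify_trend(ex$day, ex$concentration, alpha)$category
  }
  if (any(cats != "no_change")) "trend" else "no_trend"
}

#' Trend x CEA-change contingency table and exact test
#'
#' Classifies each patient as `"trend"` (any monitored nucleoside with a
#' significant post-course slope) or `"no_trend"`, crosses this with the CEA
#' change category, and runs the Freeman-Halton exact test on the resulting
#' 2 x 3 table.
#'
#' @param courses list of `treatment_course` objects.
#' @param nucleosides nucleoside subset defining trend status (default the
#'   four recapitulating nucleosides).
#' @param alpha_trend slope-test threshold (default 0.05).
#' @param convention CEA convention, see [classify_cea_change()].
#' @return list: `table` (2 x 3 counts), `p`, `status` per-patient
#'   data.frame.
#' @export
trend_cea_association <- function(courses, nucleosides = TREND_NUCLEOSIDES,
                                  alpha_trend = 0.05,
                                  convention = "multiplicative") {
  status <- lapply(courses, function(cs) {
    data.frame(
      patient_id = cs$patient_id %||% NA_character_,
      trend = .course_trend_status(cs, nucleosides, alpha_trend),
      cea = classify_cea_change(cs$cea$day, cs$cea$cea_mg_per_l,
                                convention = convention)$category,
      stringsAsFactors = FALSE)
  })
  status <- do.call(rbind, status)
  keep <- !is.na(status$cea)
  if (sum(keep) < 2)
    stop_param("need at least 2 patients with both classifications")
  tab <- table(factor(status$trend[keep], levels = c("no_trend", "trend")),
               factor(status$cea[keep],
                      levels = c("decrease", "no_change", "increase")))
  list(table = unclass(tab), p = fisher_exact_rxc(tab)$p, status = status)
}

#' Survival contrast between trend and no-trend patients
#'
#' Welch two-sample t-test of survival months between patients with and
#' without a significant post-course excretion trend.
#'
#' @inheritParams trend_cea_association
#' @return list from [group_comparison()] plus the per-patient `status`.
#' @export
survival_by_trend <- function(courses, nucleosides = TREND_NUCLEOSIDES,
                              alpha_trend = 0.05) {
  trend <- vapply(courses, .course_trend_status, character(1),
                  nucleosides = nucleosides, alpha = alpha_trend)
  surv <- vapply(courses, function(cs) cs$survival_months, numeric(1))
  res <- group_comparison(surv, trend)
  res$status <- data.frame(trend = trend, survival_months = surv)
  res
}
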