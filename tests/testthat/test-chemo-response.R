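test_that("trend classification covers the deterministic cases", {
  day <- 0:16
  up <- classify_trend(day, exp(0.1 * day))
  expect_equal(up$category, "increase")
  expect_lt(up$p, 1e-10)
  expect_equal(classify_trend(day, rep(3, 17))$category, "no_change")
  expect_equal(classify_trend(day, exp(-0.2 * day))$category, "decrease")
  expect_error(classify_trend(0:3, exp(0:3)), "5 daily")
  expect_error(classify_trend(day, c(rep(2, 16), 0)), "positive")
})

test_that("trend category is invariant to rescaling the excretions", {
  set.seed(31)
  day <- 0:16
  conc <- exp(0.05 * day + rnorm(17, 0, 0.1))
  expect_identical(classify_trend(day, conc)$category,
                   classify_trend(day, 1234 * conc)$category)
})

test_that("CEA change categories follow the +/-50% conventions", {
  expect_equal(classify_cea_change(c(-7, 45), c(10, 16))$category, "increase")
  expect_equal(classify_cea_change(c(-7, 45), c(10, 10))$category, "no_change")
  ## 6/10 = 0.6 < 2/3: decrease multiplicatively, but only -40% additively
  expect_equal(classify_cea_change(c(-7, 45), c(10, 6))$category, "decrease")
  expect_equal(classify_cea_change(c(-7, 45), c(10, 6),
                                   convention = "additive")$category,
               "no_change")
  expect_equal(classify_cea_change(c(-7, 45), c(10, 4.9),
                                   convention = "additive")$category,
               "decrease")
  ## no follow-up inside the 1-2 month window
  expect_true(is.na(classify_cea_change(c(-7, 80), c(10, 20))$category))
  expect_error(classify_cea_change(c(10, 45), c(10, 20)), "baseline")
})

test_that("Freeman-Halton test matches hand-checkable cases", {
  ## both margin-consistent 2x2 permutation tables are equally probable
  expect_equal(fisher_exact_rxc(matrix(c(1, 0, 0, 1), 2, 2))$p, 1,
               tolerance = 1e-12)
  ## degenerate tables collapse to p = 1
  expect_equal(fisher_exact_rxc(matrix(c(3, 2, 0, 0), 2, 2))$p, 1)
  expect_equal(fisher_exact_rxc(matrix(c(0, 0, 1, 2, 3, 1), 2, 3))$p,
               fisher_exact_rxc(matrix(c(1, 2, 3, 1), 2, 2))$p,
               tolerance = 1e-12)
  expect_error(fisher_exact_rxc(matrix(c(1, -1, 2, 3), 2, 2)), "non-negative")
  expect_error(fisher_exact_rxc(matrix(0L, 2, 2)), "positive")
})

test_that("dropping an empty column reduces to the 2x2 hypergeometric test", {
  tab <- matrix(c(4, 1, 0, 0, 2, 5), 2, 3)   # middle column empty
  expect_equal(fisher_exact_rxc(tab)$p,
               fisher.test(tab[, c(1, 3)])$p.value, tolerance = 1e-10)
})

test_that("enumeration probabilities over margin-fixed tables sum to one", {
  set.seed(77)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 2) + (i %% 2), 2, 3)
    if (sum(tab) == 0) next
    r <- fisher_exact_rxc(tab)
    expect_gte(r$p, 0)
    expect_lte(r$p, 1)
  }
})

make_courses <- function(n, couple, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    trending <- i <= n / 2
    cea_cat <- if (couple) {
      if (trending) "increase" else "stable"
    } else sample(c("increase", "stable", "decrease"), 1)
    cs <- generate_treatment_course(course_sim_params(
      daily_slope_log = if (trending) 0.12 else 0,
      noise_sd_log = 0.08, cea_category = cea_cat,
      survival_months = exp(rnorm(1, log(if (trending && couple) 8 else 16),
                                  0.3))), sample.int(1e8, 1))
    cs$patient_id <- sprintf("P%02d", i)
    cs
  })
}

test_that("coupled trend/CEA cohorts yield small exact-test p-values", {
  res <- trend_cea_association(make_courses(14, couple = TRUE, seed = 5))
  expect_equal(dim(res$table), c(2L, 3L))
  expect_equal(sum(res$table), 14)
  expect_lt(res$p, 0.05)
})

test_that("independent trend/CEA assignment gives unremarkable p-values", {
  ps <- vapply(1:40, function(s) {
    trend_cea_association(make_courses(14, couple = FALSE, seed = s))$p
  }, numeric(1))
  expect_gt(median(ps), 0.2)
})

test_that("survival contrast detects trend-linked poor survival", {
  res <- survival_by_trend(make_courses(30, couple = TRUE, seed = 9))
  expect_lt(res$p, 0.05)
  expect_lt(res$group_means[["trend"]], res$group_means[["no_trend"]])

  ## a single patient in one group is a hard error
  one <- make_courses(30, couple = TRUE, seed = 9)[c(1, 16:20)]
  expect_error(survival_by_trend(one), "at least 2")
})
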