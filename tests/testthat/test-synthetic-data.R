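test_that("generators are bitwise deterministic in (params, seed)", {
  ap <- actigraphy_params()
  expect_identical(generate_actigraphy(ap, 7), generate_actigraphy(ap, 7))
  up <- urine_sim_params()
  expect_identical(generate_urine_series(up, 3), generate_urine_series(up, 3))
  cp <- course_sim_params()
  expect_identical(generate_treatment_course(cp, 9),
                   generate_treatment_course(cp, 9))
  co1 <- generate_cohort(4, "mixed", 21)
  co2 <- generate_cohort(4, "mixed", 21)
  expect_identical(co1, co2)
  expect_false(identical(co1, generate_cohort(4, "mixed", 22)))
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(actigraphy_params(emission_means = c(3, 2, 5)),
               "strictly increasing")
  expect_error(actigraphy_params(stay_probs = c(1, 0.9, 0.9)), "\\(0,1\\)")
  expect_error(actigraphy_params(bed_start = "22:00", bed_end = "22:00"),
               "degenerate")
  expect_error(urine_sim_params(noise_sd_log = -0.1), ">= 0")
  expect_error(course_sim_params(n_pre_days = 1, n_post_days = 2), "5")
  expect_error(generate_cohort(0, "mixed", 1), "n_patients")
  expect_error(generate_cohort(5, "no-such-scenario", 1))
})

test_that("actigraphy generator matches its construction", {
  g <- generate_actigraphy(actigraphy_params(), seed = 5)
  expect_length(g$series$counts, 5 * 1440)
  expect_true(all(g$series$counts >= 0))
  expect_identical(g$series$counts, round(g$series$counts))

  ## no interruptions, no jitter: every in-bed epoch is latent IA and the
  ## IA fraction matches the bed-window fraction of the day
  g0 <- generate_actigraphy(
    actigraphy_params(night_interruption_rate = 0, bedtime_jitter_sd = 0),
    seed = 11)
  inbed <- circanuc:::in_bed_epochs(g0$series)
  expect_true(all(g0$states[inbed] == 1L))
  expect_true(all(g0$states[!inbed] != 1L))
  expect_equal(mean(g0$states == 1L), 8 / 24, tolerance = 1e-9)

  ## with default jitter/interruptions the IA fraction stays within 5%
  frac <- mean(generate_actigraphy(actigraphy_params(), 17)$states == 1L)
  expect_lt(abs(frac - 8 / 24), 0.05 * 8 / 24 + 0.02)
})

test_that("urine generator reduces to the closed-form curve at zero noise", {
  p <- urine_sim_params(mesor_log = log(5), amp12_log = 0.3, amp24_log = 0.6,
                        phase12 = 0.4, phase24 = -1.9, noise_sd_log = 0)
  d <- generate_urine_series(p, 2)
  t <- d$time_h
  expected <- exp(log(5) + 0.3 * cos(2 * pi * t / 12 + 0.4) +
                    0.6 * cos(2 * pi * t / 24 - 1.9))
  expect_equal(d$concentration, expected, tolerance = 1e-12)
  expect_true(all(d$concentration > 0))

  flat <- generate_urine_series(
    urine_sim_params(mesor_log = 1.3, amp12_log = 0, amp24_log = 0,
                     noise_sd_log = 0), 2)
  expect_equal(flat$concentration, rep(exp(1.3), 10), tolerance = 1e-12)
})

test_that("treatment-course generator honours its contracts", {
  flat <- generate_treatment_course(
    course_sim_params(baseline_log = log(4), daily_slope_log = 0,
                      noise_sd_log = 0), 3)
  expect_equal(flat$excretion$concentration, rep(4, 17), tolerance = 1e-12)
  expect_equal(nrow(flat$excretion), 3 + 14)

  for (cat in c("increase", "stable", "decrease")) {
    cs <- generate_treatment_course(course_sim_params(cea_category = cat), 4)
    r <- cs$cea$cea_mg_per_l[2] / cs$cea$cea_mg_per_l[1]
    switch(cat,
           increase = expect_gt(r, 1.5),
           decrease = expect_lt(r, 2 / 3),
           stable = expect_true(r >= 2 / 3 && r <= 1.5))
  }
})

test_that("trend classifier has power against a real slope", {
  hits <- vapply(1:200, function(s) {
    cs <- generate_treatment_course(
      course_sim_params(daily_slope_log = 0.1, noise_sd_log = 0.05), s)
    classify_trend(cs$excretion$day, cs$excretion$concentration)$category
  }, character(1))
  expect_gt(mean(hits == "increase"), 0.9)
})

test_that("cohort presets deliver the intended phenotypes", {
  co <- generate_cohort(29, "mixed", 123)
  expect_equal(nrow(co$covariates), 29)
  per <- table(co$urine$patient_id)
  expect_true(all(per == 10 * 8))   # 10 samples x 8 nucleosides
  expect_true(all(co$urine$concentration > 0))

  rob <- generate_cohort(9, "robust-rhythm", 31)
  ilo <- vapply(rob$actigraphy, function(a) dichotomy_index(a$series),
                numeric(1))
  expect_gt(median(ilo), 97)
})
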