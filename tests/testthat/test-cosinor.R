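test_that("eligibility rule counts only valid samples", {
  t10 <- study_sample_times()
  expect_true(check_eligibility(t10, rep(5, 10))$eligible)
  expect_false(check_eligibility(t10[1:6], rep(5, 6))$eligible)
  ## 7 samples, one non-positive -> 6 valid -> excluded
  expect_false(check_eligibility(t10[1:7], c(rep(5, 6), 0))$eligible)
  expect_error(fit_multicomponent_cosinor(t10[1:6], rep(5, 6)), "7 valid")
})

test_that("constant data give zero amplitudes and no rhythm", {
  f <- fit_multicomponent_cosinor(study_sample_times(), rep(4, 10))
  expect_equal(f$M, log(4), tolerance = 1e-9)
  expect_lt(f$A12, 1e-10)
  expect_lt(f$A24, 1e-10)
  expect_equal(unname(unclass(f)$p), c(1, 1))
  expect_false(f$rhythmic_any)
})

test_that("linearized fit agrees with a brute-force phase-grid oracle", {
  p <- urine_sim_params(mesor_log = log(8), amp12_log = 0.25,
                        amp24_log = 0.55, phase12 = 0.9, phase24 = -2.1,
                        noise_sd_log = 0.1)
  d <- generate_urine_series(p, 19)
  f <- fit_multicomponent_cosinor(d$time_h, d$concentration)
  o <- grid_cosinor_oracle(d$time_h, log(d$concentration))
  tol_phase <- 2 * pi / 72 + 1e-9    # oracle grid resolution
  expect_equal(f$M, unname(o$M), tolerance = 1e-2)
  expect_equal(f$A12, unname(o$A12), tolerance = 0.05)
  expect_equal(f$A24, unname(o$A24), tolerance = 0.05)
  expect_lt(abs(((f$theta12 - o$phase12 + pi) %% (2 * pi)) - pi), 2 * tol_phase)
  expect_lt(abs(((f$theta24 - o$phase24 + pi) %% (2 * pi)) - pi), 2 * tol_phase)
})

test_that("degenerate sampling designs are rejected", {
  ## all samples at the same clock time: 12/24-h components inseparable
  expect_error(fit_multicomponent_cosinor(c(7, 31, 55, 79, 103, 127, 151),
                                          rep(5, 7) * exp(rnorm(7, 0, 0.1))),
               "singular")
  expect_error(fit_multicomponent_cosinor(seq(0, 20, length.out = 10),
                                          exp(rnorm(10))), "24 h")
  expect_error(fit_multicomponent_cosinor(study_sample_times(),
                                          c(rep(2, 9), -1)), "non-positive")
})

test_that("time-shift equivariance and scale equivariance hold", {
  p <- urine_sim_params(noise_sd_log = 0.08)
  d <- generate_urine_series(p, 5)
  f0 <- fit_multicomponent_cosinor(d$time_h, d$concentration)

  for (delta in c(3, -5.5)) {
    fs <- fit_multicomponent_cosinor(d$time_h + delta, d$concentration)
    expect_equal(fs$M, f0$M, tolerance = 1e-8)
    expect_equal(fs$A24, f0$A24, tolerance = 1e-8)
    expect_equal(unclass(fs)$p, unclass(f0)$p, tolerance = 1e-8)
    expect_lt(circ_abs_h(fs$overall_acrophase_h,
                         (f0$overall_acrophase_h + delta) %% 24), 2 / 60)
  }

  k <- 13.7
  fk <- fit_multicomponent_cosinor(d$time_h, k * d$concentration)
  expect_equal(fk$mesor, k * f0$mesor, tolerance = 1e-8)
  expect_equal(fk$overall_A, k * f0$overall_A, tolerance = 1e-8)
  expect_equal(fk$relative_amplitude, f0$relative_amplitude, tolerance = 1e-8)
  expect_equal(unclass(fk)$p, unclass(f0)$p, tolerance = 1e-8)
})

test_that("overall amplitude dominates the component lower bound", {
  for (s in 1:20) {
    set.seed(s)
    p <- urine_sim_params(amp12_log = runif(1, 0, 0.5),
                          amp24_log = runif(1, 0, 0.7),
                          phase12 = runif(1, -pi, pi),
                          phase24 = runif(1, -pi, pi), noise_sd_log = 0)
    d <- generate_urine_series(p, s)
    f <- fit_multicomponent_cosinor(d$time_h, d$concentration)
    ## dense-grid half-range of the fitted log curve is at least |A24 - A12|
    tg <- seq(0, 24, by = 1 / 60)
    g <- f$A12 * cos(2 * pi * tg / 12 + f$theta12) +
      f$A24 * cos(2 * pi * tg / 24 + f$theta24)
    expect_gte((max(g) - min(g)) / 2, abs(f$A24 - f$A12) - 1e-9)
  }
})

test_that("rhythm detection respects alpha and strong signals", {
  p <- urine_sim_params(amp24_log = 0.8, amp12_log = 0, noise_sd_log = 0.05)
  f <- fit_multicomponent_cosinor(generate_urine_series(p, 2)$time_h,
                                  generate_urine_series(p, 2)$concentration)
  expect_true(detect_rhythm(f, 0.1)$rhythmic_24h)
  expect_false(detect_rhythm(f, 0)$rhythmic_any)   # alpha = 0 flags nothing
})

test_that("parameter bias vanishes as noise shrinks", {
  bias <- vapply(c(0.2, 0.05, 0.01), function(sd) {
    errs <- vapply(1:30, function(s) {
      p <- urine_sim_params(mesor_log = log(6), amp12_log = 0.2,
                            amp24_log = 0.5, phase12 = 0.7, phase24 = -2.2,
                            noise_sd_log = sd)
      d <- generate_urine_series(p, s)
      f <- fit_multicomponent_cosinor(d$time_h, d$concentration)
      abs(f$A24 - 0.5)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.01)
})

test_that("cohort summaries use circular acrophase statistics", {
  mk <- function(peak_h, pid) {
    p <- urine_sim_params(amp12_log = 0, amp24_log = 0.6,
                          phase24 = -2 * pi * peak_h / 24, noise_sd_log = 0)
    d <- generate_urine_series(p, 1)
    fit_multicomponent_cosinor(d$time_h, d$concentration, patient_id = pid,
                               nucleoside = "pseudouridine")
  }
  ## acrophases straddling midnight: circular median 00:00, not 12:00
  fits <- list(mk(23, "a"), mk(1, "b"))
  s <- summarize_cohort(fits)
  expect_lt(circ_abs_h(s$acrophase_median_h, 0), 0.05)
  expect_lt(circ_abs_h(s$acrophase_mean_h, 0), 0.05)

  one <- summarize_cohort(list(mk(15, "solo")))
  expect_equal(one$n, 1)
  expect_equal(one$mesor_mean, one$mesor_median)
  expect_equal(one$mesor_min, one$mesor_max)
  expect_error(summarize_cohort(list()), "no fits")
})
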