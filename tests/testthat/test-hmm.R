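test_that("HMM recovers well-separated latent states and is deterministic", {
  g <- generate_actigraphy(separated_params(), seed = 101)
  m <- fit_hmm(g$series, n_restarts = 5, seed = 1)
  expect_true(all(diff(m$means) > 0))
  expect_equal(rowSums(m$trans), rep(1, 3), tolerance = 1e-9)
  expect_gt(mean(m$states == g$states), 0.95)
  ## IA should be overwhelmingly persistent in a regular sleeper
  expect_gt(m$trans[1, 1], 0.98)

  m2 <- fit_hmm(g$series, n_restarts = 5, seed = 1)
  expect_identical(m$loglik, m2$loglik)
  expect_identical(m$states, m2$states)
})

test_that("reported indices do not depend on the restart initialization", {
  g <- generate_actigraphy(separated_params(), seed = 55)
  i1 <- hmm_indices(fingerprint(g$series, fit_hmm(g$series, 4, seed = 2)),
                    fit_hmm(g$series, 4, seed = 2), g$series)
  i2 <- hmm_indices(fingerprint(g$series, fit_hmm(g$series, 4, seed = 9)),
                    fit_hmm(g$series, 4, seed = 9), g$series)
  expect_equal(i1, i2, tolerance = 1e-5)
})

test_that("degenerate and short series are rejected", {
  expect_error(fit_hmm(actigraphy_series(rep(0, 2880))), "degenerate")
  expect_error(fit_hmm(actigraphy_series(rpois(720, 20))), "24 h")
})

test_that("fingerprint concentrates IA in a regular rest window", {
  g <- generate_actigraphy(
    separated_params(bed_start = "00:00", bed_end = "08:00",
                     bedtime_jitter_sd = 0, night_interruption_rate = 0),
    seed = 77)
  m <- fit_hmm(g$series, n_restarts = 5, seed = 1)
  fp <- fingerprint(g$series, m)
  expect_equal(fp$p_IA + fp$p_MA + fp$p_HA, rep(1, nrow(fp)),
               tolerance = 1e-9)
  inside <- fp$time_min >= 30 & fp$time_min < 450    # clear of the edges
  outside <- fp$time_min >= 510
  expect_true(all(fp$p_IA[inside] > 0.95))
  expect_true(all(fp$p_IA[outside] < 0.05))

  ## destroying the time structure flattens the fingerprint (hourly bins
  ## average enough epochs for the sampling noise to settle)
  set.seed(1)
  shuf <- actigraphy_series(sample(g$series$counts))
  fps <- fingerprint(shuf, m, bin_minutes = 60)
  expect_lt(max(fps$p_IA) - min(fps$p_IA), 0.2)
})

test_that("rest duration, center of rest and Rhythm Index obey limit laws", {
  ## square-wave rest 00:00-08:00
  sq <- fingerprint_from_profile(rep(c(1, 0), c(48, 96)))
  idx <- hmm_indices(sq)
  expect_equal(idx$rest_duration_a, 8, tolerance = 1e-9)
  expect_equal(idx$center_of_rest_c, 4, tolerance = 1e-9)
  expect_equal(idx$rhythm_index, 100, tolerance = 1e-9)

  ## square wave wrapping midnight keeps its center and index
  wrap <- fingerprint_from_profile(rep(c(1, 0, 1), c(24, 96, 24)))
  iw <- hmm_indices(wrap)
  expect_equal(iw$rest_duration_a, 8, tolerance = 1e-9)
  expect_equal(circ_abs_h(iw$center_of_rest_c, 0), 0, tolerance = 1e-9)
  expect_equal(iw$rhythm_index, 100, tolerance = 1e-9)

  ## uniform IA profile: no circadian regulation of rest
  flat <- fingerprint_from_profile(rep(8 / 24, 144))
  expect_equal(hmm_indices(flat)$rhythm_index, 0, tolerance = 1e-9)

  ## a = 0 and a = 24 are undefined
  expect_true(is.na(hmm_indices(fingerprint_from_profile(rep(0, 144)))$rhythm_index))
  expect_true(is.na(hmm_indices(fingerprint_from_profile(rep(1, 144)))$rhythm_index))
})

test_that("robust synthetic sleepers score a high Rhythm Index", {
  ris <- vapply(1:5, function(s) {
    g <- generate_actigraphy(separated_params(), seed = 200 + s)
    m <- fit_hmm(g$series, n_restarts = 4, seed = 1)
    hmm_indices(fingerprint(g$series, m), m, g$series)$rhythm_index
  }, numeric(1))
  expect_true(all(ris > 85))
})
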