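test_that("Spearman grid reproduces exact monotone relations", {
  x <- c(2, 5, 1, 9, 4, 7, 3)
  d <- data.frame(x = x, up = exp(x), down = -x^3, const = rep(1, 7))
  g <- spearman_matrix(d)
  get <- function(a, b) g[g$var1 == a & g$var2 == b, ]
  expect_equal(get("x", "up")$rho, 1)
  expect_equal(get("x", "down")$rho, -1)
  expect_true(is.na(get("x", "const")$rho))   # constant variable flagged
  expect_equal(get("x", "up")$tier, "***")
})

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(4)
  x <- rnorm(25); y <- x + rnorm(25)
  r0 <- spearman_matrix(data.frame(x = x, y = y))$rho
  r1 <- spearman_matrix(data.frame(x = exp(x), y = y^3 + 5 * y))$rho
  expect_equal(r0, r1)
})

test_that("null Spearman correlations stay small at n = 29", {
  rhos <- vapply(1:200, function(s) {
    set.seed(s)
    spearman_matrix(data.frame(x = runif(29), y = runif(29)))$rho
  }, numeric(1))
  expect_lt(median(abs(rhos)), 0.25)
})

make_coupled_fits <- function(n, seed, couple = TRUE, noise = 0.1) {
  set.seed(seed)
  rest <- runif(n, 6, 10)
  amp <- if (couple) 0.06 * rest else rep(0.35, n)
  fits <- lapply(seq_len(n), function(i) {
    p <- urine_sim_params(amp12_log = 0.05, amp24_log = amp[i],
                          noise_sd_log = noise)
    d <- generate_urine_series(p, sample.int(1e8, 1))
    fit_multicomponent_cosinor(d$time_h, d$concentration)
  })
  list(fits = fits, rest = rest)
}

test_that("bootstrap correlation check is deterministic in the seed", {
  cp <- make_coupled_fits(12, 7)
  b1 <- bootstrap_correlation_check(cp$fits, "relative_amplitude", cp$rest,
                                    B = 300, seed = 5)
  b2 <- bootstrap_correlation_check(cp$fits, "relative_amplitude", cp$rest,
                                    B = 300, seed = 5)
  expect_identical(b1, b2)
  expect_warning(
    bootstrap_correlation_check(cp$fits, "relative_amplitude", cp$rest,
                                B = 50, seed = 1), "B < 100")
})

test_that("bootstrap flag is never significant when the plain p exceeds it", {
  violations <- 0L
  for (s in 1:8) {
    cp <- make_coupled_fits(10, 100 + s, couple = (s %% 2 == 0), noise = 0.2)
    b <- bootstrap_correlation_check(cp$fits, "relative_amplitude", cp$rest,
                                     B = 200, seed = s)
    expect_gte(b$bootstrap_p_q90, 0)
    if (b$bootstrap_significant && b$p > 0.1) violations <- violations + 1L
  }
  expect_equal(violations, 0L)
})

test_that("stepwise AIC finds a strong sex effect and rejects pure noise", {
  n <- 100
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    cov <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                      age = rnorm(n, 60, 10),
                      who_ps = sample(0:2, n, TRUE),
                      site = sample(c("colon", "rectum"), n, TRUE))
    y <- 2 * (cov$sex == "F") + rnorm(n)
    "sex" %in% stepwise_covariate_model(y, cov)$selected_terms
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  n_terms <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    cov <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    length(stepwise_covariate_model(rnorm(30), cov)$selected_terms)
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(n_terms)))), 0L)
})

test_that("stepwise search never worsens the full-model AIC", {
  for (s in 1:10) {
    set.seed(s)
    cov <- data.frame(a = rnorm(40), b = rnorm(40),
                      g = sample(c("x", "y"), 40, TRUE))
    y <- 0.8 * cov$a + rnorm(40)
    m <- stepwise_covariate_model(y, cov)
    expect_lte(m$aic_selected, m$aic_full + 1e-8)
  }
})

test_that("stepwise selection is invariant to covariate order", {
  set.seed(12)
  cov <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- 1.5 * cov$a - 0.9 * cov$c + rnorm(50)
  t1 <- sort(stepwise_covariate_model(y, cov)$selected_terms)
  t2 <- sort(stepwise_covariate_model(y, cov[, c("c", "b", "a")])$selected_terms)
  expect_identical(t1, t2)
})

test_that("rank-deficient designs are reported with the aliased covariate", {
  set.seed(3)
  cov <- data.frame(a = rnorm(30))
  cov$twin <- 2 * cov$a
  expect_error(stepwise_covariate_model(rnorm(30), cov), "aliased.*twin")
})

test_that("group comparison behaves under identity, symmetry and signal", {
  v <- c(1, 3, 5, 2, 1, 3, 5, 2)
  g <- rep(c("a", "b"), each = 4)
  same <- group_comparison(v, g)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  set.seed(6)
  x <- c(rnorm(15), rnorm(15, 3))
  grp <- rep(c("lo", "hi"), each = 15)
  r1 <- group_comparison(x, grp)            # default levels: hi, lo
  r2 <- group_comparison(x, factor(grp, c("lo", "hi")))
  expect_equal(r1$p, r2$p)
  expect_equal(r1$t, -r2$t)
  expect_error(group_comparison(c(1, 2, 3), c("a", "a", "b")), "at least 2")

  power <- mean(vapply(1:100, function(s) {
    set.seed(s)
    group_comparison(c(rnorm(15), rnorm(15, 3)),
                     rep(c("a", "b"), each = 15))$p < 0.001
  }, logical(1)))
  expect_gte(power, 0.99)
})
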