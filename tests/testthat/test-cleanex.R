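test_that("build-up model obeys its limiting values", {
  expect_identical(cleanex_model(0, 2, 25, 0.6), 0)
  expect_identical(cleanex_model(default_taus, 0, 25, 0.6),
                   rep(0, length(default_taus)))
  expect_error(cleanex_model(-0.01, 2, 25, 0.6), ">= 0")
  expect_error(cleanex_model(0.1, -2, 25, 0.6), ">= 0")
})

test_that("build-up model is continuous across the RA + k1H = RB degeneracy", {
  tau <- seq(0.005, 0.3, length.out = 20)
  # at the degeneracy the model equals k1h * tau * exp(-rb * tau)
  exact_limit <- 1 * tau * exp(-10 * tau)
  expect_equal(cleanex_model(tau, 1, 9, 10), exact_limit, tolerance = 1e-9)
  # approaching from both sides agrees with the on-point value
  lo <- cleanex_model(tau, 1, 9 - 1e-6, 10)
  hi <- cleanex_model(tau, 1, 9 + 1e-6, 10)
  expect_equal(lo, exact_limit, tolerance = 1e-6)
  expect_equal(hi, exact_limit, tolerance = 1e-6)
  # finite-difference continuity scan: the two-sided difference must
  # shrink proportionally to the offset (no jump at the degeneracy)
  for (eps in 10^seq(-10, -4)) {
    gap <- max(abs(cleanex_model(tau, 1, 9 + eps, 10) -
                     cleanex_model(tau, 1, 9 - eps, 10)))
    expect_lt(gap, eps + 1e-12)
  }
})

test_that("noise-free fits recover every default truth to 1e-6 relative", {
  design <- study_design()
  truths <- default_ground_truths(design)
  for (tr in truths) {
    y <- cleanex_model(design$mixing_times, tr$k1h_true, tr$ra_true,
                       tr$rb_true)
    crv <- build_up_curve(tr$site, design$mixing_times, y,
                          rep(1e-5, length(y)))
    f <- fit_cleanex(crv, fast_control())
    expect_equal(f$k1h, tr$k1h_true, tolerance = 1e-6)
    expect_equal(f$ra, tr$ra_true, tolerance = 1e-6)
    expect_equal(f$rb, tr$rb_true, tolerance = 1e-6)
  }
})

test_that("Monte-Carlo recovery: mean fitted k1h lands on the truth", {
  clean <- cleanex_model(default_taus, 2, 25, 0.6)
  sigma <- 0.002
  set.seed(11)
  est <- vapply(1:100, function(i) {
    y <- pmax(clean + rnorm(7, sd = sigma), 0)
    fit_cleanex(build_up_curve(g_site(), default_taus, y, rep(sigma, 7)),
                fast_control())$k1h
  }, numeric(1))
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 2), 3 * se_mean)
})

test_that("68% intervals from the error procedure have nominal coverage", {
  clean <- cleanex_model(default_taus, 2, 25, 0.6)
  sigma <- 0.002
  set.seed(7)
  cover <- vapply(1:500, function(i) {
    y <- pmax(clean + rnorm(7, sd = sigma), 0)
    f <- fit_cleanex(build_up_curve(g_site(), default_taus, y,
                                    rep(sigma, 7)), fast_control())
    is.finite(f$k1h) && abs(f$k1h - 2) <= f$k1h_err
  }, logical(1))
  expect_gte(mean(cover), 0.60)
  expect_lte(mean(cover), 0.76)
})

test_that("Monte-Carlo resampling errors agree in scale with covariance", {
  clean <- cleanex_model(default_taus, 2, 25, 0.6)
  set.seed(3)
  y <- clean + rnorm(7, sd = 0.002)
  crv <- build_up_curve(g_site(), default_taus, y, rep(0.002, 7))
  f_cov <- fit_cleanex(crv, fast_control())
  f_mc <- fit_cleanex(crv, cleanex_control(error_method = "mc",
                                           mc_draws = 200, seed = 5))
  expect_equal(f_mc$k1h, f_cov$k1h)  # same point estimate
  expect_true(is.finite(f_mc$k1h_err) && f_mc$k1h_err > 0)
  expect_lt(abs(log(f_mc$k1h_err / f_cov$k1h_err)), log(3))
})

test_that("fitted k1h increases monotonically with the true k1h", {
  ladder <- c(0.5, 1, 2, 3, 4)
  est <- vapply(ladder, function(k) {
    clean <- cleanex_model(default_taus, k, 25, 0.6)
    set.seed(21)  # same noise realization on every rung
    y <- pmax(clean + rnorm(7, sd = 0.002), 0)
    fit_cleanex(build_up_curve(g_site(), default_taus, y, rep(0.002, 7)),
                fast_control())$k1h
  }, numeric(1))
  expect_equal(cor(est, ladder, method = "spearman"), 1)
})

test_that("undetectable build-up is reported as not detected, not an error", {
  # all-zero ratios: clean short-circuit
  crv0 <- build_up_curve(g_site(), default_taus, rep(0, 7), rep(0.002, 7))
  f0 <- fit_cleanex(crv0, fast_control())
  expect_false(f0$detected)
  expect_true(is.na(f0$k1h))
  # pure noise below the detection limit
  set.seed(9)
  y <- pmax(rnorm(7, sd = 0.0005), 0)
  f1 <- fit_cleanex(build_up_curve(g_site(), default_taus, y,
                                   rep(0.002, 7)), fast_control())
  expect_false(f1$detected)
  # normalization propagates the flag instead of failing
  norm <- normalize_k1h(f1, g_site())
  expect_false(norm$detected)
  expect_true(is.na(norm$k1h_norm))
})

test_that("build-up maximum matches closed form and numerical optimization", {
  f <- cleanex_fit(k1h = 2, ra = 25, rb = 0.6)
  pk <- max_buildup(f)
  expect_equal(pk$tau_peak, log(27 / 0.6) / 26.4, tolerance = 1e-12)
  num <- optimize(function(t) cleanex_model(t, 2, 25, 0.6),
                  c(0.001, 2), maximum = TRUE)
  expect_equal(pk$tau_peak, num$maximum, tolerance = 1e-4)
  expect_equal(pk$ratio_peak, num$objective, tolerance = 1e-8)
  # degenerate-rate limit and the no-exchange case
  pk_deg <- max_buildup(cleanex_fit(k1h = 1, ra = 9, rb = 10))
  expect_equal(pk_deg$tau_peak, 0.1, tolerance = 1e-6)
  expect_identical(max_buildup(cleanex_fit(0, 25, 0.6))$ratio_peak, 0)
})

test_that("all default truths stay in the transient-opening regime", {
  # build-up maxima below 0.1, as expected for very short-lived openings
  for (tr in default_ground_truths()) {
    pk <- max_buildup(cleanex_fit(tr$k1h_true, tr$ra_true, tr$rb_true))
    expect_lt(pk$ratio_peak, 0.1)
  }
})
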