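test_that("intensity-to-rate conversion and its error propagation", {
  expect_identical(r1rho_from_intensities(1, 1, 0.02), 0)
  expect_equal(r1rho_from_intensities(exp(-1), 1, 0.02), 50)
  expect_equal(r1rho_from_intensities(0.5, 1, 0.02), log(2) / 0.02)
  expect_error(r1rho_from_intensities(-0.1, 1, 0.02), "non-positive")
  expect_error(r1rho_from_intensities(0.5, 0, 0.02), "non-positive")

  expect_identical(r1rho_error_from_noise(1, 1, 0, 0.02), 0)
  expect_equal(r1rho_error_from_noise(1, 1, 0.01, 0.02),
               50 * sqrt(2) * 0.01)
  # halving the spin-lock intensity at fixed noise inflates the error
  expect_gt(r1rho_error_from_noise(0.5, 1, 0.01, 0.02),
            r1rho_error_from_noise(1, 1, 0.01, 0.02))
})

test_that("dispersion model collapses to R2^0 without exchange", {
  nu1 <- default_nu1
  expect_equal(dispersion_model(nu1, 30, 2e4, 0, 2 * pi * 1200),
               rep(30, 12))
  expect_equal(dispersion_model(nu1, 30, 2e4, 0.01, 0), rep(30, 12))
})

test_that("dispersion model is monotone and flattens at high power", {
  y <- dispersion_model(default_nu1, 30, 2e4, 0.005, 2 * pi * 1200)
  expect_true(all(diff(y) <= 0))
  for (tr in default_ground_truths()) {
    hi <- dispersion_model(1e6, tr$r20_true, tr$kex_true, tr$pb_true,
                           tr$dw_true)
    expect_lt(hi - tr$r20_true, 1e-3)
  }
})

test_that("noise-free dispersion fits are self-consistent to 1e-6", {
  pb <- 0.001
  phi <- 4e5
  dw <- sqrt(phi / ((1 - pb) * pb))
  y <- dispersion_model(default_nu1, 30, 2e4, pb, dw)
  crv <- dispersion_curve(g_site(), default_nu1, y, rep(0.5, 12), 0.02)
  f <- fit_dispersion(crv, fast_dcontrol(pb_fixed = pb))
  expect_equal(f$r20, 30, tolerance = 1e-6)
  expect_equal(f$kex, 2e4, tolerance = 1e-6)
  expect_equal(f$phi_ex, phi, tolerance = 1e-6)
  expect_identical(f$parameterization_mode, "fast_exchange")
})

test_that("median kex from noisy BM-oracle curves lands within 10%", {
  tr <- ground_truth_site(g_site(), 1, 25, 0.5, 30, 2e4, 0.001,
                          2 * pi * 2400)
  clean <- simulate_r1rho_bm(tr, default_nu1)
  set.seed(31)
  est <- vapply(1:100, function(i) {
    y <- clean + rnorm(12, sd = 0.5)
    f <- fit_dispersion(
      dispersion_curve(g_site(), default_nu1, pmax(y, 1e-3),
                       rep(0.5, 12), 0.02),
      fast_dcontrol())
    if (f$rex_observed) f$kex else NA_real_
  }, numeric(1))
  expect_lt(abs(median(est, na.rm = TRUE) / 2e4 - 1), 0.10)
})

test_that("a flat profile is reported as 'no Rex' without a kex", {
  set.seed(13)
  y <- 30 + rnorm(12, sd = 0.5)
  crv <- dispersion_curve(g_site(), default_nu1, y, rep(0.5, 12), 0.02)
  f <- fit_dispersion(crv, fast_dcontrol())
  expect_false(f$rex_observed)
  expect_true(is.na(f$kex))
  expect_identical(rex_at_min_spinlock(f, 500), 0)
  # and the flag propagates through the kinetics combination
  cs <- combine_kinetics(list(k1h_norm = 1, k1h_norm_err = 0.1,
                              detected = TRUE), f, g_site())
  expect_true(is.na(cs$kclose_approx))
  expect_true(is.na(cs$rel_kopen_index))
})

test_that("the fixed-pb choice is immaterial deep in fast exchange", {
  # kex >> dw for every pb considered: only phi_ex = pA pB dw^2 is
  # identifiable, so refitting with a different assumed pb must leave
  # (r20, kex, phi_ex) essentially unchanged
  pb_true <- 0.001
  dw <- 2 * pi * 400
  y <- dispersion_model(default_nu1, 30, 5e4, pb_true, dw)
  crv <- dispersion_curve(g_site(), default_nu1, y, rep(0.5, 12), 0.02)
  f1 <- fit_dispersion(crv, fast_dcontrol(pb_fixed = 0.001,
                                          model_selection = FALSE))
  f2 <- fit_dispersion(crv, fast_dcontrol(pb_fixed = 0.01,
                                          model_selection = FALSE))
  expect_lt(abs(f1$r20 / f2$r20 - 1), 0.01)
  expect_lt(abs(f1$kex / f2$kex - 1), 0.01)
  expect_lt(abs(f1$phi_ex / f2$phi_ex - 1), 0.01)
})

test_that("a larger exchange amplitude yields a larger fitted Rex", {
  # thymine-like site (larger phi_ex, AT pair) vs guanine-like site
  mk <- function(phi) {
    pb <- 0.001
    dw <- sqrt(phi / ((1 - pb) * pb))
    tr <- ground_truth_site(g_site(), 1, 25, 0.5, 28, 2.2e4, pb, dw)
    clean <- simulate_r1rho_bm(tr, default_nu1)
    set.seed(17)
    y <- clean + rnorm(12, sd = 0.4)
    fit_dispersion(dispersion_curve(g_site(), default_nu1, y,
                                    rep(0.4, 12), 0.02),
                   fast_dcontrol())
  }
  f_g <- mk(2e5)
  f_t <- mk(8e5)
  expect_gt(rex_at_min_spinlock(f_t, 500), rex_at_min_spinlock(f_g, 500))
})

test_that("Rex at the weakest spin-lock follows the model arithmetic", {
  f <- exchange_fit(30, 2e4, 0.005, 2 * pi * 1200)
  expect_equal(rex_at_min_spinlock(f, 500),
               dispersion_model(500, 30, 2e4, 0.005, 2 * pi * 1200) - 30)
  expect_gt(rex_at_min_spinlock(f, 500), rex_at_min_spinlock(f, 2000))
})

test_that("dispersion fitting rejects inadequate spin-lock coverage", {
  y4 <- dispersion_model(c(500, 700, 900, 1100), 30, 2e4, 0.001,
                         2 * pi * 2000)
  crv <- dispersion_curve(g_site(), c(500, 700, 900, 1100), y4,
                          rep(0.5, 4), 0.02)
  expect_error(fit_dispersion(crv, fast_dcontrol()), "decade")
})

test_that("full-mode refit warns about the pb/dw degeneracy", {
  pb <- 0.005
  dw <- 2 * pi * 1200
  y <- dispersion_model(default_nu1, 30, 2e4, pb, dw)
  crv <- dispersion_curve(g_site(), default_nu1, y, rep(0.5, 12), 0.02)
  expect_warning(
    f <- fit_dispersion(crv, fast_dcontrol(mode = "full", pb_fixed = pb)),
    "degenerate")
  expect_identical(f$parameterization_mode, "full")
  # the identifiable composite is still recovered
  expect_equal((1 - f$pb) * f$pb * f$dw^2, (1 - pb) * pb * dw^2,
               tolerance = 0.05)
})
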