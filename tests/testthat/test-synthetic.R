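test_that("numerical two-pool integration matches the closed form", {
  tau <- default_taus
  params <- list(c(2, 20, 0.6), c(0.2, 40, 0.3), c(8, 120, 2),
                 c(1, 9.0000001, 10),   # essentially at the degeneracy
                 c(1, 8.5, 9.5))
  for (p in params) {
    s <- g_site()
    tr <- ground_truth_site(s, p[1], p[2], p[3], 30, 2e4, 0.001,
                            2 * pi * 2000)
    crv <- simulate_cleanex_numeric(tr, tau)
    expect_equal(crv$ratios, cleanex_model(tau, p[1], p[2], p[3]),
                 tolerance = 1e-8)
  }
  # no exchange pathway: identically zero
  tr0 <- ground_truth_site(g_site(), 0, 20, 0.6, 30, 2e4, 0.001,
                           2 * pi * 2000)
  expect_identical(simulate_cleanex_numeric(tr0, tau)$ratios, rep(0, 7))
})

test_that("BM propagation reduces to pure relaxation without exchange", {
  nu1 <- default_nu1
  no_minor <- ground_truth_site(g_site(), 1, 25, 0.5, 30, 2e4, 0,
                                2 * pi * 1200)
  expect_equal(simulate_r1rho_bm(no_minor, nu1), rep(30, 12),
               tolerance = 1e-6 / 30)
  degenerate <- ground_truth_site(g_site(), 1, 25, 0.5, 30, 2e4, 0.01, 0)
  expect_equal(simulate_r1rho_bm(degenerate, nu1), rep(30, 12),
               tolerance = 1e-6 / 30)
})

test_that("BM propagation agrees with the closed-form dispersion model", {
  # the reference point of the fast-exchange regime
  tr <- ground_truth_site(g_site(), 1, 25, 0.5, 30, 2e4, 0.005,
                          2 * pi * 1200)
  bm <- simulate_r1rho_bm(tr, 1000)
  eq <- dispersion_model(1000, 30, 2e4, 0.005, 2 * pi * 1200)
  expect_lt(abs(bm - eq) / eq, 0.02)
  # and across the whole default spin-lock grid
  bm_grid <- simulate_r1rho_bm(tr, default_nu1)
  eq_grid <- dispersion_model(default_nu1, 30, 2e4, 0.005, 2 * pi * 1200)
  expect_lt(max(abs(bm_grid - eq_grid) / bm_grid), 0.02)
})

test_that("eigenvalue extraction cross-checks the propagator", {
  tr <- ground_truth_site(g_site(), 1, 25, 0.5, 30, 2e4, 0.005,
                          2 * pi * 1200)
  expect_equal(r1rho_bm_eigen(tr, default_nu1),
               simulate_r1rho_bm(tr, default_nu1), tolerance = 2e-3)
})

test_that("R1rho is insensitive to the assumed longitudinal rate", {
  tr <- ground_truth_site(g_site(), 1, 25, 0.5, 30, 2e4, 0.001,
                          2 * pi * 2400)
  lo <- simulate_r1rho_bm(tr, default_nu1, r1 = 0.75)   # -50%
  hi <- simulate_r1rho_bm(tr, default_nu1, r1 = 2.25)   # +50%
  expect_lt(max(abs(lo - hi) / hi), 1e-3)
})

test_that("generated studies are deterministic in the seed", {
  design <- study_design(duplexes = c("C/C", "5mC/C"))
  truths <- default_ground_truths(design)
  a <- generate_study(design, truths, seed = 42)
  b <- generate_study(design, truths, seed = 42)
  expect_identical(a$buildup, b$buildup)
  expect_identical(a$dispersion, b$dispersion)
  # different seeds: same noise-free means, different residuals
  c1 <- generate_study(design, truths, seed = 1)
  c2 <- generate_study(design, truths, seed = 2)
  clean <- generate_study(design, truths, seed = 1, noise = FALSE)
  expect_false(identical(c1$buildup$ratio, c2$buildup$ratio))
  r1 <- c1$buildup$ratio - clean$buildup$ratio
  r2 <- c2$buildup$ratio - clean$buildup$ratio
  expect_false(identical(r1, r2))
  expect_lt(abs(mean(r1) - mean(r2)), 5 * 0.0015 / sqrt(length(r1)))
})

test_that("a noise-free study reproduces the closed-form build-up exactly", {
  design <- study_design(duplexes = "C/C")
  truths <- default_ground_truths(design)
  st <- generate_study(design, truths, seed = 1, noise = FALSE)
  for (key in names(truths)) {
    tr <- truths[[key]]
    rows <- st$buildup[st$buildup$position == tr$site$position, ]
    expect_equal(rows$ratio,
                 cleanex_model(design$mixing_times, tr$k1h_true,
                               tr$ra_true, tr$rb_true),
                 tolerance = 1e-8)
  }
})

test_that("the study layout matches the design and rejects duplicates", {
  design <- study_design()
  truths <- default_ground_truths(design)
  st <- generate_study(design, truths, seed = 42)
  expect_identical(nrow(st$buildup), 24L * 7L)
  expect_identical(nrow(st$dispersion), 24L * 12L)
  expect_length(st$manifest$truths, 24L)
  dup <- c(truths, truths[1])
  expect_error(generate_study(design, dup, seed = 1), "duplicate")
})

test_that("cross-relaxation bias is zero at sigma = 0 and grows with it", {
  tr <- ground_truth_site(g_site(), 1, 25, 0.5, 30, 2e4, 0.001,
                          2 * pi * 2400)
  nu1 <- default_nu1[c(1, 5, 9, 12)]
  expect_lt(estimate_cross_relaxation_bias(tr, 0, nu1), 1e-10)
  biases <- vapply(c(0.2, 0.5, 1, 2, 4), function(sg)
    estimate_cross_relaxation_bias(tr, sg, nu1), numeric(1))
  expect_true(all(diff(biases) >= 0))
  # typical imino conditions: below the 5% negligibility threshold
  expect_lt(biases[3], 0.05)
})
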