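test_that("intrinsic exchange factors reproduce the pKa arithmetic", {
  expect_equal(intrinsic_exchange_ratio("C")$exact, 10^(4.5 - 9.4))
  expect_equal(intrinsic_exchange_ratio("C")$reported_2sf, 1.3e-5)
  expect_equal(intrinsic_exchange_ratio("5mC")$reported_2sf, 1.0e-5)
  expect_equal(intrinsic_exchange_ratio("5hmC")$reported_2sf, 4.0e-6)
  expect_error(intrinsic_exchange_ratio("5caC"), "supply one")
  custom <- pka_table(pka_n3 = c(C = 4.5, `5caC` = 2.1))
  expect_equal(intrinsic_exchange_ratio("5caC", custom)$exact,
               10^(2.1 - 9.4))
})

test_that("normalization factors match both conventions", {
  expect_equal(normalization_factor("C"), 1)
  expect_equal(normalization_factor("C", convention = "full_precision"), 1)
  expect_equal(normalization_factor("5mC"), 1.3)
  expect_equal(normalization_factor("5hmC"), 3.3)
  expect_equal(normalization_factor("5mC", convention = "full_precision"),
               10^0.1, tolerance = 1e-12)
  expect_equal(normalization_factor("5hmC", convention = "full_precision"),
               10^0.5, tolerance = 1e-12)
  # rounded and exact conventions agree within 6%
  for (m in c("5mC", "5hmC"))
    expect_lt(abs(normalization_factor(m) /
                    normalization_factor(m, convention = "full_precision")
                  - 1), 0.06)
})

test_that("normalization factors depend only on pKa differences", {
  # a uniform shift of every pKa (equivalent to rescaling all kint by a
  # common constant) leaves every factor unchanged
  shifted <- pka_table(pka_n3 = c(C = 4.5, `5mC` = 4.4, `5hmC` = 4.0) +
                         log10(2), pka_n1_g = 9.4 + log10(2))
  for (m in c("C", "5mC", "5hmC")) {
    expect_equal(normalization_factor(m, shifted, "full_precision"),
                 normalization_factor(m, convention = "full_precision"))
  }
})

test_that("k1h normalization applies the partner-specific factor", {
  f <- cleanex_fit(k1h = 2, ra = 25, rb = 0.6, k1h_err = 0.1)
  expect_equal(normalize_k1h(f, g_site(mod = "5mC"))$k1h_norm, 2.6)
  expect_equal(normalize_k1h(f, g_site(mod = "C"))$k1h_norm, 2.0)
  f1 <- cleanex_fit(k1h = 1, ra = 25, rb = 0.6, k1h_err = 0.1)
  n <- normalize_k1h(f1, g_site(mod = "5hmC"))
  expect_equal(n$k1h_norm, 3.3)
  expect_equal(n$k1h_norm_err, 0.33)  # error scales identically
  # thymine passes through unchanged
  expect_equal(normalize_k1h(f, t_site())$k1h_norm, 2.0)
  expect_equal(normalize_k1h(f, t_site())$factor, 1)
})

test_that("kinetics combination produces the opening/closing summary", {
  site <- g_site(mod = "5mC")
  norm <- list(k1h_norm = 2.6, k1h_norm_err = 0.1, detected = TRUE)
  ex <- exchange_fit(30, 4e4, 0.001, 2 * pi * 2400, kex_err = 2e3,
                     site = site)
  cs <- combine_kinetics(norm, ex, site)
  expect_equal(cs$kclose_approx, 4e4)
  expect_equal(cs$rel_kopen_index, 2.6 * 4e4)
  expect_true(cs$ex2_ok)  # kex / k1h_norm ~ 1.5e4 >= 1e3
  # threshold flips the flag
  expect_false(combine_kinetics(norm, ex, site,
                                ex2_threshold = 1e5)$ex2_ok)
  # not-detected k1h: partial summary, no index
  cs_nd <- combine_kinetics(list(detected = FALSE), ex, site)
  expect_true(is.na(cs_nd$rel_kopen_index))
  expect_equal(cs_nd$kclose_approx, 4e4)
  # mismatched identities are refused
  other <- g_site(duplex = "5hmC/C", mod = "C")
  ex_other <- exchange_fit(30, 4e4, 0.001, 2 * pi * 2400, site = other)
  expect_error(combine_kinetics(norm, ex_other, site), "mismatch")
})

test_that("equal kex with 4x the normalized k1h gives 4x the index", {
  site_a <- g_site(duplex = "a/a")
  site_b <- g_site(duplex = "b/b")
  ex_a <- exchange_fit(30, 2.5e4, 0.001, 2 * pi * 2400, site = site_a)
  ex_b <- exchange_fit(30, 2.5e4, 0.001, 2 * pi * 2400, site = site_b)
  cs_a <- combine_kinetics(list(k1h_norm = 0.5, k1h_norm_err = 0.02,
                                detected = TRUE), ex_a, site_a)
  cs_b <- combine_kinetics(list(k1h_norm = 2.0, k1h_norm_err = 0.08,
                                detected = TRUE), ex_b, site_b)
  expect_equal(cs_b$rel_kopen_index / cs_a$rel_kopen_index, 4)
})

test_that("comparative report yields unit fold changes for duplicates", {
  mk <- function(duplex) {
    lapply(6:9, function(p) {
      site <- duplex_site(duplex, p, "G", "C")
      kinetics_summary(site, k1h_norm = p / 10, k1h_norm_err = 0.01,
                       kclose_approx = 2e4, kclose_err = 1e3,
                       rel_kopen_index = p / 10 * 2e4, ex2_ok = TRUE)
    })
  }
  rep_tab <- comparative_report(c(mk("C/C"), mk("dup/dup")), "C/C")
  expect_true(all(abs(rep_tab$fold_k1h - 1) < 1e-12))
  expect_true(all(abs(rep_tab$fold_kex - 1) < 1e-12))
  ref_rows <- rep_tab[rep_tab$duplex == "C/C", ]
  expect_true(all(ref_rows$fold_kopen_index == 1))
  expect_error(comparative_report(mk("C/C"), "missing/x"), "not present")
})

test_that("designed Kop contrasts survive the noise-free pipeline", {
  design <- study_design(duplexes = c("C/C", "5mC/C"))
  truths <- default_ground_truths(design)
  st <- generate_study(design, truths, seed = 1, noise = FALSE)
  cx <- fit_cleanex_table(st$buildup, fast_control())
  ex <- fit_dispersion_table(st$dispersion, fast_dcontrol())
  summaries <- lapply(names(cx), function(key) {
    norm <- normalize_k1h(cx[[key]])
    combine_kinetics(norm, ex[[key]], cx[[key]]$site)
  })
  rep_tab <- comparative_report(summaries, "C/C")
  got <- rep_tab[rep_tab$duplex == "5mC/C" & rep_tab$position %in% 7:8,
                 "fold_k1h"]
  expect_equal(got, c(4, 4), tolerance = 1e-5)
})
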