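#' Effective R1rho from spin-lock intensities
#'
#' Converts the intensity of an imino resonance measured after a spin-lock
#' period of length `relax_period` (`i_sl`) and the reference intensity
#' without the spin-lock (`i_0`) into the effective rotating-frame
#' relaxation rate \eqn{R_{1\rho} = -(1/T)\,\ln(I_{SL}/I_0)}.
#'
#' @param i_sl Intensity with spin-lock, > 0. Vectorized.
#' @param i_0 Reference intensity without spin-lock, > 0.
#' @param relax_period Spin-lock relaxation period T in seconds, > 0.
#' @return Effective R1rho in s^-1.
#' @examples
#' r1rho_from_intensities(0.5, 1, 0.02)  # ln(2)/0.02 = 34.657 s^-1
#' @export
r1rho_from_intensities <- function(i_sl, i_0, relax_period) {
  check_numeric(i_sl, "i_sl"); check_numeric(i_0, "i_0")
  if (any(i_sl <= 0))
    stop_invalid("non-positive spin-lock intensity (", min(i_sl),
                 "): check baseline correction and phasing")
  if (any(i_0 <= 0))
    stop_invalid("non-positive reference intensity (", min(i_0),
                 "): check baseline correction and phasing")
  if (length(relax_period) != 1 || !is.finite(relax_period) ||
      relax_period <= 0)
    stop_invalid("relax_period must be a single positive duration (s)")
  -log(i_sl / i_0) / relax_period
}

#' Baseline-noise error of an effective R1rho value
#'
#' First-order propagation of the baseline-noise amplitude through
#' [r1rho_from_intensities()]:
#' \eqn{\sigma(R_{1\rho}) = (1/T)\sqrt{(\sigma/I_{SL})^2 + (\sigma/I_0)^2}}.
#'
#' @inheritParams r1rho_from_intensities
#' @param baseline_sigma Baseline noise standard deviation in intensity
#'   units, >= 0.
#' @return Standard error of R1rho in s^-1.
#' @examples
#' r1rho_error_from_noise(1, 1, 0.01, 0.02)  # 50*sqrt(2)*0.01
#' @export
r1rho_error_from_noise <- function(i_sl, i_0, baseline_sigma, relax_period) {
  check_numeric(i_sl, "i_sl"); check_numeric(i_0, "i_0")
  if (any(i_sl <= 0) || any(i_0 <= 0))
    stop_invalid("intensities must be > 0")
  if (any(baseline_sigma < 0)) stop_invalid("baseline_sigma must be >= 0")
  if (length(relax_period) != 1 || relax_period <= 0)
    stop_invalid("relax_period must be a single positive duration (s)")
  sqrt((baseline_sigma / i_sl)^2 + (baseline_sigma / i_0)^2) / relax_period
}

#' On-resonance two-state R1rho dispersion model
#'
#' Effective R1rho of the major state of a two-state exchange process
#' (closed/open base pair) under an on-resonance spin-lock of strength
#' `nu1`, as a function of the intrinsic transverse rate `r20`, exchange
#' rate `kex = kopen + kclose`, minor-state population `pb` and
#' chemical-shift difference `dw`:
#' \deqn{R_{1\rho} = R_2^0 + \frac{p_A p_B \Delta\omega^2 k_{ex}}
#'   {\frac{\omega_{Ae}^2\omega_{Be}^2}{\omega_e^2} + k_{ex}^2
#'    - p_A p_B \Delta\omega^2\left(1 + \frac{2 k_{ex}^2 (p_A\omega_{Ae}^2
#'    + p_B\omega_{Be}^2)}{\omega_{Ae}^2\omega_{Be}^2
#'    + \omega_e^2 k_{ex}^2}\right)}}
#' with \eqn{\omega_{Ae}^2 = \omega_1^2},
#' \eqn{\omega_{Be}^2 = \Delta\omega^2 + \omega_1^2},
#' \eqn{\omega_e^2 = \Omega_A^2 + \omega_1^2} and
#' \eqn{\Omega_A = -p_B k_{ex}^2 \Delta\omega/(k_{ex}^2 + \Delta\omega^2)},
#' where \eqn{\omega_1 = 2\pi\,\nu_1}. The expression is an approximation
#' whose accuracy in the fast-exchange regime is quantified against the
#' Bloch-McConnell propagator [simulate_r1rho_bm()].
#'
#' @param nu1 Spin-lock field strength(s) nu1 = omega1/(2*pi) in Hz, > 0.
#'   Vectorized.
#' @param r20 Intrinsic transverse relaxation rate in s^-1, > 0.
#' @param kex Exchange rate in s^-1, > 0.
#' @param pb Minor-state population in `[0, 1)`.
#' @param dw Chemical-shift difference in rad s^-1, >= 0.
#' @return R1rho in s^-1, same length as `nu1`.
#' @examples
#' dispersion_model(seq(500, 15000, length.out = 6),
#'                  r20 = 30, kex = 2e4, pb = 0.005, dw = 2 * pi * 1200)
#' @export
dispersion_model <- function(nu1, r20, kex, pb, dw) {
  check_numeric(nu1, "nu1")
  if (any(nu1 <= 0)) stop_invalid("nu1 must be > 0 (Hz)")
  if (r20 <= 0 || kex <= 0) stop_invalid("r20 and kex must be > 0")
  if (pb < 0 || pb >= 1) stop_invalid("pb must lie in [0, 1)")
  if (dw < 0) stop_invalid("dw must be >= 0 (rad s^-1)")
  pa <- 1 - pb
  w1 <- 2 * pi * nu1
  wae2 <- w1^2
  wbe2 <- dw^2 + w1^2
  omega_a <- -pb * kex^2 * dw / (kex^2 + dw^2)
  we2 <- omega_a^2 + w1^2
  phi <- pa * pb * dw^2
  denom <- wae2 * wbe2 / we2 + kex^2 -
    phi * (1 + 2 * kex^2 * (pa * wae2 + pb * wbe2) /
             (wae2 * wbe2 + we2 * kex^2))
  if (any(denom <= 0))
    stop_invalid("dispersion model denominator non-positive for ",
                 sprintf("r20=%g, kex=%g, pb=%g, dw=%g", r20, kex, pb, dw),
                 ": parameters outside the approximation's validity domain")
  r20 + phi * kex / denom
}

dispersion_model_phi <- function(nu1, r20, kex, phi_ex, pb_fixed) {
  # fast-exchange parameterization: only phi_ex = pA pB dw^2 is
  # identifiable; dw is derived from the fixed pb for the auxiliaries
  dw <- sqrt(phi_ex / ((1 - pb_fixed) * pb_fixed))
  dispersion_model(nu1, r20, kex, pb_fixed, dw)
}

#' Control settings for dispersion fitting
#'
#' @param mode `"fast_exchange"` (default) fits `{r20, kex, phi_ex}` with
#'   `pb` held fixed — in fast exchange only the composite amplitude
#'   `phi_ex = pA*pB*dw^2` is identifiable; `"full"` frees `pb` and `dw`
#'   (strongly degenerate in the fast regime; a warning is attached).
#' @param pb_fixed Fixed minor-state population for fast-exchange mode.
#' @param error_method `"mc"` (Monte-Carlo residual resampling, default)
#'   or `"covariance"`.
#' @param mc_draws,seed Monte-Carlo settings.
#' @param kex_bounds Bounds on kex in s^-1.
#' @param model_selection Logical; compare against the flat (r20-only)
#'   model by corrected AIC and report "no Rex" when the flat model wins.
#' @return A list of class `"dispersion_control"`.
#' @export
dispersion_control <- function(mode = c("fast_exchange", "full"),
                               pb_fixed = 0.001,
                               error_method = c("mc", "covariance"),
                               mc_draws = 200L, seed = 1L,
                               kex_bounds = c(1e2, 1e7),
                               model_selection = TRUE) {
  if (pb_fixed <= 0 || pb_fixed > 0.5)
    stop_invalid("pb_fixed must lie in (0, 0.5]")
  structure(
    list(mode = match.arg(mode), pb_fixed = pb_fixed,
         error_method = match.arg(error_method),
         mc_draws = as.integer(mc_draws), seed = as.integer(seed),
         kex_bounds = kex_bounds, model_selection = model_selection),
    class = "dispersion_control")
}

aicc_from_chi2 <- function(chi2, n, k) {
  # least-squares AICc on weighted residuals
  n * log(chi2 / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

dispersion_start <- function(nu1, y, kex_bounds) {
  r20_0 <- y[which.max(nu1)]
  rex <- y - r20_0
  rex_max <- max(rex)
  # nu1 at half-dispersion -> kex scale
  half <- rex_max / 2
  above <- rex >= half
  nu1_half <- if (any(above)) max(nu1[above]) else stats::median(nu1)
  kex_0 <- min(max(2 * pi * nu1_half, kex_bounds[1] * 2), kex_bounds[2] / 2)
  phi_0 <- max(rex_max, 1e-3) * kex_0
  c(r20 = max(r20_0, 1e-3), kex = kex_0, phi_ex = phi_0)
}

#' Fit an on-resonance R1rho dispersion profile
#'
#' Weighted least-squares fit of [dispersion_model()] to a dispersion
#' curve. The default fast-exchange parameterization fits
#' `{r20, kex, phi_ex}` with `pb` fixed (the individual `pb` and `dw`
#' cannot be separated from their product `pA*pB*dw^2` in fast exchange);
#' `"full"` mode frees all four parameters with a degeneracy warning.
#' A corrected-AIC comparison against the flat model (`r20` only) decides
#' whether exchange broadening is present at all; when the flat model wins
#' the site is reported with `rex_observed = FALSE` and no `kex`.
#'
#' @param curve A [dispersion_curve()].
#' @param control A [dispersion_control()].
#' @return An [exchange_fit()].
#' @examples
#' s <- duplex_site("C/C", 7, "G", "C")
#' nu1 <- exp(seq(log(500), log(15000), length.out = 8))
#' y <- dispersion_model(nu1, 30, 2e4, 0.005, 2 * pi * 1200)
#' crv <- dispersion_curve(s, nu1, y, rep(0.5, 8), 0.02)
#' fit_dispersion(crv, dispersion_control(error_method = "covariance"))
#' @export
fit_dispersion <- function(curve, control = dispersion_control()) {
  stopifnot(inherits(curve, "dispersion_curve"))
  nu1 <- curve$spinlock_nu1
  y <- curve$r1rho
  if (length(nu1) < 4)
    stop_invalid("dispersion fitting needs at least 4 spin-lock points")
  if (max(nu1) / min(nu1) < 10)
    stop_invalid("spin-lock grid must span at least one decade of nu1")
  w <- 1 / curve$r1rho_errors^2
  pb <- control$pb_fixed
  kb <- control$kex_bounds
  start <- dispersion_start(nu1, y, kb)

  fitter <- function(yy, st) {
    minpack.lm::nlsLM(
      yy ~ dispersion_model_phi(nu1, r20, kex, phi_ex, pb),
      start = as.list(st), weights = w,
      lower = c(r20 = 1e-6, kex = kb[1], phi_ex = 0),
      upper = c(r20 = 1e4, kex = kb[2], phi_ex = 1e12),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  fit <- tryCatch(fitter(y, start), error = function(e) NULL)
  if (is.null(fit)) {
    return(exchange_fit(r20 = start[["r20"]], kex = start[["kex"]],
                        pb = pb,
                        dw = sqrt(start[["phi_ex"]] / ((1 - pb) * pb)),
                        converged = FALSE, site = curve$site))
  }
  p <- coef(fit)
  n <- length(y)
  resid_w <- (y - dispersion_model_phi(nu1, p[["r20"]], p[["kex"]],
                                       p[["phi_ex"]], pb)) * sqrt(w)
  chi2 <- sum(resid_w^2)
  chi2_red <- chi2 / max(n - 3, 1)

  if (control$model_selection) {
    r20_flat <- sum(w * y) / sum(w)
    chi2_flat <- sum(w * (y - r20_flat)^2)
    if (aicc_from_chi2(chi2_flat, n, 1) <= aicc_from_chi2(chi2, n, 3)) {
      return(exchange_fit(r20 = r20_flat,
                          r20_err = sqrt(1 / sum(w)),
                          kex = NA_real_, pb = NA_real_, dw = NA_real_,
                          chi2_reduced = chi2_flat / max(n - 1, 1),
                          rex_observed = FALSE, site = curve$site))
    }
  }

  errs <- dispersion_errors(fit, fitter, nu1, y, w, pb, control)
  dw_hat <- sqrt(p[["phi_ex"]] / ((1 - pb) * pb))
  dw_err <- if (is.finite(errs[["phi_ex"]]) && p[["phi_ex"]] > 0)
    errs[["phi_ex"]] / (2 * sqrt(p[["phi_ex"]] * (1 - pb) * pb))
  else NA_real_

  ef <- exchange_fit(
    r20 = p[["r20"]], kex = p[["kex"]], pb = pb, dw = dw_hat,
    phi_ex = (1 - pb) * pb * dw_hat^2,
    r20_err = errs[["r20"]], kex_err = errs[["kex"]],
    phi_ex_err = errs[["phi_ex"]], dw_err = dw_err,
    chi2_reduced = chi2_red, parameterization_mode = "fast_exchange",
    site = curve$site)

  if (control$mode == "full") {
    ef <- refit_full(curve, ef, w, control)
  }
  ef
}

refit_full <- function(curve, ef, w, control) {
  nu1 <- curve$spinlock_nu1
  y <- curve$r1rho
  kb <- control$kex_bounds
  start <- list(r20 = ef$r20, kex = ef$kex, pb = ef$pb, dw = max(ef$dw, 1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ dispersion_model(nu1, r20, kex, pb, dw),
      start = start, weights = w,
      lower = c(r20 = 1e-6, kex = kb[1], pb = 1e-6, dw = 0),
      upper = c(r20 = 1e4, kex = kb[2], pb = 0.5, dw = 1e7),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("full-mode refit did not converge; returning the ",
            "fast-exchange parameterization", call. = FALSE)
    return(ef)
  }
  warning("full parameterization: pb and dw are strongly degenerate in ",
          "fast exchange (only pA*pB*dw^2 is identifiable); interpret ",
          "their individual values with caution", call. = FALSE)
  p <- coef(fit)
  n <- length(y)
  resid_w <- (y - dispersion_model(nu1, p[["r20"]], p[["kex"]], p[["pb"]],
                                   p[["dw"]])) * sqrt(w)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(p)))
  exchange_fit(
    r20 = p[["r20"]], kex = p[["kex"]], pb = min(p[["pb"]], 0.5),
    dw = p[["dw"]],
    r20_err = se[["r20"]], kex_err = se[["kex"]], pb_err = se[["pb"]],
    dw_err = se[["dw"]],
    chi2_reduced = sum(resid_w^2) / max(n - 4, 1),
    parameterization_mode = "full", site = curve$site)
}

dispersion_errors <- function(fit, fitter, nu1, y, w, pb, control) {
  p <- coef(fit)
  nms <- names(p)
  if (control$error_method == "covariance") {
    # known per-point errors: report unscaled (known-sigma) covariance
    se <- tryCatch({
      sm <- summary(fit)
      sm$coefficients[, "Std. Error"] / sm$sigma
    }, error = function(e) setNames(rep(NA_real_, length(p)), nms))
    return(se)
  }
  yhat <- dispersion_model_phi(nu1, p[["r20"]], p[["kex"]], p[["phi_ex"]], pb)
  res <- y - yhat
  draws <- matrix(NA_real_, nrow = control$mc_draws, ncol = length(p),
                  dimnames = list(NULL, nms))
  set.seed(control$seed)
  for (i in seq_len(control$mc_draws)) {
    y_i <- yhat + sample(res, replace = TRUE)
    fit_i <- tryCatch(fitter(y_i, p), error = function(e) NULL)
    if (!is.null(fit_i)) draws[i, ] <- coef(fit_i)
  }
  apply(draws, 2, sd, na.rm = TRUE)
}

#' Exchange contribution to R1rho at the weakest spin-lock
#'
#' The conformational-exchange contribution
#' `Rex = R1rho(nu1_min) - R2^0` predicted by a fitted dispersion model at
#' the lowest measured spin-lock field, where exchange broadening is
#' largest.
#'
#' @param fit An [exchange_fit()].
#' @param nu1_min Spin-lock field strength in Hz.
#' @return Rex in s^-1 (0 for a "no Rex" fit).
#' @export
rex_at_min_spinlock <- function(fit, nu1_min) {
  stopifnot(inherits(fit, "exchange_fit"))
  if (!fit$rex_observed || !is.finite(fit$phi_ex) || fit$phi_ex == 0)
    return(0)
  dispersion_model(nu1_min, fit$r20, fit$kex, fit$pb, fit$dw) - fit$r20
}
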