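#' @importFrom stats aggregate coef median optimize quantile rnorm sd setNames var
#' @importFrom utils head modifyList read.delim write.table
NULL

#' Recognized cytosine modification states
#'
#' Epigenetic modification states of the cytosine partner of a guanine
#' imino proton: unmodified cytosine (`"C"`), 5-methylcytosine (`"5mC"`),
#' 5-hydroxymethylcytosine (`"5hmC"`) and 5-carboxylcytosine (`"5caC"`).
#' `"5caC"` is accepted for completeness but carries no default pKa entry
#' (see [pka_table()]).
#'
#' @format Character vector of length 4.
#' @export
modification_states <- c("C", "5mC", "5hmC", "5caC")

#' Default duplex labels of a hemi/full-modification CpG study
#'
#' The six duplex labels of the standard design: unmodified (`"C/C"`),
#' hemi-methylated at either CpG position (`"5mC/C"`, `"C/5mC"`), fully
#' methylated (`"5mC/5mC"`), hemi-hydroxymethylated (`"5hmC/C"`) and
#' hydroxymethyl/methyl (`"5hmC/5mC"`). The label `"X/Y"` gives the
#' modification state of the cytosine at the first CpG position (X) and at
#' the second (Y).
#'
#' @format Character vector of length 6.
#' @export
default_duplexes <- c("C/C", "5mC/C", "5mC/5mC", "C/5mC", "5hmC/C", "5hmC/5mC")

stop_invalid <- function(...) stop(..., call. = FALSE)

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0)
    stop_invalid(name, " must be a non-empty numeric vector")
  if (anyNA(x)) stop_invalid(name, " contains NA")
  if (finite && any(!is.finite(x))) stop_invalid(name, " contains non-finite values")
  invisible(x)
}

#' Construct a duplex site
#'
#' One imino-bearing base-pair position in a named duplex. Only guanine
#' (N1-H) and thymine (N3-H) carry an exchangeable imino proton; a guanine
#' site records the modification state of its Watson-Crick cytosine
#' partner, a thymine site has no cytosine partner and therefore no
#' modification state.
#'
#' @param duplex_id Character label of the duplex, e.g. `"5mC/C"`.
#' @param position Integer base-pair index, 1-based along the duplex.
#' @param base `"G"` or `"T"` (imino-bearing bases only).
#' @param partner_modification One of [modification_states] for a G site;
#'   `NULL` (the default) for a T site.
#' @return An object of class `"duplex_site"`.
#' @examples
#' duplex_site("5mC/C", 7, "G", "5mC")
#' duplex_site("C/C", 10, "T")
#' @export
duplex_site <- function(duplex_id, position, base, partner_modification = NULL) {
  if (!is.character(duplex_id) || length(duplex_id) != 1 || !nzchar(duplex_id))
    stop_invalid("duplex_id must be a non-empty string")
  if (length(position) != 1 || !is.finite(position) || position < 1 ||
      position != round(position))
    stop_invalid("position must be a single integer >= 1")
  if (length(base) != 1 || !base %in% c("G", "T"))
    stop_invalid("base must be \"G\" or \"T\" (imino-bearing bases)")
  if (base == "T" && !is.null(partner_modification))
    stop_invalid("a thymine site has no cytosine partner; ",
                 "partner_modification must be NULL")
  if (base == "G") {
    if (is.null(partner_modification))
      stop_invalid("a guanine site requires partner_modification ",
                   "(one of ", paste(modification_states, collapse = ", "), ")")
    if (length(partner_modification) != 1 ||
        !partner_modification %in% modification_states)
      stop_invalid("partner_modification must be one of ",
                   paste(modification_states, collapse = ", "))
  }
  structure(
    list(duplex_id = duplex_id, position = as.integer(position),
         base = base, partner_modification = partner_modification),
    class = "duplex_site")
}

#' @export
format.duplex_site <- function(x, ...) {
  partner <- if (is.null(x$partner_modification)) "A (no partner C)"
             else x$partner_modification
  sprintf("%s %s%d (partner: %s)", x$duplex_id, x$base, x$position, partner)
}

#' @export
print.duplex_site <- function(x, ...) {
  cat("<duplex_site>", format(x), "\n")
  invisible(x)
}

site_key <- function(site) paste(site$duplex_id, site$position, sep = ":")

#' Construct a CLEANEX-PM build-up curve
#'
#' Intensity ratios I(tau_m)/I0 of one imino proton versus CLEANEX-PM
#' mixing time, with per-point standard errors.
#'
#' @param site A [duplex_site()].
#' @param mixing_times Mixing times tau_m in seconds, strictly increasing,
#'   all positive, length >= 3.
#' @param ratios Dimensionless intensity ratios, all >= 0.
#' @param ratio_errors Per-point standard errors, all > 0.
#' @return An object of class `"build_up_curve"`.
#' @export
build_up_curve <- function(site, mixing_times, ratios, ratio_errors) {
  stopifnot(inherits(site, "duplex_site"))
  check_numeric(mixing_times, "mixing_times")
  check_numeric(ratios, "ratios")
  check_numeric(ratio_errors, "ratio_errors")
  n <- length(mixing_times)
  if (n < 3) stop_invalid("a build-up curve needs at least 3 mixing times")
  if (length(ratios) != n || length(ratio_errors) != n)
    stop_invalid("mixing_times, ratios and ratio_errors must have equal length")
  if (any(mixing_times <= 0)) stop_invalid("mixing_times must be > 0")
  if (any(diff(mixing_times) <= 0))
    stop_invalid("mixing_times must be strictly increasing")
  if (any(ratios < 0)) stop_invalid("ratios must be >= 0")
  if (any(ratio_errors <= 0)) stop_invalid("ratio_errors must be > 0")
  structure(
    list(site = site, mixing_times = as.numeric(mixing_times),
         ratios = as.numeric(ratios), ratio_errors = as.numeric(ratio_errors)),
    class = "build_up_curve")
}

#' @export
print.build_up_curve <- function(x, ...) {
  cat("<build_up_curve>", format(x$site), "\n")
  cat(sprintf("  %d mixing times, %.3g-%.3g s; max ratio %.4g\n",
              length(x$mixing_times), min(x$mixing_times),
              max(x$mixing_times), max(x$ratios)))
  invisible(x)
}

#' Construct an on-resonance R1rho dispersion curve
#'
#' Effective rotating-frame relaxation rates of one imino proton versus
#' spin-lock field strength, with per-point errors and the constant
#' relaxation period used in the experiment.
#'
#' @param site A [duplex_site()].
#' @param spinlock_nu1 Spin-lock field strengths nu1 = omega1/(2*pi) in Hz,
#'   strictly increasing, all positive, length >= 4.
#' @param r1rho Effective R1rho rates in s^-1, all > 0.
#' @param r1rho_errors Per-point standard errors in s^-1, all > 0.
#' @param relax_period Constant relaxation period T in seconds.
#' @return An object of class `"dispersion_curve"`.
#' @export
dispersion_curve <- function(site, spinlock_nu1, r1rho, r1rho_errors,
                             relax_period) {
  stopifnot(inherits(site, "duplex_site"))
  check_numeric(spinlock_nu1, "spinlock_nu1")
  check_numeric(r1rho, "r1rho")
  check_numeric(r1rho_errors, "r1rho_errors")
  n <- length(spinlock_nu1)
  if (n < 4) stop_invalid("a dispersion curve needs at least 4 spin-lock points")
  if (length(r1rho) != n || length(r1rho_errors) != n)
    stop_invalid("spinlock_nu1, r1rho and r1rho_errors must have equal length")
  if (any(spinlock_nu1 <= 0)) stop_invalid("spinlock_nu1 must be > 0")
  if (any(diff(spinlock_nu1) <= 0))
    stop_invalid("spinlock_nu1 must be strictly increasing")
  if (any(r1rho <= 0)) stop_invalid("r1rho must be > 0")
  if (any(r1rho_errors <= 0)) stop_invalid("r1rho_errors must be > 0")
  if (length(relax_period) != 1 || !is.finite(relax_period) || relax_period <= 0)
    stop_invalid("relax_period must be a single positive duration (s)")
  structure(
    list(site = site, spinlock_nu1 = as.numeric(spinlock_nu1),
         r1rho = as.numeric(r1rho), r1rho_errors = as.numeric(r1rho_errors),
         relax_period = as.numeric(relax_period)),
    class = "dispersion_curve")
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat("<dispersion_curve>", format(x$site), "\n")
  cat(sprintf("  %d spin-lock points, %.3g-%.3g kHz; T = %g ms\n",
              length(x$spinlock_nu1), min(x$spinlock_nu1) / 1e3,
              max(x$spinlock_nu1) / 1e3, 1e3 * x$relax_period))
  invisible(x)
}

#' Construct a CLEANEX-PM fit result
#'
#' Fitted parameters of the two-rate water-imino transfer model: the water
#' exchange rate `k1h`, the apparent imino relaxation rate `ra` and the
#' apparent water relaxation rate `rb`, with standard errors and reduced
#' chi-square. Usually produced by [fit_cleanex()], but the constructor can
#' also be used to build a result from externally fitted values.
#'
#' @param k1h,ra,rb Fitted rates in s^-1, all >= 0.
#' @param k1h_err,ra_err,rb_err Standard errors in s^-1, all >= 0.
#' @param chi2_reduced Reduced chi-square of the fit.
#' @param detected Logical; `FALSE` marks a "signal not detected" site
#'   whose build-up never rose above the noise floor.
#' @param converged Logical convergence flag.
#' @param at_bound Logical; `TRUE` if a parameter ended at a fit bound.
#' @param site Optional [duplex_site()] the fit belongs to.
#' @return An object of class `"cleanex_fit"`.
#' @export
cleanex_fit <- function(k1h, ra, rb, k1h_err = NA_real_, ra_err = NA_real_,
                        rb_err = NA_real_, chi2_reduced = NA_real_,
                        detected = TRUE, converged = TRUE, at_bound = FALSE,
                        site = NULL) {
  if (detected) {
    for (nm in c("k1h", "ra", "rb")) {
      v <- get(nm)
      if (length(v) != 1 || !is.finite(v) || v < 0)
        stop_invalid(nm, " must be a single rate >= 0 (s^-1)")
    }
    for (nm in c("k1h_err", "ra_err", "rb_err")) {
      v <- get(nm)
      if (length(v) != 1 || (!is.na(v) && v < 0))
        stop_invalid(nm, " must be NA or >= 0")
    }
  }
  if (!is.null(site)) stopifnot(inherits(site, "duplex_site"))
  structure(
    list(k1h = k1h, ra = ra, rb = rb, k1h_err = k1h_err, ra_err = ra_err,
         rb_err = rb_err, chi2_reduced = chi2_reduced, detected = detected,
         converged = converged, at_bound = at_bound, site = site),
    class = "cleanex_fit")
}

#' @export
print.cleanex_fit <- function(x, ...) {
  cat("<cleanex_fit>")
  if (!is.null(x$site)) cat(" ", format(x$site))
  cat("\n")
  if (!x$detected) {
    cat("  signal not detected (build-up below the noise floor)\n")
    return(invisible(x))
  }
  cat(sprintf("  k1H = %.4g +/- %.2g s^-1\n", x$k1h, x$k1h_err))
  cat(sprintf("  RA  = %.4g +/- %.2g s^-1, RB = %.4g +/- %.2g s^-1\n",
              x$ra, x$ra_err, x$rb, x$rb_err))
  cat(sprintf("  reduced chi2 = %.3g%s%s\n", x$chi2_reduced,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]",
              if (isTRUE(x$at_bound)) "  [parameter at bound]" else ""))
  invisible(x)
}

#' Construct a two-state exchange fit result
#'
#' Fitted parameters of the on-resonance two-state dispersion model:
#' intrinsic transverse rate `r20`, exchange rate `kex = kopen + kclose`,
#' and either the composite amplitude `phi_ex = pA*pB*dw^2` (fast-exchange
#' parameterization, with `pb` held fixed) or free `pb` and `dw`. The two
#' representations are kept internally consistent:
#' `phi_ex == (1 - pb) * pb * dw^2` to relative 1e-12.
#'
#' @param r20 Intrinsic transverse relaxation rate R2^0 in s^-1, > 0.
#' @param kex Exchange rate in s^-1, > 0.
#' @param pb Minor-state population in `[0, 0.5]`.
#' @param dw Chemical-shift difference between the states, rad s^-1.
#' @param phi_ex Composite amplitude pA*pB*dw^2, rad^2 s^-2.
#' @param r20_err,kex_err,pb_err,dw_err,phi_ex_err Standard errors.
#' @param chi2_reduced Reduced chi-square.
#' @param parameterization_mode `"fast_exchange"` or `"full"`.
#' @param rex_observed Logical; `FALSE` when model selection preferred the
#'   flat (no-exchange) model, in which case `kex` is not interpretable.
#' @param converged Logical convergence flag.
#' @param site Optional [duplex_site()].
#' @return An object of class `"exchange_fit"`.
#' @export
exchange_fit <- function(r20, kex, pb, dw, phi_ex = NULL,
                         r20_err = NA_real_, kex_err = NA_real_,
                         pb_err = NA_real_, dw_err = NA_real_,
                         phi_ex_err = NA_real_, chi2_reduced = NA_real_,
                         parameterization_mode = c("fast_exchange", "full"),
                         rex_observed = TRUE, converged = TRUE, site = NULL) {
  parameterization_mode <- match.arg(parameterization_mode)
  if (length(r20) != 1 || !is.finite(r20) || r20 <= 0)
    stop_invalid("r20 must be a single positive rate (s^-1)")
  if (rex_observed) {
    if (length(kex) != 1 || !is.finite(kex) || kex <= 0)
      stop_invalid("kex must be a single positive rate (s^-1)")
    if (length(pb) != 1 || !is.finite(pb) || pb < 0 || pb > 0.5)
      stop_invalid("pb must lie in [0, 0.5] (minor state)")
    if (length(dw) != 1 || !is.finite(dw) || dw < 0)
      stop_invalid("dw must be a single non-negative value (rad s^-1)")
    phi_from_pb <- (1 - pb) * pb * dw^2
    if (is.null(phi_ex)) {
      phi_ex <- phi_from_pb
    } else if (phi_from_pb > 0 &&
               abs(phi_ex - phi_from_pb) > 1e-12 * phi_from_pb) {
      stop_invalid("phi_ex inconsistent with (1 - pb) * pb * dw^2")
    }
  } else {
    kex <- NA_real_; pb <- NA_real_; dw <- NA_real_
    if (is.null(phi_ex)) phi_ex <- NA_real_
  }
  if (!is.null(site)) stopifnot(inherits(site, "duplex_site"))
  structure(
    list(r20 = r20, kex = kex, pb = pb, dw = dw, phi_ex = phi_ex,
         r20_err = r20_err, kex_err = kex_err, pb_err = pb_err,
         dw_err = dw_err, phi_ex_err = phi_ex_err,
         chi2_reduced = chi2_reduced,
         parameterization_mode = parameterization_mode,
         rex_observed = rex_observed, converged = converged, site = site),
    class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("<exchange_fit>")
  if (!is.null(x$site)) cat(" ", format(x$site))
  cat("\n")
  cat(sprintf("  R2^0 = %.4g +/- %.2g s^-1\n", x$r20, x$r20_err))
  if (!x$rex_observed) {
    cat("  no Rex observed (flat model preferred); kex not reported\n")
    return(invisible(x))
  }
  cat(sprintf("  kex  = %.4g +/- %.2g s^-1 (= kopen + kclose)\n",
              x$kex, x$kex_err))
  cat(sprintf("  phi_ex = %.4g +/- %.2g rad^2 s^-2 (pb fixed at %.3g in %s mode)\n",
              x$phi_ex, x$phi_ex_err, x$pb, x$parameterization_mode))
  cat(sprintf("  reduced chi2 = %.3g%s\n", x$chi2_reduced,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Construct a per-site kinetics summary
#'
#' Combines the normalized water exchange rate (proportional to the
#' base-opening equilibrium constant Kop) with the dispersion-derived
#' exchange rate (approximately the closing rate kclose when the open-state
#' population is very small) into the semi-quantitative per-site summary.
#'
#' @param site A [duplex_site()].
#' @param k1h_norm Normalized k1H in s^-1 (relative-Kop scale); `NA` for a
#'   "not detected" site.
#' @param k1h_norm_err Standard error of `k1h_norm`.
#' @param rel_kop Optional fold change of `k1h_norm` versus the matched
#'   reference-duplex site.
#' @param kclose_approx The fitted kex in s^-1, interpreted as kclose;
#'   `NA` when no Rex was observed.
#' @param kclose_err Standard error of `kclose_approx`.
#' @param rel_kopen_index `k1h_norm * kex`, a relative opening-rate index
#'   on an arbitrary common scale; `NA` when either input is missing.
#' @param ex2_ok Logical; whether the EX2/fast-closing assumption
#'   (kex much larger than k1H) held for this site.
#' @return An object of class `"kinetics_summary"`.
#' @export
kinetics_summary <- function(site, k1h_norm, k1h_norm_err = NA_real_,
                             rel_kop = NA_real_, kclose_approx = NA_real_,
                             kclose_err = NA_real_,
                             rel_kopen_index = NA_real_, ex2_ok = NA) {
  stopifnot(inherits(site, "duplex_site"))
  if (!is.na(rel_kopen_index) && rel_kopen_index < 0)
    stop_invalid("rel_kopen_index must be >= 0")
  structure(
    list(site = site, k1h_norm = k1h_norm, k1h_norm_err = k1h_norm_err,
         rel_kop = rel_kop, kclose_approx = kclose_approx,
         kclose_err = kclose_err, rel_kopen_index = rel_kopen_index,
         ex2_ok = ex2_ok),
    class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("<kinetics_summary>", format(x$site), "\n")
  cat(sprintf("  k1H (normalized, rel. Kop scale): %.4g s^-1\n", x$k1h_norm))
  cat(sprintf("  kclose ~ kex: %.4g s^-1; rel. kopen index: %.4g\n",
              x$kclose_approx, x$rel_kopen_index))
  cat(sprintf("  EX2 assumption credible: %s\n", x$ex2_ok))
  invisible(x)
}
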