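#' pKa table for intrinsic imino exchange
#'
#' pKa values governing base-catalysed exchange of the guanine imino
#' proton with water through the open base pair: the N3 pKa of the paired
#' (possibly modified) cytosine, which acts as the base catalyst, and the
#' N1 pKa of guanine. Defaults: 4.5 (C), 4.4 (5mC), 4.0 (5hmC) for the
#' cytosine N3, and 9.4 for guanine N1. 5caC has no default entry and
#' must be supplied by the user if needed.
#'
#' @param pka_n3 Named numeric vector mapping modification states to the
#'   cytosine N3 pKa.
#' @param pka_n1_g Guanine N1 pKa.
#' @return An object of class `"pka_table"`.
#' @examples
#' pka_table()
#' pka_table(pka_n3 = c(C = 4.5, `5mC` = 4.4, `5hmC` = 4.0, `5caC` = 2.1))
#' @export
pka_table <- function(pka_n3 = c(C = 4.5, `5mC` = 4.4, `5hmC` = 4.0),
                      pka_n1_g = 9.4) {
  if (!is.numeric(pka_n3) || is.null(names(pka_n3)) ||
      any(!nzchar(names(pka_n3))))
    stop_invalid("pka_n3 must be a named numeric vector")
  unknown <- setdiff(names(pka_n3), modification_states)
  if (length(unknown))
    stop_invalid("unknown modification state(s) in pka_n3: ",
                 paste(unknown, collapse = ", "))
  if (length(pka_n1_g) != 1 || !is.finite(pka_n1_g))
    stop_invalid("pka_n1_g must be a single finite value")
  structure(list(pka_n3 = pka_n3, pka_n1_g = pka_n1_g),
            class = "pka_table")
}

#' @export
print.pka_table <- function(x, ...) {
  cat("<pka_table>\n")
  cat("  cytosine N3:",
      paste(sprintf("%s = %.2f", names(x$pka_n3), x$pka_n3),
            collapse = ", "), "\n")
  cat(sprintf("  guanine N1: %.2f\n", x$pka_n1_g))
  invisible(x)
}

# significant rounding with ties away from zero (the usual reporting
# convention; base signif() rounds half to even, turning 3.25 into 3.2)
signif_half_up <- function(x, digits = 2) {
  if (!is.finite(x) || x == 0) return(x)
  m <- floor(log10(abs(x)))
  f <- 10^(digits - 1 - m)
  sign(x) * floor(abs(x) * f + 0.5 + abs(x) * f * 1e-12) / f
}

require_pka <- function(mod, table) {
  if (length(mod) != 1 || !mod %in% modification_states)
    stop_invalid("mod must be one of ",
                 paste(modification_states, collapse = ", "))
  if (!mod %in% names(table$pka_n3))
    stop_invalid("no N3 pKa entry for \"", mod, "\"; supply one via ",
                 "pka_table(pka_n3 = c(..., `", mod, "` = <value>))")
  table$pka_n3[[mod]]
}

#' Relative intrinsic exchange factor of a modified cytosine
#'
#' The intrinsic open-state exchange rate of a guanine imino proton is
#' base-catalysed by the paired cytosine N3 and proportional to
#' `10^(pKa(N3;C) - pKa(N1;G))`. This function evaluates that
#' proportionality factor exactly, and also reports it rounded to two
#' significant figures (the field's reporting convention: 1.3e-5 for C,
#' 1.0e-5 for 5mC, 0.40e-5 for 5hmC under the default pKa values).
#'
#' @param mod A modification state (see [modification_states]).
#' @param table A [pka_table()].
#' @return A list with `exact` and `reported_2sf` (both dimensionless).
#' @examples
#' intrinsic_exchange_ratio("C")$reported_2sf    # 1.3e-5
#' intrinsic_exchange_ratio("5hmC")$reported_2sf # 4.0e-6 (= 0.40e-5)
#' @export
intrinsic_exchange_ratio <- function(mod, table = pka_table()) {
  pka_c <- require_pka(mod, table)
  exact <- 10^(pka_c - table$pka_n1_g)
  list(exact = exact, reported_2sf = signif_half_up(exact, 2))
}

#' k1H normalization factor for a modification state
#'
#' Multiplier that converts the measured water exchange rate of a guanine
#' paired with a modified cytosine onto the intrinsic-exchange scale of
#' unmodified cytosine, so normalized rates compare opening equilibria
#' (Kop) directly: `kint(C) / kint(mod)`. Two conventions are provided:
#' `"paper_rounded"` takes the ratio of the two-significant-figure
#' intrinsic factors and rounds the result to two significant figures
#' (yielding exactly 1.3 for 5mC and 3.3 for 5hmC under the default pKa
#' values); `"full_precision"` uses the exact power-of-ten ratio
#' (10^0.1 = 1.2589 for 5mC, 10^0.5 = 3.1623 for 5hmC) and is the better
#' choice for new data.
#'
#' @param mod A modification state.
#' @param table A [pka_table()].
#' @param convention `"paper_rounded"` or `"full_precision"`.
#' @return Dimensionless multiplier (1 for unmodified cytosine).
#' @examples
#' normalization_factor("5mC")                     # 1.3
#' normalization_factor("5hmC")                    # 3.3
#' normalization_factor("5hmC", convention = "full_precision")
#' @export
normalization_factor <- function(mod, table = pka_table(),
                                 convention = c("paper_rounded",
                                                "full_precision")) {
  convention <- match.arg(convention)
  ref <- intrinsic_exchange_ratio("C", table)
  val <- intrinsic_exchange_ratio(mod, table)
  if (convention == "paper_rounded")
    signif_half_up(ref$reported_2sf / val$reported_2sf, 2)
  else
    ref$exact / val$exact
}

#' Normalize a fitted k1H rate by the partner modification state
#'
#' Under the EX2 regime (closing much faster than intrinsic exchange),
#' `k1H = Kop * kint`. Because kint differs between cytosine modification
#' states, measured k1H rates of guanines paired with modified cytosines
#' are multiplied by [normalization_factor()] before comparison; the
#' normalized rate is then interpretable as Kop on a common arbitrary
#' scale. Thymine sites pass through unchanged (their exchange is not
#' catalysed by a paired cytosine).
#'
#' @param fit A [cleanex_fit()].
#' @param site A [duplex_site()] (defaults to the site stored in `fit`).
#' @param table A [pka_table()].
#' @param convention Normalization convention, see
#'   [normalization_factor()].
#' @return A list with `k1h_norm`, `k1h_norm_err` (s^-1, relative-Kop
#'   scale), `factor`, and `detected`.
#' @export
normalize_k1h <- function(fit, site = fit$site, table = pka_table(),
                          convention = c("paper_rounded",
                                         "full_precision")) {
  stopifnot(inherits(fit, "cleanex_fit"))
  convention <- match.arg(convention)
  if (is.null(site))
    stop_invalid("no site attached to the fit; pass one explicitly")
  stopifnot(inherits(site, "duplex_site"))
  if (!fit$detected)
    return(list(k1h_norm = NA_real_, k1h_norm_err = NA_real_,
                factor = NA_real_, detected = FALSE))
  factor <- if (site$base == "T") 1 else {
    if (is.null(site$partner_modification))
      stop_invalid("guanine site without a partner modification state")
    normalization_factor(site$partner_modification, table, convention)
  }
  list(k1h_norm = fit$k1h * factor,
       k1h_norm_err = fit$k1h_err * factor,
       factor = factor, detected = TRUE)
}

#' Combine exchange and dispersion results into a kinetics summary
#'
#' Merges the normalized water exchange rate (proportional to the opening
#' equilibrium constant Kop) with the dispersion-derived exchange rate
#' into the per-site semi-quantitative summary. Because the open-state
#' population is very small, `kex ~ kclose`; the product
#' `k1h_norm * kex` is then a relative index of the opening rate
#' (Kop * kclose up to the unknown constant kint of unmodified cytosine).
#' The `ex2_ok` flag records whether the fast-closing assumption behind
#' the EX2 interpretation is credible (`kex / k1h_norm` at or above
#' `ex2_threshold`). "Not detected" and "no Rex" sites propagate as
#' partial summaries with `NA` in the affected fields.
#'
#' @param norm A result of [normalize_k1h()].
#' @param exchange An [exchange_fit()], or `NULL` if no dispersion data
#'   exist for the site.
#' @param site The [duplex_site()] the summary belongs to.
#' @param ex2_threshold Minimum `kex / k1h_norm` for `ex2_ok`.
#' @return A [kinetics_summary()].
#' @export
combine_kinetics <- function(norm, exchange, site, ex2_threshold = 1e3) {
  stopifnot(inherits(site, "duplex_site"))
  if (!is.null(exchange)) {
    stopifnot(inherits(exchange, "exchange_fit"))
    if (!is.null(exchange$site) &&
        site_key(exchange$site) != site_key(site))
      stop_invalid("site mismatch: exchange fit belongs to ",
                   site_key(exchange$site), ", summary to ", site_key(site))
    kex <- if (exchange$rex_observed) exchange$kex else NA_real_
    kex_err <- if (exchange$rex_observed) exchange$kex_err else NA_real_
  } else {
    kex <- NA_real_; kex_err <- NA_real_
  }
  k1h_norm <- if (isTRUE(norm$detected)) norm$k1h_norm else NA_real_
  k1h_err <- if (isTRUE(norm$detected)) norm$k1h_norm_err else NA_real_
  idx <- if (is.finite(k1h_norm) && is.finite(kex)) k1h_norm * kex
         else NA_real_
  ex2 <- if (is.finite(k1h_norm) && is.finite(kex) && k1h_norm > 0)
    kex / k1h_norm >= ex2_threshold else NA
  kinetics_summary(site, k1h_norm = k1h_norm, k1h_norm_err = k1h_err,
                   kclose_approx = kex, kclose_err = kex_err,
                   rel_kopen_index = idx, ex2_ok = ex2)
}

#' Per-position fold changes versus a reference duplex
#'
#' Site-specific comparison of the opening/closing kinetics across
#' duplexes: for every position, the fold change of the normalized k1H
#' (relative Kop), of kex (~ kclose) and of the relative opening-rate
#' index with respect to the matched site of a reference duplex. Sites
#' missing in either duplex are reported with `NA`.
#'
#' @param summaries A list of [kinetics_summary()] objects.
#' @param reference_duplex Duplex label to compare against.
#' @return A data frame with one row per (duplex, position), columns
#'   `duplex`, `position`, `k1h_norm`, `kclose`, `rel_kopen_index` and
#'   fold-change columns `fold_k1h`, `fold_kex`, `fold_kopen_index`.
#' @export
comparative_report <- function(summaries, reference_duplex) {
  rows <- lapply(summaries, function(s) {
    data.frame(duplex = s$site$duplex_id, position = s$site$position,
               k1h_norm = s$k1h_norm, k1h_norm_err = s$k1h_norm_err,
               kclose = s$kclose_approx,
               rel_kopen_index = s$rel_kopen_index,
               ex2_ok = s$ex2_ok)
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!reference_duplex %in% tab$duplex)
    stop_invalid("reference duplex \"", reference_duplex,
                 "\" not present in the summaries")
  ref <- tab[tab$duplex == reference_duplex, ]
  ref_k1h <- setNames(ref$k1h_norm, ref$position)
  ref_kex <- setNames(ref$kclose, ref$position)
  ref_idx <- setNames(ref$rel_kopen_index, ref$position)
  pos <- as.character(tab$position)
  tab$fold_k1h <- tab$k1h_norm / ref_k1h[pos]
  tab$fold_kex <- tab$kclose / ref_kex[pos]
  tab$fold_kopen_index <- tab$rel_kopen_index / ref_idx[pos]
  tab
}
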