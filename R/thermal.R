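#' Construct a UV melting curve
#'
#' Absorbance versus temperature of a duplex melting experiment.
#'
#' @param temperatures Temperatures in degrees Celsius, strictly
#'   increasing, length >= 10.
#' @param absorbance Absorbance values (arbitrary units).
#' @return An object of class `"melting_curve"`.
#' @export
melting_curve <- function(temperatures, absorbance) {
  check_numeric(temperatures, "temperatures")
  check_numeric(absorbance, "absorbance")
  if (length(temperatures) < 10)
    stop_invalid("a melting curve needs at least 10 points")
  if (length(absorbance) != length(temperatures))
    stop_invalid("temperatures and absorbance must have equal length")
  if (any(diff(temperatures) <= 0))
    stop_invalid("temperatures must be strictly increasing")
  structure(list(temperatures = as.numeric(temperatures),
                 absorbance = as.numeric(absorbance)),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> %d points, %.1f-%.1f degC\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures)))
  invisible(x)
}

#' Melting temperature by the first-derivative method
#'
#' Smooths the absorbance curve with a Savitzky-Golay (moving-polynomial)
#' filter, differentiates numerically, locates the maximum of the first
#' derivative and refines it by quadratic interpolation around the
#' discrete maximum (avoiding quantization of Tm to the temperature
#' spacing). The uncertainty is estimated by bootstrap over the smoothing
#' residuals.
#'
#' @param curve A [melting_curve()].
#' @param window Odd smoothing window length in points (default 7).
#' @param poly_order Polynomial order of the filter (default 2).
#' @param n_boot Number of bootstrap draws for the uncertainty.
#' @param seed Seed for the bootstrap.
#' @return A list with `tm` (degC), `tm_err` (degC, `NA` if
#'   `n_boot = 0`), and `derivative` (data frame of temperature and
#'   smoothed dA/dT).
#' @examples
#' t <- seq(25, 95, by = 1)
#' a <- 0.5 + 0.3 / (1 + exp(-(t - 55.4) / 2.5))
#' tm_from_first_derivative(melting_curve(t, a), n_boot = 0)$tm
#' @export
tm_from_first_derivative <- function(curve, window = 7, poly_order = 2,
                                     n_boot = 100L, seed = 1L) {
  stopifnot(inherits(curve, "melting_curve"))
  if (window %% 2 != 1 || window < poly_order + 2)
    stop_invalid("window must be odd and exceed poly_order + 1")
  tm_once <- function(a) {
    sm <- signal::sgolayfilt(a, p = poly_order, n = window)
    dT <- curve$temperatures
    d <- diff(sm) / diff(dT)
    tmid <- (dT[-1] + dT[-length(dT)]) / 2
    i <- which.max(d)
    # a transition requires an interior derivative peak that stands out
    # above the background slope (a linear drift has none)
    prominence <- d[i] - median(d)
    if (i == 1 || i == length(d) ||
        prominence <= max(abs(median(d)), 1e-6 * max(abs(d))))
      stop_invalid("no melting transition: the first derivative has no ",
                   "interior maximum standing out above the baseline ",
                   "slope in the temperature range")
    # quadratic vertex through the three points around the maximum
    x <- tmid[(i - 1):(i + 1)]; y <- d[(i - 1):(i + 1)]
    den <- (y[1] - 2 * y[2] + y[3])
    tm <- if (den < 0)
      x[2] - (x[3] - x[2]) * (y[3] - y[1]) / (2 * den)
    else x[2]
    list(tm = tm, deriv = data.frame(temperature = tmid, dA_dT = d),
         smooth = sm)
  }
  base <- tm_once(curve$absorbance)
  tm_err <- NA_real_
  if (n_boot > 0) {
    res <- curve$absorbance - base$smooth
    set.seed(seed)
    draws <- vapply(seq_len(n_boot), function(i) {
      tryCatch(tm_once(base$smooth + sample(res, replace = TRUE))$tm,
               error = function(e) NA_real_)
    }, numeric(1))
    tm_err <- sd(draws, na.rm = TRUE)
  }
  list(tm = base$tm, tm_err = tm_err, derivative = base$deriv)
}
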