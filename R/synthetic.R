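#' Construct a ground-truth parameter set for one site
#'
#' True two-state exchange and transfer parameters of one imino site, used
#' by the numerical simulators and recorded in the manifest of a generated
#' study for downstream recovery tests.
#'
#' @param site A [duplex_site()].
#' @param k1h_true Water exchange rate in s^-1, > 0.
#' @param ra_true,rb_true Apparent imino/water relaxation rates, s^-1, > 0.
#' @param r20_true Intrinsic transverse rate, s^-1, > 0.
#' @param kex_true Exchange rate kopen + kclose, s^-1, > 0.
#' @param pb_true Open-state population, in (0, 0.5).
#' @param dw_true Chemical-shift difference, rad s^-1, > 0.
#' @param noise_sigma Baseline-noise standard deviation on intensity
#'   ratios (dimensionless), >= 0.
#' @return An object of class `"ground_truth_site"`.
#' @export
ground_truth_site <- function(site, k1h_true, ra_true, rb_true, r20_true,
                              kex_true, pb_true, dw_true,
                              noise_sigma = 0.0015) {
  stopifnot(inherits(site, "duplex_site"))
  for (nm in c("ra_true", "rb_true", "r20_true", "kex_true")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      stop_invalid(nm, " must be a single positive value")
  }
  # zero is allowed for k1h (no exchange pathway), pb (no minor state)
  # and dw (degenerate states) so the no-exchange limits can be simulated
  if (length(k1h_true) != 1 || !is.finite(k1h_true) || k1h_true < 0)
    stop_invalid("k1h_true must be a single value >= 0")
  if (length(dw_true) != 1 || !is.finite(dw_true) || dw_true < 0)
    stop_invalid("dw_true must be a single value >= 0")
  if (pb_true < 0 || pb_true >= 0.5)
    stop_invalid("pb_true must lie in [0, 0.5)")
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  structure(
    list(site = site, k1h_true = k1h_true, ra_true = ra_true,
         rb_true = rb_true, r20_true = r20_true, kex_true = kex_true,
         pb_true = pb_true, dw_true = dw_true, noise_sigma = noise_sigma),
    class = "ground_truth_site")
}

#' Construct a study design
#'
#' Acquisition layout of a six-duplex imino-exchange study. The defaults
#' reproduce the standard design: mixing times of 5, 10, 15, 20, 50, 100
#' and 200 ms; 12 log-spaced spin-lock fields spanning 0.5-15 kHz; a
#' constant relaxation period of 20 ms. The 12-bp duplex sequence is a
#' configurable synthetic stand-in carrying a CpG step at positions 7/8.
#'
#' @param duplexes Character vector of duplex labels `"X/Y"` where X and Y
#'   are the modification states of the cytosines at the first and second
#'   CpG position.
#' @param positions Integer base-pair positions carrying the imino sites.
#' @param mixing_times CLEANEX mixing times in seconds.
#' @param spinlock_nu1 Spin-lock field grid in Hz.
#' @param relax_period Spin-lock relaxation period T in seconds.
#' @param baseline_sigma Baseline noise (intensity units, reference
#'   intensity 1) used to derive the per-point R1rho errors.
#' @param sequence 12-base top-strand sequence (synthetic default, CpG at
#'   positions 7-8).
#' @param cpg_positions The two positions whose cytosines carry the X/Y
#'   modification states.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(duplexes = default_duplexes,
                         positions = 6:9,
                         mixing_times = c(5, 10, 15, 20, 50, 100, 200) / 1000,
                         spinlock_nu1 = exp(seq(log(500), log(15000),
                                                length.out = 12)),
                         relax_period = 0.02,
                         baseline_sigma = 0.0035,
                         sequence = "GTGACACGTGTC",
                         cpg_positions = c(7L, 8L)) {
  if (!all(duplexes %in% default_duplexes) &&
      !all(grepl("^[^/]+/[^/]+$", duplexes)))
    stop_invalid("duplex labels must have the form \"X/Y\"")
  check_numeric(mixing_times, "mixing_times")
  check_numeric(spinlock_nu1, "spinlock_nu1")
  if (any(mixing_times <= 0) || any(diff(mixing_times) <= 0))
    stop_invalid("mixing_times must be positive and strictly increasing")
  if (any(spinlock_nu1 <= 0) || any(diff(spinlock_nu1) <= 0))
    stop_invalid("spinlock_nu1 must be positive and strictly increasing")
  if (relax_period <= 0) stop_invalid("relax_period must be > 0")
  if (nchar(sequence) != 12)
    stop_invalid("sequence must be a 12-base string")
  structure(
    list(duplexes = duplexes, positions = as.integer(positions),
         mixing_times = mixing_times, spinlock_nu1 = spinlock_nu1,
         relax_period = relax_period, baseline_sigma = baseline_sigma,
         sequence = sequence, cpg_positions = as.integer(cpg_positions)),
    class = "study_design")
}

#' Partner-cytosine modification state at a position of a labelled duplex
#'
#' For a duplex labelled `"X/Y"`, the guanine at the first CpG position
#' pairs with a cytosine in state X, the guanine at the second CpG
#' position with a cytosine in state Y; guanines elsewhere pair with
#' unmodified cytosine.
#'
#' @param duplex_id Duplex label, e.g. `"5mC/C"`.
#' @param position Base-pair position.
#' @param cpg_positions The two CpG positions (default 7 and 8).
#' @return A modification state string.
#' @export
partner_modification_at <- function(duplex_id, position,
                                    cpg_positions = c(7L, 8L)) {
  parts <- strsplit(duplex_id, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop_invalid("duplex_id must have the form \"X/Y\"")
  if (position == cpg_positions[1]) parts[1]
  else if (position == cpg_positions[2]) parts[2]
  else "C"
}

#' Simulate a CLEANEX-PM build-up curve by numerical integration
#'
#' Numerically integrates the coupled two-pool magnetization-transfer
#' system
#' \deqn{d m_i/dt = -(R_A + k_{1H})\, m_i + k_{1H}\, m_w, \qquad
#'       d m_w/dt = -R_B\, m_w}
#' with \eqn{m_w(0) = 1}, \eqn{m_i(0) = 0} (water as a large labelled
#' reservoir decaying at RB; back-transfer from the vastly smaller imino
#' pool neglected). This is the system whose exact solution is
#' [cleanex_model()], so the integrator serves as an independent oracle
#' for the closed form.
#'
#' @param truth A [ground_truth_site()].
#' @param mixing_times Mixing times in seconds, > 0.
#' @param noise Logical; add Gaussian noise of sd `truth$noise_sigma`
#'   (clipped at zero, since measured ratios are reported non-negative).
#' @param seed Integer seed used when `noise = TRUE`.
#' @return A [build_up_curve()].
#' @export
simulate_cleanex_numeric <- function(truth, mixing_times, noise = FALSE,
                                     seed = 1L) {
  stopifnot(inherits(truth, "ground_truth_site"))
  check_numeric(mixing_times, "mixing_times")
  if (any(mixing_times < 0)) stop_invalid("mixing_times must be >= 0")
  ratios <- cleanex_ode_ratios(truth$k1h_true, truth$ra_true, truth$rb_true,
                               mixing_times)
  sigma <- truth$noise_sigma
  if (noise && sigma > 0) {
    set.seed(seed)
    ratios <- pmax(ratios + rnorm(length(ratios), sd = sigma), 0)
  }
  build_up_curve(truth$site, mixing_times, ratios,
                 rep(max(sigma, 1e-6), length(mixing_times)))
}

cleanex_ode_ratios <- function(k1h, ra, rb, mixing_times) {
  if (k1h == 0) return(rep(0, length(mixing_times)))
  pos <- mixing_times > 0
  if (!all(pos)) {
    out <- numeric(length(mixing_times))
    out[pos] <- cleanex_ode_ratios(k1h, ra, rb, mixing_times[pos])
    return(out)
  }
  deriv <- function(t, y, parms) {
    list(c(-(parms$ra + parms$k1h) * y[1] + parms$k1h * y[2],
           -parms$rb * y[2]))
  }
  out <- tryCatch(
    deSolve::lsoda(y = c(imino = 0, water = 1),
                   times = c(0, mixing_times), func = deriv,
                   parms = list(k1h = k1h, ra = ra, rb = rb),
                   rtol = 1e-11, atol = 1e-13),
    warning = function(w)
      stop_invalid("ODE integration failed for k1h=", k1h, ", ra=", ra,
                   ", rb=", rb, ": ", conditionMessage(w)),
    error = function(e)
      stop_invalid("ODE integration failed for k1h=", k1h, ", ra=", ra,
                   ", rb=", rb, ": ", conditionMessage(e)))
  as.numeric(out[-1, "imino"])
}

bm_generator <- function(r20, kex, pb, dw, w1, r1 = 1.5) {
  # two-state Bloch-McConnell generator, spin-lock w1 along +x,
  # state A on resonance (offset 0), state B offset dw (rad/s);
  # magnetization order (Ax, Ay, Az, Bx, By, Bz), free decay to zero
  kab <- pb * kex
  kba <- (1 - pb) * kex
  block <- function(delta) {
    matrix(c(-r20, delta,    0,
             -delta, -r20, -w1,
             0,       w1,  -r1),
           nrow = 3, byrow = TRUE)
  }
  L <- matrix(0, 6, 6)
  L[1:3, 1:3] <- block(0) - diag(kab, 3)
  L[4:6, 4:6] <- block(dw) - diag(kba, 3)
  L[1:3, 4:6] <- diag(kba, 3)
  L[4:6, 1:3] <- diag(kab, 3)
  L
}

#' Simulate an on-resonance R1rho value by Bloch-McConnell propagation
#'
#' Propagates the six-dimensional two-state Bloch-McConnell system (x, y,
#' z magnetization of both states) under a spin-lock field `w1 = 2*pi*nu1`
#' applied along +x, on resonance with the major state; the minor state
#' sits at offset `dw_true`. Exchange enters with rates
#' `kAB = pb*kex` and `kBA = (1-pb)*kex`. The effective R1rho is extracted
#' exactly as the experiment does, by the two-point log formula
#' `-(1/T) * log(Mx(T)/Mx(0))` on the total spin-locked x magnetization
#' (see [r1rho_from_intensities()]). Propagation uses the matrix
#' exponential of the exact generator. An eigenvalue-based extraction is
#' available as a cross-check via [r1rho_bm_eigen()].
#'
#' @param truth A [ground_truth_site()].
#' @param nu1 Spin-lock field strength(s) in Hz, > 0. Vectorized.
#' @param relax_period Relaxation period T in seconds, > 0.
#' @param r1 Longitudinal relaxation rate of both states in s^-1
#'   (default 1.5; on-resonance locking makes the result insensitive to
#'   this choice).
#' @return R1rho in s^-1, one value per element of `nu1`.
#' @export
simulate_r1rho_bm <- function(truth, nu1, relax_period = 0.02, r1 = 1.5) {
  stopifnot(inherits(truth, "ground_truth_site"))
  check_numeric(nu1, "nu1")
  if (any(nu1 <= 0)) stop_invalid("nu1 must be > 0 (Hz)")
  if (relax_period <= 0) stop_invalid("relax_period must be > 0")
  vapply(nu1, function(v) {
    L <- bm_generator(truth$r20_true, truth$kex_true, truth$pb_true,
                      truth$dw_true, 2 * pi * v, r1)
    m0 <- c(1 - truth$pb_true, 0, 0, truth$pb_true, 0, 0)
    mt <- as.numeric(Matrix::expm(L * relax_period) %*% m0)
    mx <- mt[1] + mt[4]
    if (mx <= 0)
      stop_invalid("locked magnetization non-positive at T = ",
                   relax_period, " s for kex=", truth$kex_true, ", pb=",
                   truth$pb_true, ", dw=", truth$dw_true,
                   "; use a shorter relaxation period")
    -log(mx) / relax_period
  }, numeric(1))
}

#' Eigenvalue extraction of R1rho from the Bloch-McConnell generator
#'
#' Cross-check for [simulate_r1rho_bm()]: decomposes the six-dimensional
#' generator into eigenmodes and returns the decay rate of the slowest
#' mode that actually contributes to the spin-locked x magnetization
#' (modes perpendicular to the effective field carry negligible weight for
#' an on-resonance lock and are excluded by their projection).
#'
#' @inheritParams simulate_r1rho_bm
#' @param weight_tol Minimum relative modal contribution to the observed
#'   x magnetization for a mode to be considered.
#' @return R1rho in s^-1, one value per element of `nu1`.
#' @export
r1rho_bm_eigen <- function(truth, nu1, r1 = 1.5, weight_tol = 1e-3) {
  stopifnot(inherits(truth, "ground_truth_site"))
  vapply(nu1, function(v) {
    L <- bm_generator(truth$r20_true, truth$kex_true, truth$pb_true,
                      truth$dw_true, 2 * pi * v, r1)
    e <- eigen(L)
    m0 <- c(1 - truth$pb_true, 0, 0, truth$pb_true, 0, 0)
    w <- solve(e$vectors, m0)
    proj_x <- drop(rep(c(1, 0, 0), 2) %*% e$vectors)
    contrib <- Mod(proj_x * w)
    keep <- contrib > weight_tol * sum(contrib)
    -max(Re(e$values[keep]))
  }, numeric(1))
}

#' Cross-relaxation bias estimate for R1rho dispersion
#'
#' Estimates how much homonuclear 1H-1H cross-relaxation with a nearby
#' passive proton could bias the measured R1rho. The two-state
#' Bloch-McConnell system is augmented with one neighbor spin coupled by a
#' Solomon-type rotating-frame cross-relaxation rate `neighbor_sigma`
#' acting between corresponding Cartesian components, and the maximum
#' relative deviation of R1rho over the spin-lock grid is returned. This
#' is a reconstruction of the usual two-spin treatment, not a published
#' derivation.
#'
#' @param truth A [ground_truth_site()].
#' @param neighbor_sigma Cross-relaxation rate in s^-1 (may be negative).
#' @param nu1 Spin-lock grid in Hz.
#' @param relax_period Relaxation period T in seconds.
#' @param neighbor_offset Offset of the neighbor resonance from the
#'   carrier, rad s^-1 (default 2*pi*3000, a proton a few ppm away at
#'   600 MHz).
#' @param r1 Longitudinal relaxation rate, s^-1.
#' @return Maximum over the grid of
#'   `|R1rho(sigma) - R1rho(0)| / R1rho(0)` (dimensionless).
#' @export
estimate_cross_relaxation_bias <- function(truth, neighbor_sigma, nu1,
                                           relax_period = 0.02,
                                           neighbor_offset = 2 * pi * 3000,
                                           r1 = 1.5) {
  stopifnot(inherits(truth, "ground_truth_site"))
  if (!is.finite(neighbor_sigma))
    stop_invalid("neighbor_sigma must be finite")
  base <- simulate_r1rho_bm(truth, nu1, relax_period, r1)
  with_sigma <- vapply(nu1, function(v) {
    r1rho_bm_neighbor(truth, 2 * pi * v, relax_period, neighbor_sigma,
                      neighbor_offset, r1)
  }, numeric(1))
  max(abs(with_sigma - base) / base)
}

r1rho_bm_neighbor <- function(truth, w1, relax_period, sigma,
                              neighbor_offset, r1) {
  # 9-dimensional system: (Ax..Bz) as in bm_generator plus neighbor
  # (Nx, Ny, Nz) at its own offset under the same lock, coupled to state A
  # by the cross-relaxation rate sigma on matching components
  L6 <- bm_generator(truth$r20_true, truth$kex_true, truth$pb_true,
                     truth$dw_true, w1, r1)
  L <- matrix(0, 9, 9)
  L[1:6, 1:6] <- L6
  L[7:9, 7:9] <- matrix(c(-truth$r20_true, neighbor_offset, 0,
                          -neighbor_offset, -truth$r20_true, -w1,
                          0, w1, -r1), nrow = 3, byrow = TRUE)
  L[1:3, 7:9] <- L[1:3, 7:9] - diag(sigma, 3)
  L[7:9, 1:3] <- L[7:9, 1:3] - diag(sigma, 3)
  m0 <- c(1 - truth$pb_true, 0, 0, truth$pb_true, 0, 0, 1, 0, 0)
  mt <- as.numeric(Matrix::expm(L * relax_period) %*% m0)
  mx <- mt[1] + mt[4]
  if (mx <= 0)
    stop_invalid("locked magnetization non-positive in the neighbor-",
                 "coupled system; use a shorter relaxation period")
  -log(mx / (1)) / relax_period
}

#' Default ground truths of the six-duplex synthetic study
#'
#' Per-site true parameters emulating the study conditions: water exchange
#' rates of order 0.1-10 s^-1 that place all build-up maxima below 0.1,
#' exchange rates of order 10^4 s^-1, open-state populations of a few
#' tenths of a percent, shift differences around 2*pi*1000-1500 rad s^-1,
#' and a built-in 4-fold opening-equilibrium contrast at the CpG guanines
#' of the hemi-methylated duplex ("5mC/C") relative to the unmodified one
#' ("C/C"). The `k1h_true` values are stored on the raw (un-normalized)
#' scale: the designed relative-Kop value divided by the pKa-derived
#' normalization factor of the partner cytosine, so that the analysis
#' pipeline recovers the designed Kop contrasts after normalization.
#'
#' @param design A [study_design()].
#' @param noise_sigma Baseline-noise sd on intensity ratios.
#' @return A named list of [ground_truth_site()] objects, keyed
#'   `"duplex:position"`.
#' @export
default_ground_truths <- function(design = study_design(),
                                  noise_sigma = 0.0015) {
  # designed relative-Kop values at positions 6..9; the 5hmC-paired
  # guanine (position 7 of the 5hmC duplexes) is set far below the
  # detection limit, emulating that its water exchange is not observed
  kop_rel <- list(
    "C/C"       = c(0.30, 0.50, 0.60, 0.80),
    "5mC/C"     = c(0.60, 2.00, 2.40, 1.60),
    "5mC/5mC"   = c(0.30, 0.50, 0.60, 0.65),
    "C/5mC"     = c(0.35, 0.55, 1.20, 0.65),
    "5hmC/C"    = c(0.30, 0.05, 0.60, 0.80),
    "5hmC/5mC"  = c(0.30, 0.05, 0.55, 0.65))
  kex <- list(
    "C/C"       = c(1.8e4, 1.5e4, 1.5e4, 2.0e4),
    "5mC/C"     = c(2.5e4, 2.8e4, 2.6e4, 2.4e4),
    "5mC/5mC"   = c(2.4e4, 2.6e4, 2.5e4, 2.2e4),
    "C/5mC"     = c(2.2e4, 2.4e4, 3.5e4, 2.3e4),
    "5hmC/C"    = c(2.3e4, 2.6e4, 2.4e4, 2.2e4),
    "5hmC/5mC"  = c(2.3e4, 2.5e4, 2.6e4, 3.5e4))
  r20 <- list(
    "C/C"       = c(35, 36, 35, 34),
    "5mC/C"     = c(27, 26, 27, 28),
    "5mC/5mC"   = c(28, 27, 28, 29),
    "C/5mC"     = c(29, 28, 27, 28),
    "5hmC/C"    = c(30, 29, 28, 29),
    "5hmC/5mC"  = c(28, 28, 27, 28))
  # open-state population and shift difference: only the product
  # pA*pB*dw^2 is identifiable in fast exchange, so the truths use the
  # same representative pb as the analysis default (0.001) with dw sized
  # to give exchange contributions of a few s^-1 at the weakest spin-lock
  dw_hz <- c(2600, 2400, 2500, 2200)   # per position 6..9
  pb <- rep(0.001, 4)
  pka <- pka_table()

  truths <- list()
  for (dx in design$duplexes) {
    if (!dx %in% names(kop_rel))
      stop_invalid("no default ground truth for duplex \"", dx,
                   "\"; supply truths explicitly")
    for (j in seq_along(design$positions)) {
      pos <- design$positions[j]
      idx <- pos - 5L
      if (idx < 1 || idx > 4)
        stop_invalid("default truths cover positions 6-9 only")
      mod <- partner_modification_at(dx, pos, design$cpg_positions)
      site <- duplex_site(dx, pos, "G", mod)
      factor <- normalization_factor(mod, pka, "paper_rounded")
      truths[[site_key(site)]] <- ground_truth_site(
        site,
        k1h_true = kop_rel[[dx]][idx] / factor,
        ra_true = 25, rb_true = 0.5,
        r20_true = r20[[dx]][idx],
        kex_true = kex[[dx]][idx],
        pb_true = pb[idx],
        dw_true = 2 * pi * dw_hz[idx],
        noise_sigma = noise_sigma)
    }
  }
  truths
}

#' Generate a full synthetic study
#'
#' Simulates CLEANEX-PM build-up and R1rho dispersion tables for every
#' site of a study design, using the numerical two-pool and
#' Bloch-McConnell simulators, with seeded Gaussian noise. Per-point
#' R1rho errors are derived from the design's baseline noise through
#' [r1rho_error_from_noise()] on the implied spin-lock intensities, and
#' the added noise has exactly those standard deviations. All randomness
#' flows from the single `seed`; repeated calls are identical.
#'
#' @param design A [study_design()].
#' @param truths Named list of [ground_truth_site()], keyed
#'   `"duplex:position"` (default [default_ground_truths()]).
#' @param seed Integer seed.
#' @param noise Logical; `FALSE` returns noise-free tables.
#' @return A list of class `"synthetic_study"` with elements `buildup`
#'   and `dispersion` (data frames in the interchange schemas of
#'   [read_table()]), and `manifest` (design, seed and all true
#'   parameters).
#' @export
generate_study <- function(design = study_design(),
                           truths = default_ground_truths(design),
                           seed = 1L, noise = TRUE) {
  stopifnot(inherits(design, "study_design"))
  keys <- vapply(truths, function(tr) site_key(tr$site), character(1))
  if (anyDuplicated(keys))
    stop_invalid("duplicate (duplex, position) in truths: ",
                 paste(keys[duplicated(keys)], collapse = ", "))
  set.seed(seed)
  bu_rows <- list(); di_rows <- list()
  for (tr in truths) {
    site <- tr$site
    clean <- cleanex_ode_ratios(tr$k1h_true, tr$ra_true, tr$rb_true,
                                design$mixing_times)
    sigma <- tr$noise_sigma
    ratios <- if (noise && sigma > 0)
      pmax(clean + rnorm(length(clean), sd = sigma), 0) else clean
    bu_rows[[site_key(site)]] <- data.frame(
      duplex = site$duplex_id, position = site$position, base = site$base,
      partner_mod = site$partner_modification %||% "",
      tau_m_s = design$mixing_times, ratio = ratios,
      ratio_err = rep(max(sigma, 1e-6), length(clean)))

    r_clean <- simulate_r1rho_bm(tr, design$spinlock_nu1,
                                 design$relax_period)
    i_sl <- exp(-r_clean * design$relax_period)
    errs <- r1rho_error_from_noise(i_sl, 1, design$baseline_sigma,
                                   design$relax_period)
    errs <- pmax(errs, 1e-6)
    r_obs <- if (noise) r_clean + rnorm(length(r_clean), sd = errs)
             else r_clean
    r_obs <- pmax(r_obs, 1e-3)
    di_rows[[site_key(site)]] <- data.frame(
      duplex = site$duplex_id, position = site$position, base = site$base,
      partner_mod = site$partner_modification %||% "",
      nu1_hz = design$spinlock_nu1, r1rho_s = r_obs, r1rho_err_s = errs,
      T_s = design$relax_period)
  }
  manifest <- list(
    seed = as.integer(seed), noise = noise,
    design = unclass(design),
    truths = lapply(truths, function(tr) {
      c(list(duplex = tr$site$duplex_id, position = tr$site$position,
             base = tr$site$base,
             partner_mod = tr$site$partner_modification %||% ""),
        tr[setdiff(names(tr), "site")])
    }))
  structure(
    list(buildup = do.call(rbind, c(bu_rows, make.row.names = FALSE)),
         dispersion = do.call(rbind, c(di_rows, make.row.names = FALSE)),
         manifest = manifest),
    class = "synthetic_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat(sprintf("  %d build-up curves, %d dispersion curves (seed %d%s)\n",
              length(unique(paste(x$buildup$duplex, x$buildup$position))),
              length(unique(paste(x$dispersion$duplex, x$dispersion$position))),
              x$manifest$seed,
              if (x$manifest$noise) "" else ", noise-free"))
  invisible(x)
}
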