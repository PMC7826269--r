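---
title: "Base-pair opening and closing kinetics from imino proton NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-pair opening and closing kinetics from imino proton NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iminokinetics)
```

## The measurement problem

A Watson–Crick base pair in duplex DNA is not static: it transiently
opens, and only in the open state can the guanine N1–H or thymine N3–H
imino proton exchange with water. Two NMR experiments probe this process
from complementary sides.

**Water–imino exchange (CLEANEX-PM).** Magnetization transferred from
water builds up on the imino resonance as a function of the mixing time
$\tau_m$. The build-up follows a two-rate transfer model

$$\frac{I(\tau_m)}{I_0} = \frac{k_{1H}}{R_A + k_{1H} - R_B}
  \left\{e^{-R_B \tau_m} - e^{-(R_A + k_{1H})\tau_m}\right\},$$

where $k_{1H}$ is the water–imino exchange rate and $R_A$, $R_B$ are
apparent relaxation rates of the imino and water protons. Without an
added exchange catalyst the process sits in the EX2 limit (closing much
faster than intrinsic open-state exchange), so

$$k_{1H} = K_{op}\, k_{int},$$

with $K_{op} = k_{open}/k_{close}$ the opening equilibrium constant and
$k_{int}$ the intrinsic exchange rate of the open state.

**On-resonance rotating-frame dispersion ($R_{1\rho}$).** Locking the
imino magnetization at field strength $\omega_1$ and measuring the decay
rate as a function of $\omega_1$ resolves microsecond exchange between
the closed (major, A) and open (minor, B) states. The effective rate is
computed from the spin-locked and reference intensities as
$R_{1\rho} = -(1/T)\ln(I_{SL}/I_0)$ and fitted to a two-state model in
which $R_{1\rho} = R_2^0 + R_{ex}(\omega_1)$, with the exchange term
parameterized by $k_{ex} = k_{open} + k_{close}$, the minor-state
population $p_B$ and the shift difference $\Delta\omega$ (the exact
expression, including its auxiliary effective frequencies, is documented
in `?dispersion_model`). Because the open population is very small,
$k_{ex} \approx k_{close}$.

**The combination.** The pKa of the cytosine N3 — the base catalyst of
guanine imino exchange — depends on the epigenetic modification state of
the cytosine (4.5 for C, 4.4 for 5mC, 4.0 for 5hmC; guanine N1 9.4), so
$k_{int} \propto 10^{pK_a(N3;C) - pK_a(N1;G)}$. Multiplying measured
$k_{1H}$ rates by the resulting factors (1.3 for 5mC, 3.3 for 5hmC under
the rounded two-significant-figure convention) places all sites on a
common relative-$K_{op}$ scale. The product of the normalized $k_{1H}$
and $k_{ex}$ is then a relative index of the opening rate
($K_{op} \cdot k_{close}$, up to the unknown proportionality constant in
$k_{int}$). The analysis is deliberately semi-quantitative: absolute
$k_{open}$ and $k_{close}$ are never reported, only ratios between
duplexes, because the proportionality constant of $k_{int}$ is unknown
and catalyst titrations (which could estimate it) perturb the duplex.

## Fitting choices

The fits are weighted least squares (Levenberg–Marquardt) with
inverse-variance weights from the per-point errors.

**CLEANEX.** Parameters $\{k_{1H}, R_A, R_B\}$, bounds
$k_{1H} \in [0, 100]$, $R_A \in [0.1, 200]$, $R_B \in [0.01, 5]$
s$^{-1}$. Start values: $k_{1H}$ from the initial slope, with an
amplitude-based fallback ($\max_i I_i/I_0 \times R_A^{(0)}$) because the
earliest mixing-time points of weak sites can sit in the noise; $R_A$
from the reciprocal position of the build-up maximum; $R_B$ from a fixed
0.5 s$^{-1}$. If the first solution's reduced $\chi^2$ exceeds 2, a
small $R_A$ multi-start grid (5, 25, 80 s$^{-1}$) guards against the
shallow local minima this model develops when early points are
noise-dominated. The model's removable singularity at
$R_A + k_{1H} = R_B$ is evaluated through `expm1`, which is continuous
to machine precision across the degeneracy. $R_A$ and $R_B$ are
*apparent* rates and are fitted per site; a shared-$R_B$ mode is
available (`cleanex_control(shared_rb = )`) since the water relaxation
rate could arguably be common to all sites.

**Detection limit.** A site whose fitted build-up amplitude stays below
twice the median ratio error is reported as *not detected* rather than
given a meaningless rate — weak sites at the baseline-noise level are a
real feature of these experiments.

**Dispersion.** The default `fast_exchange` parameterization fits
$\{R_2^0, k_{ex}, \Phi_{ex}\}$ with $p_B$ held fixed, because in fast
exchange only the composite $\Phi_{ex} = p_A p_B \Delta\omega^2$ is
identifiable. The fixed $p_B$ defaults to 0.001 (the open population is
very small); $\Delta\omega$ is derived from $\Phi_{ex}$ and $p_B$ for
the model's auxiliary terms. Two caveats follow. First, the derived
$\Delta\omega$ enters the model denominator, so the fixed-$p_B$ choice
is only immaterial *deep* in fast exchange
($k_{ex} \gg \Delta\omega_{derived}$); the test suite demonstrates the
insensitivity there, and in the moderate regime the assumed $p_B$ should
reflect prior knowledge. Second, `full` mode frees $p_B$ and
$\Delta\omega$ but is strongly degenerate and attaches a warning; it
exists for slow-intermediate regimes, not for routine use. Start values:
$R_2^0$ from the highest-power point, $k_{ex}$ from the field at
half-dispersion, $\Phi_{ex}$ from $R_{ex} \times k_{ex}$; bounds
$k_{ex} \in [10^2, 10^7]$ s$^{-1}$.

**"No Rex" model selection.** A corrected-AIC comparison against the
flat model ($R_2^0$ only) decides whether exchange broadening is present
at all; when the flat model wins, the site is reported without a
$k_{ex}$, matching how flat profiles are annotated in practice.

**Uncertainties.** Default: Monte-Carlo residual resampling (200 seeded
draws, refitting on fitted-plus-resampled residuals). Fast alternative:
the covariance matrix at the solution, *not* rescaled by the residual
variance, because the per-point errors are known from baseline noise.
With 4 residual degrees of freedom, rescaled ("summary") errors would
have the coverage of a $t_4$ interval (about 63%) rather than the
nominal 68%; the unscaled intervals cover the truth in 60–76% of seeded
replicates, which the suite verifies on 500 fits. The bulk pipeline uses
covariance errors by default through its configuration; single-curve
calls default to Monte-Carlo.

**EX2 flag.** The summary marks `ex2_ok` when
$k_{ex}/k_{1H,norm} \ge 10^3$. The EX2 assumption underlying
$k_{1H} = K_{op} k_{int}$ requires closing to be much faster than
intrinsic exchange; $10^3$ is a deliberately conservative documented
choice, as the regime is usually asserted rather than quantified.

## What the synthetic generator emulates — and what it does not

`generate_study()` simulates the standard six-duplex design (C/C, 5mC/C,
5mC/5mC, C/5mC, 5hmC/C, 5hmC/5mC; 12-bp duplex with a CpG at positions
7/8; guanine sites at positions 6–9) under the canonical acquisition
grid: mixing times 5, 10, 15, 20, 50, 100, 200 ms; twelve log-spaced
spin-lock fields 0.5–15 kHz; relaxation period 20 ms. The default
12-base sequence is a synthetic stand-in (the biological sequence is a
configurable parameter, not a constant of the method).

The simulators are *numerical*, independent of the closed forms they
feed: the build-up comes from integrating the coupled two-pool transfer
system (water treated as a large labelled reservoir decaying at $R_B$,
back-transfer neglected because the imino pool is vastly smaller), and
the dispersion from matrix-exponential propagation of the
six-dimensional two-state Bloch–McConnell system with the lock applied
on-resonance with the major state, read out by the same two-point log
formula as the experiment. An eigenvalue-based extraction cross-checks
the propagation. The longitudinal rate defaults to 1.5 s$^{-1}$; for an
on-resonance lock the result is insensitive to it (verified under ±50%
variation).

Default ground truths place the study in the regime the analysis
assumes: $k_{1H}$ of order 0.1–10 s$^{-1}$ with all build-up maxima
below 0.1; $k_{ex}$ of order $10^4$ s$^{-1}$; open-state populations of
0.1%; shift differences of $2\pi \times$ 2.2–2.6 kHz. The truths use
the same representative $p_B$ as the analysis default, because only
$p_A p_B \Delta\omega^2$ is physically identifiable — any $(p_B,
\Delta\omega)$ pair with the same product describes the same data. Three
designed features mirror the qualitative structure of real
modification studies: a four-fold opening-equilibrium contrast at both
CpG guanines of the hemi-methylated duplex relative to unmodified; a
two-fold contrast at its flanking sites; and 5hmC-paired guanines far
below the CLEANEX detection limit (their exchange is not observable,
and the pipeline must say so rather than invent a rate).

Noise is additive Gaussian: constant sd 0.0015 on intensity ratios
(baseline-noise-limited; measured ratios are reported non-negative, so
simulated values are clipped at zero — relevant only for sites already
near the detection limit), and on $R_{1\rho}$ the sd propagated from a
baseline amplitude of 0.0035 through the intensity-to-rate conversion,
giving per-point errors around 0.4–0.5 s$^{-1}$ in the default study.

What passing tests on this generator do *not* show about real data: no
peak overlap or deconvolution errors, no $B_1$ inhomogeneity or
off-resonance effects during the lock, no temperature drift, no
three-state exchange, homoscedastic noise only (a heteroscedastic
option would be a straightforward extension), and cross-relaxation only
in the form of the reconstructed two-spin estimate below.

**Cross-relaxation estimate.** `estimate_cross_relaxation_bias()`
augments the Bloch–McConnell system with one passive neighbor proton
coupled by a Solomon-type rotating-frame cross-relaxation rate and
reports the maximal relative change of $R_{1\rho}$ over the spin-lock
grid. This is a reconstruction of the usual two-spin treatment — not a
published derivation — with a documented negligibility threshold of 5%;
for typical imino conditions ($\sigma = 1$ s$^{-1}$, $R_2^0 = 30$
s$^{-1}$) the bias evaluates to about 3%.

## Numerical choices

* Angular frequencies are rad s$^{-1}$ internally; all user-facing I/O
  uses $\nu = \omega/2\pi$ in Hz, converted exactly once at the
  boundary.
* The dispersion expression is evaluated *exactly as written above*,
  including its minor-state offset term
  $\Omega_A = -p_B k_{ex}^2 \Delta\omega/(k_{ex}^2 + \Delta\omega^2)$,
  which differs from some population-averaged forms in the literature;
  rather than second-guessing it, the Bloch–McConnell oracle quantifies
  the approximation: agreement is within 2% (in practice better than
  0.7%) over a 156-point grid spanning $k_{ex}$ $5\times10^3$–$10^5$
  s$^{-1}$, $p_B$ $10^{-4}$–$10^{-2}$, $\Delta\omega/2\pi$ 0.1–3 kHz
  with $k_{ex} \ge 3\Delta\omega$, and deviations outside that regime
  are measured and reported by the same test rather than hidden.
* The two-pool integration (`deSolve::lsoda`, tolerances $10^{-11}$)
  matches the closed form to $10^{-8}$ relative everywhere tested,
  including at the $R_A + k_{1H} = R_B$ degeneracy.
* Melting curves are smoothed with a Savitzky–Golay filter (window 7,
  order 2 — configurable; no specific smoother is canonical),
  differentiated, and the derivative maximum refined by quadratic vertex
  interpolation so $T_m$ is not quantized to the 1 °C sampling.
  A curve whose derivative maximum does not stand out above the
  background slope is reported as having no transition. Recovery bias on
  ideal sigmoids is below 0.01 °C; the acceptance bound is 0.1 °C.
* Helical-parameter summaries use the sample ($n-1$) standard deviation
  — distribution widths are the quantity of interest and the estimator
  choice is otherwise immaterial at $10^5$ frames (sampling every 10 ps
  of a 1 μs trajectory). Frames are used raw, not block-averaged.
* Rounding of reported intrinsic-exchange factors uses
  ties-away-from-zero at two significant figures (the reporting
  convention that makes $1.3/0.40 = 3.25$ round to 3.3); base R's
  `signif()` rounds ties to even and would give 3.2.
* All randomness flows from a single user-supplied seed; per-stage seeds
  are derived deterministically from it, and two pipeline runs with the
  same configuration produce byte-identical output files.

## Design decisions that were genuinely open

* **Normalization convention.** The printed factors 1.3 and 3.3 arise
  from pre-rounded intrinsic-exchange values; the exact power-of-ten
  ratios are $10^{0.1} = 1.259$ and $10^{0.5} = 3.162$. Both conventions
  are implemented (`paper_rounded`, the default, for reproducing the
  reported scale; `full_precision` recommended for new data); they agree
  within 6%.
* **Which sites get normalized.** Only the guanine directly paired with
  the modified cytosine; flanking guanines keep the unmodified-cytosine
  factor, and thymines are never normalized (their exchange is not
  catalysed by a paired cytosine N3).
* **Per-site vs shared apparent rates.** $R_A$/$R_B$ independent per
  site by default (they are "apparent" and site-dependent); shared-$R_B$
  offered via configuration.
* **Problem sizes in the test suite.** The recovery study runs the full
  six-duplex design with 100 noisy replicates (4,800 fits), the error
  coverage check 500 replicates, and the oracle-equivalence grids
  156–240 parameter sets — sizes chosen to give the medians and coverage
  rates stable sampling distributions while keeping the whole suite
  under a minute.

## Limitations

Off-resonance $R_{1\rho}$ geometry, three-site exchange, pulse-level
simulation of the experiment, spectral processing and peak
deconvolution, and absolute opening/closing rates are out of scope. The
$T_m$ module extracts transition midpoints only, not thermodynamic
parameters. The helical-parameter module consumes pre-computed
per-frame tables; it never runs molecular dynamics or the extraction
program itself.
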