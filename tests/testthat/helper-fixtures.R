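# shared fixtures: everything is generated in code, no stored data

g_site <- function(duplex = "C/C", position = 7, mod = "C") {
  duplex_site(duplex, position, "G", mod)
}

t_site <- function(duplex = "C/C", position = 10) {
  duplex_site(duplex, position, "T")
}

default_taus <- c(5, 10, 15, 20, 50, 100, 200) / 1000

default_nu1 <- exp(seq(log(500), log(15000), length.out = 12))

fast_control <- function(...) cleanex_control(error_method = "covariance", ...)

fast_dcontrol <- function(...) dispersion_control(error_method = "covariance",
                                                  ...)

# parameter grid over the two-state fast-exchange regime used by the
# oracle-equivalence checks; `fast` flags kex >= 3*dw
oracle_grid <- function() {
  grid <- expand.grid(
    kex = 10^seq(log10(5e3), 5, length.out = 5),
    pb = 10^seq(-4, -2, length.out = 4),
    dw = 2 * pi * c(100, 300, 1000, 3000),
    r20 = c(10, 35, 60))
  grid$fast <- grid$kex >= 3 * grid$dw
  grid
}

oracle_grid_deviation <- function(grid, nu1 = default_nu1) {
  s <- g_site()
  vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tr <- ground_truth_site(s, 1, 25, 0.5, g$r20, g$kex, g$pb, g$dw)
    bm <- simulate_r1rho_bm(tr, nu1)
    eq <- dispersion_model(nu1, g$r20, g$kex, g$pb, g$dw)
    max(abs(bm - eq) / bm)
  }, numeric(1))
}
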