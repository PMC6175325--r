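# Shared fixtures and small numeric helpers for the suite.

unit_zener <- function() zener(E_e = 1, tau_eps = 2, tau_sig = 1)

baseline_biot <- function() {
  biot_medium(phi = 0.5, rho_s = 2650, rho_f = 1000, K_s = 3.6e10,
              K_f = 2.2e9, eta_f = 1e-3, B = 1e-11, tortuosity = 1.25,
              K_r = 5e7, mu_r = 5e3)
}

log_grid <- function(lo, hi, per_decade = 10) {
  10^seq(log10(lo), log10(hi), by = 1 / per_decade)
}

# worst-case relative deviation between two complex vectors
rel_err <- function(a, b) max(Mod(a - b) / Mod(b))

# scaled complementary error function, exact reference for E_{1/2}(-x)
erfcx <- function(x) exp(x^2) * 2 * stats::pnorm(x * sqrt(2),
                                                 lower.tail = FALSE)

# fitting windows for the spectral power-law tails: the subleading term
# decays as (tau/tau_eps)^(-alpha), so sit ~2/alpha decades out to see
# the asymptote at the 1e-2 level
slope_windows <- function(al) {
  d0 <- max(4, ceiling(2 / al))
  list(lo = log_grid(10^-(d0 + 2), 10^-d0, 20),
       hi = log_grid(10^d0, 10^(d0 + 2), 20))
}

# spectral band wide enough that truncated tail mass (~ (Omega
# tau_eps)^(-alpha)) stays below the 1e-6 creep comparison level
creep_band <- function(al) {
  d <- max(18, ceiling(8 / al))
  log_grid(10^-d, 10^d, 0.25)
}
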