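test_that("time-spectral density takes its closed-form values", {
  # at tau = tau_eps with alpha = 1/2 the denominator is 1 + 1 + 0
  p <- fractional_kv(1, 1, alpha = 0.5)
  expect_equal(time_spectral(p, 1)$values, 1 / (2 * pi))
  p2 <- fractional_kv(1, 3, alpha = 0.5)
  expect_equal(time_spectral(p2, 3)$values, 1 / (2 * pi * 3))
  # non-negative everywhere
  tau <- log_grid(1e-8, 1e8, 5)
  for (al in c(0.1, 0.5, 0.95)) {
    expect_true(all(time_spectral(fractional_kv(1, 1, al), tau)$values >= 0))
  }
})

test_that("time and frequency spectral densities are the same function", {
  # S_eps(Omega) = a R_eps(1/Omega)/Omega^2, an algebraic identity
  Om <- log_grid(1e-8, 1e8, 10)
  for (al in seq(0.1, 0.9, by = 0.1)) {
    for (ratio in c(0, 1e-3, 0.5, 0.999)) {
      p <- fractional_zener(2, 1, ratio * 1, al)
      S <- freq_spectral(p, Om)
      R <- time_spectral(p, 1 / Om)
      expect_lt(max(abs(S$values - S$a * R$values / Om^2) / S$values),
                1e-14)
    }
  }
})

test_that("time-spectral density integrates to one", {
  for (al in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    p <- fractional_kv(1, 1, al)
    total <- stats::integrate(function(u) {
      tau <- exp(u)
      time_spectral(p, tau)$values * tau
    }, -46 / al, 46 / al, rel.tol = 1e-10, subdivisions = 2000L)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("log-log asymptote slopes match alpha - 1 and -alpha - 1", {
  for (al in c(0.2, 0.5, 0.8)) {
    p <- fractional_kv(1, 1, al)
    w <- slope_windows(al)
    expect_lt(abs(loglog_slope(w$lo, time_spectral(p, w$lo)$values) -
                   (al - 1)), 0.01)
    expect_lt(abs(loglog_slope(w$hi, time_spectral(p, w$hi)$values) -
                   (-al - 1)), 0.01)
    expect_lt(abs(loglog_slope(w$lo, freq_spectral(p, w$lo)$values) -
                   (al - 1)), 0.01)
    expect_lt(abs(loglog_slope(w$hi, freq_spectral(p, w$hi)$values) -
                   (-al - 1)), 0.01)
  }
  # alpha -> 0: both tails approach a single Omega^-1 law
  p <- fractional_kv(1, 1, 0.01)
  lo <- log_grid(1e-6, 1e-4, 20)
  hi <- log_grid(1e4, 1e6, 20)
  expect_equal(loglog_slope(lo, freq_spectral(p, lo)$values), -1,
               tolerance = 0.02)
  expect_equal(loglog_slope(hi, freq_spectral(p, hi)$values), -1,
               tolerance = 0.02)
})

test_that("alpha = 1 collapses to a single-relaxation atom", {
  p <- fractional_zener(1, 2, 1, alpha = 1)
  R <- time_spectral(p, c(1, 2, 3))
  expect_equal(R$atom, 2)                       # at tau = tau_eps
  S <- freq_spectral(p, c(0.1, 1))
  expect_equal(S$atom, 0.5)                     # at Omega = 1/tau_eps
  expect_equal(S$a, (1 / 1) * (1 - 1 / 2))
  # atom creep is a single exponential saturation
  expect_equal(creep_from_spectrum(S, 1e9), S$a, tolerance = 1e-12)
})

test_that("creep quadrature agrees with the Mittag-Leffler oracle", {
  tt <- log_grid(1e-3, 1e3, 2)
  for (al in c(0.3, 0.5, 0.8)) {
    p <- fractional_kv(1, 1, al)
    S <- freq_spectral(p, creep_band(al))
    J_quad <- creep_from_spectrum(S, tt)
    J_ml <- S$a * (1 - mittag_leffler(al, -tt^al))
    expect_lt(max(abs(J_quad / J_ml - 1)), 1e-6)
  }
  # fractional Zener: same oracle with the Zener compliance weight
  p <- fractional_zener(2, 1, 1e-3, 0.6)
  S <- freq_spectral(p, log_grid(1e-18, 1e18, 0.25))
  tt <- log_grid(1e-2, 1e2, 2)
  J_ml <- S$a * (1 - mittag_leffler(0.6, -tt^0.6))
  expect_lt(max(abs(creep_from_spectrum(S, tt) / J_ml - 1)), 1e-6)
})

test_that("generic relaxation superposition matches closed forms", {
  # S(Omega) = exp(-Omega): G_tau(t) = 1/(1 + t)
  t <- c(0.2, 1, 5, 40)
  G <- relaxation_from_spectrum(function(Om) exp(-Om), t,
                                band = c(1e-10, 1e4))
  expect_equal(G, 1 / (1 + t), tolerance = 1e-8)
  # half-Gaussian density: G_tau(t) = sqrt(pi/2) erfcx(t/sqrt(2))
  G2 <- relaxation_from_spectrum(function(Om) exp(-Om^2 / 2), c(0.5, 2),
                                 band = c(1e-10, 1e3))
  expect_equal(G2, sqrt(pi / 2) * erfcx(c(0.5, 2) / sqrt(2)),
               tolerance = 1e-8)
  expect_error(relaxation_from_spectrum(function(Om) Om, 0, c(1, 10)),
               "positive")
})

test_that("creep limits and coverage checks behave", {
  p <- fractional_kv(1, 1, 0.5)
  S <- freq_spectral(p, log_grid(1e-18, 1e18, 0.25))
  expect_lt(creep_from_spectrum(S, 1e-10), 1e-4 * S$a)   # J(0+) -> 0
  expect_equal(creep_from_spectrum(S, 1e12), S$a, tolerance = 1e-4)
  narrow <- freq_spectral(p, log_grid(1e-2, 1e2, 2))
  expect_error(creep_from_spectrum(narrow, 1), "coverage")
  expect_error(creep_from_spectrum(S, -1), "positive")
  expect_error(creep_from_spectrum(time_spectral(p, 1), 1), "frequency")
})
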