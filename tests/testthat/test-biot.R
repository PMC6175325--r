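test_that("effective densities follow the mass-coupling closure", {
  d <- derive_densities(baseline_biot())
  expect_equal(d$rho, 1825)                    # phi rho_f + (1-phi) rho_s
  expect_equal(d$rho_22, 625)                  # tortuosity phi rho_f
  expect_equal(d$rho_12, -125)
  expect_equal(d$rho_c, 2500)                  # tortuosity rho_f / phi
  expect_equal(d$rho_11, (1 - 0.5) * 2650 + 125)
  # closure identities
  expect_equal(d$rho_12 + d$rho_22, 0.5 * 1000)
  expect_true(d$rho_12 <= 0)
  expect_equal(d$gamma_22, d$rho_22 / d$rho)
})

test_that("characteristic frequencies obey their identities", {
  set.seed(7)
  for (p in random_biot(20)) {
    d <- derive_densities(p)
    expect_equal(d$f_c_prime * 2 * pi * p$B * p$tortuosity * p$rho_f /
                   (p$eta_f * p$phi), 1, tolerance = 1e-12)
    expect_equal(d$f_c_prime,
                 d$f_c * (d$gamma_12 + d$gamma_22) / d$gamma_22,
                 tolerance = 1e-12)
    # f_c' is the Zener crossover omega_eps / 2 pi
    expect_equal(d$f_c_prime, biot_to_zener(p)$omega_eps / (2 * pi),
                 tolerance = 1e-12)
  }
})

test_that("the baseline medium maps to its hand-computed Zener", {
  bz <- biot_to_zener(baseline_biot())
  expect_equal(bz$omega_eps, 4.0e4)            # eta_f / (rho_c B)
  expect_equal(bz$omega_sig / bz$omega_eps, 1 / (1 - 1e6 / (1825 * 2500)))
  expect_equal(bz$zener$E_e, 5e3)
  expect_equal(bz$rho, 1825)
  expect_equal(bz$c0, sqrt(5e3 / 1825))
})

test_that("Stoll shear dispersion is exactly a Zener medium", {
  set.seed(21)
  for (p in random_biot(30)) {
    bz <- biot_to_zener(p)
    om <- log_grid(bz$omega_eps / 1e3, bz$omega_eps * 1e3, 8)
    expect_lt(rel_err(biot_shear_stoll(p, om)$E,
                      zener_modulus(bz$zener, om)), 1e-12)
    expect_gte(bz$omega_sig, bz$omega_eps)
    denom <- bz$omega_eps / bz$omega_sig
    expect_gt(denom, 0)
    expect_lt(denom, 1)
  }
})

test_that("original Biot and Stoll formulations agree", {
  set.seed(22)
  for (p in random_biot(30)) {
    we <- biot_to_zener(p)$omega_eps
    om <- log_grid(we / 1e3, we * 1e3, 8)
    ko <- biot_shear_original(p, om)$k
    ks <- biot_shear_stoll(p, om)$k
    expect_lt(rel_err(ko, ks), 1e-10)
  }
})

test_that("limits: locked fluid and vanishing fluid inertia are elastic", {
  p0 <- baseline_biot()
  om <- log_grid(1e2, 1e6, 6)
  # eta_f huge: f/f_c -> 0, lossless elastic propagation at c0
  p <- do.call(biot_medium, utils::modifyList(unclass(p0),
                                              list(eta_f = 1e9)))
  d <- biot_shear_original(p, om)
  k_el <- om * sqrt(1825 / 5e3)
  expect_lt(max(abs(Re(d$k) / k_el - 1)), 1e-10)
  expect_lt(max(d$alpha_k / Re(d$k)), 1e-10)
  # rho_f -> 0: loss terms vanish in the Stoll form
  p2 <- do.call(biot_medium, utils::modifyList(unclass(p0),
                                               list(rho_f = 1e-6)))
  d2 <- biot_shear_stoll(p2, om)
  expect_lt(max(d2$alpha_k / Re(d2$k)), 1e-12)
})

test_that("parameter validation catches unphysical media", {
  expect_error(biot_medium(0, 2650, 1000, 1, 1, 1e-3, 1e-11, 1.25, 1, 1),
               "phi")
  expect_error(biot_medium(0.5, 2650, 1000, 1, 1, 1e-3, 1e-11, 0.9, 1, 1),
               "tortuosity")
  expect_error(biot_medium(0.5, -1, 1000, 1, 1, 1e-3, 1e-11, 1.25, 1, 1),
               "positive")
})
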