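test_that("fractional modulus reduces to the classical solids", {
  om <- log_grid(1e-4, 1e4, 10)
  # alpha = 1 is exactly the Zener modulus
  fz <- fractional_zener(1, 2, 1, alpha = 1)
  expect_lt(rel_err(frac_modulus(fz, om), zener_modulus(unit_zener(), om)),
            1e-12)
  expect_equal(frac_modulus(fz, 1), 1.5 + 0.5i)
  # static limit for any order
  for (al in c(0.2, 0.7)) {
    p <- fractional_zener(3, 1, 0.01, al)
    expect_equal(frac_modulus(p, 0), 3 + 0i)
  }
})

test_that("spring-pot asymptote has phase alpha*pi/2", {
  # tau_sig = 0, omega*tau_eps >> 1: E -> (i omega eta)^alpha; the
  # relative correction is the static term 1/(omega tau)^alpha
  for (al in c(0.3, 0.5, 0.9)) {
    p <- fractional_kv(1, 1, al)
    E <- frac_modulus(p, 1e30)
    expect_equal(Arg(E), al * pi / 2, tolerance = 1e-6)
    expect_equal(Mod(E), (1e30)^al, tolerance = 1e-6)
  }
})

test_that("fractional parameters are validated", {
  expect_error(fractional_zener(1, 1, 1, 0.5), "tau_sig < tau_eps")
  expect_error(fractional_zener(1, 1, 0.1, 1.2), "alpha")
  expect_error(fractional_zener(1, 1, 0.1, 0), "alpha")
})

test_that("hysteresis modulus is frequency independent", {
  h <- hysteresis(K = 2e3, H = 150)
  E <- hysteresis_modulus(h, c(1, 1e4))
  expect_equal(E[1], E[2])
  expect_equal(E[1], 2e3 + 150i)
})

test_that("small fractional order approaches hysteresis, larger does not", {
  # loss varies as omega^alpha: over 2 decades the max/min ratio is
  # 100^alpha, so alpha = 0.01 is nearly flat and alpha = 0.3 is not
  r_small <- hysteresis_limit_check(1, 1, eps_order = 0.01, band = c(1, 100))
  expect_lt(r_small, 1.10)
  expect_equal(r_small, 100^0.01, tolerance = 1e-6)
  r_mid <- hysteresis_limit_check(1, 1, eps_order = 0.3, band = c(1, 100))
  expect_equal(r_mid, 100^0.3, tolerance = 1e-6)
  # flatter and flatter as the order shrinks
  r_tiny <- hysteresis_limit_check(1, 1, eps_order = 0.001,
                                   band = c(1, 100))
  expect_lt(r_tiny, r_small)
  expect_error(hysteresis_limit_check(1, 1, 0.01, band = c(1, 10)),
               "2 decades")
})
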