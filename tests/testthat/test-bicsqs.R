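test_that("four-parameter modulus has the stated limits", {
  m <- four_param_model(mu = 5e3, omega_mu = 1e6, omega_eps = 4e4,
                        omega_sig = 5.1e4)
  expect_equal(bicsqs_modulus(m, 0), 5e3 + 0i)
  # |E| grows linearly with frequency far above every crossover
  hi <- bicsqs_modulus(m, c(1e10, 2e10))
  expect_equal(Mod(hi[2]) / Mod(hi[1]), 2, tolerance = 1e-3)
  # omega_mu -> infinity recovers the Zener modulus
  m2 <- four_param_model(1, 1e12 * 1, 0.5, 1)
  om <- log_grid(1e-3, 1e2, 10)
  expect_lt(rel_err(bicsqs_modulus(m2, om),
                    zener_modulus(unit_zener(), om)), 1e-9)
  expect_error(four_param_model(1, 1, 2, 1), "omega_sig >= omega_eps")
})

test_that("two Kelvin units in series realize the four-parameter model", {
  m <- four_param_model(5e3, 1e6, 4e4, 5.1228e4)
  net <- fourparam_to_network(m)
  expect_identical(net$topology, "kelvin_chain")
  expect_length(net$E, 2)
  expect_true(all(net$E > 0) && all(net$eta > 0))
  om <- log_grid(1e2, 1e8, 10)
  expect_lt(rel_err(network_modulus(net, om), bicsqs_modulus(m, om)),
            1e-12)
  # static compliance conservation
  expect_equal(Mod(network_modulus(net, 0)), 5e3)
})

test_that("near-Zener parameters degenerate to the Zener conjugate", {
  # omega_mu far above the band: the omega_mu unit is almost rigid and
  # the chain modulus matches the Zener curve
  m <- four_param_model(1, 1e12, 0.5, 1)
  net <- fourparam_to_network(m)
  om <- log_grid(1e-3, 1e2, 10)
  expect_lt(rel_err(network_modulus(net, om),
                    zener_modulus(unit_zener(), om)), 1e-9)
})

test_that("non-realizable parameter sets are reported", {
  # omega_sig above omega_mu makes a partial-fraction weight negative
  m <- four_param_model(1, omega_mu = 5, omega_eps = 1, omega_sig = 10)
  expect_error(fourparam_to_network(m), "negative")
  expect_error(rheowave:::fourparam_maxwell_network(m), "omega_sig")
})

test_that("network identification inverts both realizations", {
  m <- four_param_model(5e3, 1e6, 4e4, 5.1e4)
  kel <- fourparam_to_network(m)
  m2 <- rheowave:::network_to_fourparam(kel)
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$omega_mu, m$omega_mu)
  expect_equal(m2$omega_eps, m$omega_eps)
  expect_equal(m2$omega_sig, m$omega_sig)
  mw <- rheowave:::fourparam_maxwell_network(m)
  m3 <- rheowave:::network_to_fourparam(mw)
  expect_equal(m3$omega_eps, m$omega_eps)
  expect_equal(m3$omega_mu, m$omega_mu)
})
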