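test_that("network modulus reproduces elementary impedances", {
  # pure spring, terminal damper, and the glassy limit of the Zener net
  spring <- sdnet("maxwell_wiechert", E_e = 3)
  expect_equal(network_modulus(spring, c(0, 1, 1e6)), rep(3 + 0i, 3))

  damper <- sdnet("maxwell_wiechert", E = 0, eta = 2)
  expect_equal(network_modulus(damper, 5), 10i)

  zen <- sdnet("maxwell_wiechert", E = 1, eta = 1, E_e = 1)
  expect_equal(network_modulus(zen, 1e12), 2 + 0i, tolerance = 1e-9)
  expect_equal(network_modulus(zen, 0), 1 + 0i)
})

test_that("kelvin chain modulus is the inverted compliance sum", {
  # series spring (2 Pa) + Kelvin unit: hand compliance algebra
  net <- sdnet("kelvin_chain", E = c(2, 2), eta = c(0, 4))
  om <- c(0.3, 1, 7)
  expect_equal(network_modulus(net, om),
               1 / (1 / 2 + 1 / (2 + 4i * om)))
  # every unit of zero compliance -> degenerate network
  suppressMessages(empty <- sdnet("kelvin_chain", E = 0, eta = 0))
  expect_error(network_modulus(empty, om), "degenerate")
})

test_that("network construction enforces realizability", {
  expect_error(sdnet("maxwell_wiechert", E = -1, eta = 1), "non-negative")
  expect_error(sdnet("kelvin_chain", E = 1, eta = 1, E_e = 2),
               "equilibrium spring")
  expect_error(sdnet("maxwell_wiechert", E = 1, eta = c(1, 2)),
               "same length")
  expect_message(net <- sdnet("maxwell_wiechert", E = c(1, 0),
                              eta = c(1, 0), E_e = 1),
                 "degenerate pair")
  expect_length(net$E, 1)
})

test_that("passivity holds for random valid networks", {
  set.seed(11)
  om <- log_grid(1e-3, 1e3, 4)
  for (i in 1:25) {
    topo <- sample(c("maxwell_wiechert", "kelvin_chain"), 1)
    npair <- sample(1:6, 1)
    net <- sdnet(topo, E = 10^runif(npair, -2, 2),
                 eta = 10^runif(npair, -2, 2),
                 E_e = if (topo == "maxwell_wiechert") 10^runif(1, -2, 2)
                       else 0)
    Ew <- network_modulus(net, om)
    expect_true(all(Im(Ew) >= 0))
    expect_true(all(Re(Ew) > 0))
  }
})

test_that("relaxation modulus matches the Zener closed form", {
  net <- zener_to_network(unit_zener())
  t <- c(0.1, 0.5, 1, 5, 50)
  r <- relaxation_modulus(net, t)
  # G(t) = E_e + E_e (tau_eps/tau_sig - 1) exp(-t/tau_sig) = 1 + exp(-t)
  expect_equal(r$G, 1 + exp(-t))
  expect_equal(r$G_minus, 0)
  expect_equal(r$G_e, 1)
  # fading memory: non-increasing, G(inf) = E_e
  expect_true(all(diff(r$G) <= 0))
  expect_equal(relaxation_modulus(net, 1e6)$G, 1)
})

test_that("Kelvin-Voigt relaxation is an equilibrium spring plus impulse", {
  net <- zener_to_network(kelvin_voigt(E_e = 2, eta = 3))
  r <- relaxation_modulus(net, c(0.5, 2))
  expect_equal(r$G, c(2, 2))
  expect_equal(r$G_minus, 3)
  expect_error(relaxation_modulus(net, c(0, 1)), "impulse")
  # no impulse: t = 0 is samplable and gives the glass modulus
  zn <- zener_to_network(unit_zener())
  expect_equal(relaxation_modulus(zn, 0)$G, 2)
})

test_that("kelvin-chain relaxation agrees with its conjugate maxwell form", {
  net <- conjugate_network(zener_to_network(unit_zener()))
  expect_identical(net$topology, "kelvin_chain")
  t <- c(0.2, 1, 3)
  expect_equal(relaxation_modulus(net, t)$G, 1 + exp(-t))
})
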