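test_that("exactly the seven shear parameters move the dispersion", {
  sens <- shear_sensitivity(baseline_biot())
  flagged <- sens$parameter[sens$affects]
  expect_setequal(flagged, c("phi", "rho_s", "rho_f", "eta_f", "B",
                             "tortuosity", "mu_r"))
  expect_equal(sum(sens$affects), 7)
  # the bulk moduli are exactly inert, not merely below threshold
  bulk <- sens$max_rel_dk[sens$parameter %in% c("K_s", "K_f", "K_r")]
  expect_equal(bulk, c(0, 0, 0))
  expect_error(shear_sensitivity(baseline_biot(), rel_step = 0.5),
               "rel_step")
})

test_that("viscosity and permeability enter only through their ratio", {
  p <- baseline_biot()
  raw <- unclass(p)
  raw$eta_f <- raw$eta_f * 37
  raw$B <- raw$B * 37
  p2 <- do.call(biot_medium, raw)
  om <- log_grid(1e3, 1e6, 10)
  expect_lt(rel_err(biot_shear_stoll(p2, om)$k,
                    biot_shear_stoll(p, om)$k), 1e-13)
})

test_that("the parameter reduction has rank five, four when approximated", {
  p <- baseline_biot()
  r_exact <- identifiability_rank(p)
  expect_equal(as.integer(r_exact), 5)
  r_approx <- identifiability_rank(p, model = "approximate")
  expect_equal(as.integer(r_approx), 4)
  # clear spectral gap in both cases
  for (r in list(r_exact, r_approx)) {
    d <- attr(r, "singular_values")
    expect_gt(d[as.integer(r)] / d[1], 1e-6)
    if (length(d) > as.integer(r))
      expect_lt(d[as.integer(r) + 1] / d[1], 1e-8)
  }
})

test_that("a shear-wave measurement alone identifies three functionals", {
  # k(omega) factors through (mu_r/rho, omega_eps, omega_sig): the
  # dispersion Jacobian has rank 3, and 2 with the frozen crossover
  # ratio
  p <- baseline_biot()
  expect_equal(as.integer(identifiability_rank(p,
                                               observables = "dispersion")),
               3)
  expect_equal(as.integer(identifiability_rank(p, model = "approximate",
                                               observables = "dispersion")),
               2)
})

test_that("rank estimation validates its frequency grid", {
  p <- baseline_biot()
  expect_error(identifiability_rank(p, omega = c(1, 2, 3)), "3 decades")
  expect_error(identifiability_rank(p, omega = log_omega_grid(1, 10, 50)),
               "3 decades")
})
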