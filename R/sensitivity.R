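#' Which Biot parameters affect the shear wave?
#'
#' Perturbs each of the ten Biot parameters in turn by a relative step,
#' recomputes the Stoll-form shear dispersion, and flags the parameter
#' as shear-affecting when the maximum relative wavenumber change across
#' the frequency grid exceeds a threshold.  The three bulk moduli
#' (\code{K_s}, \code{K_f}, \code{K_r}) never enter the shear branch
#' and are never flagged; the remaining seven are.
#'
#' @param p baseline [biot_medium()].
#' @param omega angular frequency grid [rad/s]; default: 61 log-spaced
#'   points over two decades either side of the Zener crossover
#'   \eqn{\omega_\epsilon}.
#' @param rel_step relative perturbation, in \code{(0, 0.2]} (default
#'   0.1).
#' @param threshold relative wavenumber change above which a parameter
#'   counts as affecting shear (default 1e-8, far above rounding, far
#'   below any physical sensitivity).
#' @return data frame of class \code{"shear_sensitivity"} with columns
#'   \code{parameter}, \code{max_rel_dk}, \code{affects}.
#' @examples
#' p <- biot_medium(0.5, 2650, 1000, 3.6e10, 2.2e9, 1e-3, 1e-11, 1.25,
#'                  5e7, 5e3)
#' shear_sensitivity(p)
#' @export
shear_sensitivity <- function(p, omega = NULL, rel_step = 0.1,
                              threshold = 1e-8) {
  stopifnot(inherits(p, "biot_params"))
  if (rel_step <= 0 || rel_step > 0.2)
    stop("`rel_step` must lie in (0, 0.2]")
  if (is.null(omega)) {
    we <- biot_to_zener(p)$omega_eps
    omega <- log_omega_grid(we / 100, we * 100, 61)
  }
  k0 <- biot_shear_stoll(p, omega)$k
  pars <- names(unclass(p))
  res <- vapply(pars, function(nm) {
    p2 <- unclass(p)
    p2[[nm]] <- p2[[nm]] * (1 + rel_step)
    p2 <- do.call(biot_medium, p2)
    k1 <- biot_shear_stoll(p2, omega)$k
    max(Mod(k1 - k0) / Mod(k0))
  }, numeric(1))
  out <- data.frame(parameter = pars, max_rel_dk = unname(res),
                    affects = unname(res) > threshold)
  class(out) <- c("shear_sensitivity", class(out))
  out
}

#' Numerical identifiability rank of the Biot shear-wave parameterization
#'
#' Counts independent parameter combinations of the Biot shear-wave
#' model by the numerical rank of a finite-difference Jacobian with
#' respect to the seven shear-affecting parameters
#' (\eqn{\phi, \rho_s, \rho_f, \eta_f, B}, tortuosity, \eqn{\mu_r}).
#' Columns are scaled by each parameter's magnitude (sensitivities to
#' \eqn{\ln} parameter), rows by the baseline observable magnitudes;
#' singular values below \code{tol} times the leading one count as
#' zero.
#'
#' Two observable sets answer two different questions:
#' \describe{
#'   \item{\code{"reduction"} (default)}{the physics-based parameter
#'     reduction: the map from the seven raw parameters to the
#'     sufficient combination vector
#'     \eqn{(\mu_r,\ \rho,\ \rho_c,\ \eta_f/B,\ \rho_f)} that fully
#'     determines the shear response.  Its rank — 5 in the exact model —
#'     verifies those combinations are functionally independent, i.e.
#'     the ten-parameter model genuinely reduces to five numbers and no
#'     fewer.  Under \code{model = "approximate"} the crossover ratio
#'     \eqn{\omega_\sigma/\omega_\epsilon = 1/(1 - \rho_f^2/(\rho\rho_c))}
#'     is held fixed (its denominator is typically above 0.8 and barely
#'     moves), \eqn{\rho_f} loses its lone role and the count drops to
#'     4 — the size of a Zener medium description.}
#'   \item{\code{"dispersion"}}{the stacked real and imaginary parts of
#'     the Stoll wavenumber \eqn{k(\omega)} over the frequency grid.
#'     Because \eqn{k^2 = (\rho/\mu_r)\,\omega^2 (1 +
#'     i\omega/\omega_\sigma)/(1 + i\omega/\omega_\epsilon)}, a
#'     shear-wave measurement alone constrains only the three
#'     functionals \eqn{\mu_r/\rho,\ \omega_\epsilon,\ \omega_\sigma}:
#'     this rank is 3 (exact) or 2 (approximate), however many
#'     parameters the medium description carries.}
#' }
#'
#' @param p baseline [biot_medium()].
#' @param omega angular frequency grid [rad/s] for the
#'   \code{"dispersion"} observables; at least 10 points spanning at
#'   least 3 decades around \eqn{\omega_\epsilon}.  Default: 40
#'   log-spaced points over \eqn{[\omega_\epsilon/100,
#'   100\,\omega_\epsilon]}.
#' @param model \code{"exact"} or \code{"approximate"} (see above).
#' @param observables \code{"reduction"} or \code{"dispersion"}.
#' @param tol relative singular-value tolerance (default 1e-6).
#' @param rel_step relative finite-difference step (default 1e-4).
#' @return integer rank, with the scaled singular values attached as
#'   attribute \code{"singular_values"}.
#' @examples
#' p <- biot_medium(0.5, 2650, 1000, 3.6e10, 2.2e9, 1e-3, 1e-11, 1.25,
#'                  5e7, 5e3)
#' identifiability_rank(p)                                    # 5
#' identifiability_rank(p, model = "approximate")             # 4
#' identifiability_rank(p, observables = "dispersion")        # 3
#' @export
identifiability_rank <- function(p, omega = NULL,
                                 model = c("exact", "approximate"),
                                 observables = c("reduction", "dispersion"),
                                 tol = 1e-6, rel_step = 1e-4) {
  stopifnot(inherits(p, "biot_params"))
  model <- match.arg(model)
  observables <- match.arg(observables)
  we <- biot_to_zener(p)$omega_eps
  if (is.null(omega)) omega <- log_omega_grid(we / 100, we * 100, 40)
  omega <- as.numeric(omega)
  if (length(omega) < 10 || max(omega) / min(omega) < 1e3)
    stop("`omega` must have >= 10 points spanning >= 3 decades")
  base <- unlist(unclass(p)[biot_shear_names])
  r0 <- with(derive_densities(p), p$rho_f^2 / (rho * rho_c))  # frozen ratio

  combos <- function(theta) {
    rho <- theta[["phi"]] * theta[["rho_f"]] +
      (1 - theta[["phi"]]) * theta[["rho_s"]]
    rho_c <- theta[["tortuosity"]] * theta[["rho_f"]] / theta[["phi"]]
    c(mu_r = theta[["mu_r"]], rho = rho, rho_c = rho_c,
      eta_over_B = theta[["eta_f"]] / theta[["B"]], rho_f = theta[["rho_f"]])
  }
  obsfun <- if (observables == "reduction") {
    function(theta) {
      cm <- combos(theta)
      if (model == "exact") cm else cm[names(cm) != "rho_f"]
    }
  } else {
    function(theta) {
      cm <- combos(theta)
      omega_eps <- cm[["eta_over_B"]] / cm[["rho_c"]]   # eta_f/(rho_c B)
      loss_frac <- if (model == "exact") {
        cm[["rho_f"]]^2 / (cm[["rho"]] * cm[["rho_c"]])
      } else r0
      z <- zener(E_e = cm[["mu_r"]], tau_eps = 1 / omega_eps,
                 tau_sig = (1 - loss_frac) / omega_eps)
      k <- dispersion(zener_modulus(z, omega), rho = cm[["rho"]],
                      omega = omega)$k
      c(Re(k), Im(k))
    }
  }

  y0 <- obsfun(base)
  scale_y <- abs(y0)
  if (observables == "dispersion") {
    # balance the two parts of each complex sample by |k|
    n <- length(omega)
    m <- sqrt(y0[1:n]^2 + y0[n + 1:n]^2)
    scale_y <- c(m, m)
  }
  J <- matrix(0, length(y0), length(base))
  for (j in seq_along(base)) {
    h <- rel_step * base[j]
    up <- base; up[j] <- up[j] + h
    dn <- base; dn[j] <- dn[j] - h
    J[, j] <- (obsfun(up) - obsfun(dn)) / (2 * h) * base[j] / scale_y
  }
  d <- svd(J, nu = 0, nv = 0)$d
  if (d[1] == 0) stop("ill-conditioned baseline: zero leading singular value")
  structure(sum(d > tol * d[1]), singular_values = d)
}
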