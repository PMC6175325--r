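#' Low-frequency Biot poroelastic medium
#'
#' The ten parameters of the low-frequency (laminar pore flow) Biot
#' model of a fluid-saturated porous solid.  Only seven of them enter
#' the shear-wave branch; the three bulk moduli are carried so that a
#' full material description validates, and their irrelevance to shear
#' is checked by [shear_sensitivity()].
#'
#' @param phi porosity, in (0, 1).
#' @param rho_s solid (grain) density [kg/m^3].
#' @param rho_f pore-fluid density [kg/m^3].
#' @param K_s solid bulk modulus [Pa].
#' @param K_f fluid bulk modulus [Pa].
#' @param eta_f fluid viscosity [Pa s].
#' @param B permeability [m^2].
#' @param tortuosity tortuosity (structure constant), >= 1.
#' @param K_r frame bulk modulus [Pa].
#' @param mu_r frame shear modulus [Pa].
#' @return object of class \code{"biot_params"}.
#' @examples
#' biot_medium(phi = 0.5, rho_s = 2650, rho_f = 1000, K_s = 3.6e10,
#'             K_f = 2.2e9, eta_f = 1e-3, B = 1e-11, tortuosity = 1.25,
#'             K_r = 5e7, mu_r = 5e3)
#' @export
biot_medium <- function(phi, rho_s, rho_f, K_s, K_f, eta_f, B,
                        tortuosity, K_r, mu_r) {
  vals <- c(phi = phi, rho_s = rho_s, rho_f = rho_f, K_s = K_s, K_f = K_f,
            eta_f = eta_f, B = B, tortuosity = tortuosity, K_r = K_r,
            mu_r = mu_r)
  if (any(!is.finite(vals))) stop("all Biot parameters must be finite")
  if (phi <= 0 || phi >= 1) stop("`phi` must lie strictly in (0, 1)")
  if (tortuosity < 1) stop("`tortuosity` must be >= 1")
  if (any(vals[c("rho_s", "rho_f", "K_s", "K_f", "eta_f", "B", "K_r",
                 "mu_r")] <= 0))
    stop("densities, moduli, viscosity and permeability must be positive")
  structure(as.list(vals), class = "biot_params")
}

#' @export
print.biot_params <- function(x, ...) {
  cat("Low-frequency Biot medium\n")
  cat(sprintf("  phi = %g, rho_s = %g, rho_f = %g kg/m^3\n",
              x$phi, x$rho_s, x$rho_f))
  cat(sprintf("  K_s = %g, K_f = %g, K_r = %g, mu_r = %g Pa\n",
              x$K_s, x$K_f, x$K_r, x$mu_r))
  cat(sprintf("  eta_f = %g Pa s, B = %g m^2, tortuosity = %g\n",
              x$eta_f, x$B, x$tortuosity))
  invisible(x)
}

biot_shear_names <- c("phi", "rho_s", "rho_f", "eta_f", "B", "tortuosity",
                      "mu_r")

#' Effective densities and characteristic frequencies of a Biot medium
#'
#' Computes the aggregate density \eqn{\rho = \phi\rho_f +
#' (1-\phi)\rho_s}, the effective (mass-coupling) densities and their
#' normalized counterparts \eqn{\gamma_{ij} = \rho_{ij}/\rho}, the
#' Darcy friction coefficient \eqn{b = \eta_f \phi^2/B}, and the two
#' characteristic frequencies
#' \deqn{f_c = \frac{b}{2\pi(\rho_{12}+\rho_{22})}, \qquad
#'       f_c' = f_c\,\frac{\gamma_{12}+\gamma_{22}}{\gamma_{22}}
#'            = \frac{\eta_f \phi}{2\pi B\, \alpha_t\, \rho_f},}
#' where \eqn{\alpha_t} is the tortuosity.  The mass-coupling closure
#' used is \eqn{\rho_{22} = \alpha_t\,\phi\,\rho_f},
#' \eqn{\rho_{12} = \phi\rho_f - \rho_{22} \le 0} and
#' \eqn{\rho_{11} = (1-\phi)\rho_s - \rho_{12}}.  The Stoll-form mass
#' coupling density is \eqn{\rho_c = \alpha_t\,\rho_f/\phi}; \eqn{f_c'}
#' equals \eqn{\omega_\epsilon/(2\pi)} of the Zener equivalent.
#'
#' @param p a [biot_medium()].
#' @return object of class \code{"biot_densities"}: list with
#'   \code{rho}, \code{rho_11}, \code{rho_12}, \code{rho_22},
#'   \code{gamma_11}, \code{gamma_12}, \code{gamma_22}, \code{rho_c},
#'   \code{b_fric}, \code{f_c}, \code{f_c_prime}.
#' @examples
#' p <- biot_medium(0.5, 2650, 1000, 3.6e10, 2.2e9, 1e-3, 1e-11, 1.25,
#'                  5e7, 5e3)
#' derive_densities(p)
#' @export
derive_densities <- function(p) {
  stopifnot(inherits(p, "biot_params"))
  if (p$phi < 1e-12) stop("phi -> 0: mass coupling density diverges")
  rho <- p$phi * p$rho_f + (1 - p$phi) * p$rho_s
  rho_22 <- p$tortuosity * p$phi * p$rho_f
  rho_12 <- p$phi * p$rho_f - rho_22
  rho_11 <- (1 - p$phi) * p$rho_s - rho_12
  b_fric <- p$eta_f * p$phi^2 / p$B
  f_c <- b_fric / (2 * pi * (rho_12 + rho_22))
  f_c_prime <- p$eta_f * p$phi / (2 * pi * p$B * p$tortuosity * p$rho_f)
  structure(list(rho = rho, rho_11 = rho_11, rho_12 = rho_12,
                 rho_22 = rho_22,
                 gamma_11 = rho_11 / rho, gamma_12 = rho_12 / rho,
                 gamma_22 = rho_22 / rho,
                 rho_c = p$tortuosity * p$rho_f / p$phi,
                 b_fric = b_fric, f_c = f_c, f_c_prime = f_c_prime),
            class = "biot_densities")
}

#' @export
print.biot_densities <- function(x, ...) {
  cat("Biot effective densities\n")
  cat(sprintf("  rho = %g, rho_11 = %g, rho_12 = %g, rho_22 = %g kg/m^3\n",
              x$rho, x$rho_11, x$rho_12, x$rho_22))
  cat(sprintf("  rho_c = %g kg/m^3, b = %g Pa s/m^2\n", x$rho_c, x$b_fric))
  cat(sprintf("  f_c = %g Hz, f_c' = %g Hz\n", x$f_c, x$f_c_prime))
  invisible(x)
}

#' Shear-wave dispersion of the Biot medium (original formulation)
#'
#' The shear branch of the original Biot equations:
#' \eqn{(k/\omega)^2 = \rho\,(\kappa_r - i\kappa_i)} with
#' \deqn{\kappa_r = \frac{1}{\mu_r}\,
#'   \frac{1 + \dfrac{\gamma_{22}(\gamma_{11}\gamma_{22} -
#'         \gamma_{12}^2)}{(\gamma_{12}+\gamma_{22})^2}\,(f/f_c)^2}
#'        {1 + \dfrac{\gamma_{22}^2}{(\gamma_{12}+\gamma_{22})^2}\,
#'         (f/f_c)^2},
#'   \qquad
#'   \kappa_i = \frac{1}{\mu_r}\,
#'   \frac{(\gamma_{12}+\gamma_{22})\, f/f_c}
#'        {1 + \dfrac{\gamma_{22}^2}{(\gamma_{12}+\gamma_{22})^2}\,
#'         (f/f_c)^2},}
#' written in the \eqn{e^{+i\omega t}} convention (the compliance loss
#' term carries \eqn{-i}, so \eqn{\mathrm{Im}\,E \ge 0}).  Valid in the
#' low-frequency (laminar Darcy flow) regime.  Under the mass-coupling
#' closure of [derive_densities()] this agrees with the Stoll form
#' [biot_shear_stoll()] to rounding error.
#'
#' @param p a [biot_medium()].
#' @param omega angular frequencies [rad/s].
#' @return a [dispersion()] curve.
#' @export
biot_shear_original <- function(p, omega) {
  stopifnot(inherits(p, "biot_params"))
  omega <- as.numeric(omega)
  d <- derive_densities(p)
  Fr <- omega / (2 * pi * d$f_c)           # f/f_c
  g12p22 <- d$gamma_12 + d$gamma_22
  cr <- d$gamma_22 * (d$gamma_11 * d$gamma_22 - d$gamma_12^2) / g12p22^2
  cd <- (d$gamma_22 / g12p22)^2
  kappa_r <- (1 + cr * Fr^2) / (1 + cd * Fr^2) / p$mu_r
  kappa_i <- g12p22 * Fr / (1 + cd * Fr^2) / p$mu_r
  E <- 1 / (kappa_r - 1i * kappa_i)
  dispersion(E, rho = d$rho, omega = omega)
}

#' Shear-wave dispersion of the Biot medium (Stoll formulation)
#'
#' The low-frequency Biot shear dispersion written in terms of the
#' mass-coupling density \eqn{\rho_c = \alpha_t \rho_f/\phi}:
#' \deqn{\left(\frac{k}{\omega}\right)^2 = \frac{\rho}{\mu_r}\,
#'   \frac{1 + i\omega\,(\rho_c - \rho_f^2/\rho)\,B/\eta_f}
#'        {1 + i\omega\,\rho_c\, B/\eta_f},}
#' i.e. the dynamic modulus
#' \eqn{E(\omega) = \mu_r (1 + i\omega \rho_c B/\eta_f)/(1 +
#' i\omega(\rho_c - \rho_f^2/\rho) B/\eta_f)} — a Zener modulus (see
#' [biot_to_zener()]).
#'
#' @inheritParams biot_shear_original
#' @return a [dispersion()] curve.
#' @export
biot_shear_stoll <- function(p, omega) {
  stopifnot(inherits(p, "biot_params"))
  omega <- as.numeric(omega)
  d <- derive_densities(p)
  Boe <- p$B / p$eta_f
  num <- 1 + 1i * omega * d$rho_c * Boe
  den <- 1 + 1i * omega * (d$rho_c - p$rho_f^2 / d$rho) * Boe
  E <- p$mu_r * num / den
  dispersion(E, rho = d$rho, omega = omega)
}

#' Exact Zener equivalent of the Biot shear wave
#'
#' The Biot shear-wave modulus is identically a Zener modulus with
#' \deqn{E_e = \mu_r, \quad
#'       \omega_\epsilon = \frac{\eta_f}{\rho_c B}, \quad
#'       \omega_\sigma = \frac{\omega_\epsilon}
#'         {1 - \rho_f^2/(\rho\,\rho_c)} \ge \omega_\epsilon, \quad
#'       c_0^2 = \mu_r/\rho,}
#' where \eqn{\omega_\epsilon = 1/\tau_\epsilon} and
#' \eqn{\omega_\sigma = 1/\tau_\sigma}.  The identity is exact: the
#' Stoll-form modulus and [zener_modulus()] with these parameters are
#' the same rational function of frequency.
#'
#' @param p a [biot_medium()].
#' @return list with elements \code{zener} (a [zener()] object),
#'   \code{rho} (aggregate density, for [dispersion()]),
#'   \code{omega_eps}, \code{omega_sig}, \code{c0}.
#' @examples
#' p <- biot_medium(0.5, 2650, 1000, 3.6e10, 2.2e9, 1e-3, 1e-11, 1.25,
#'                  5e7, 5e3)
#' biot_to_zener(p)$omega_eps   # 4e4 rad/s
#' @export
biot_to_zener <- function(p) {
  stopifnot(inherits(p, "biot_params"))
  d <- derive_densities(p)
  loss_frac <- p$rho_f^2 / (d$rho * d$rho_c)
  if (loss_frac >= 1)
    stop("invalid medium: rho_f^2/(rho * rho_c) >= 1")
  omega_eps <- p$eta_f / (d$rho_c * p$B)
  omega_sig <- omega_eps / (1 - loss_frac)
  z <- zener(E_e = p$mu_r, tau_eps = 1 / omega_eps, tau_sig = 1 / omega_sig)
  list(zener = z, rho = d$rho, omega_eps = omega_eps,
       omega_sig = omega_sig, c0 = sqrt(p$mu_r / d$rho))
}

#' Sample physically plausible Biot media
#'
#' Draws random parameter sets inside soft-tissue/sediment-like ranges
#' (porosity 0.2-0.8, tortuosity 1-3, log-uniform viscosity,
#' permeability and frame shear modulus) for property sweeps and
#' validation.  Uses the current RNG state; set a seed for
#' reproducibility.
#'
#' @param n number of media to draw.
#' @return list of [biot_medium()] objects.
#' @export
random_biot <- function(n) {
  lapply(seq_len(n), function(i) {
    biot_medium(phi = stats::runif(1, 0.2, 0.8),
                rho_s = stats::runif(1, 1500, 3000),
                rho_f = stats::runif(1, 800, 1200),
                K_s = 10^stats::runif(1, 9, 11),
                K_f = 10^stats::runif(1, 8.5, 9.5),
                eta_f = 10^stats::runif(1, -3.5, -2),
                B = 10^stats::runif(1, -13, -9),
                tortuosity = stats::runif(1, 1, 3),
                K_r = 10^stats::runif(1, 6, 8),
                mu_r = 10^stats::runif(1, 3, 5))
  })
}
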