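#' Shear-wave dispersion curve from a dynamic modulus
#'
#' Converts a complex dynamic modulus into a plane shear-wave dispersion
#' curve through
#' \deqn{\left(\frac{k}{\omega}\right)^2 = \frac{\rho}{E(\omega)},}
#' taking the principal complex square root and enforcing
#' \eqn{\mathrm{Re}(k) > 0} (outgoing wave).  With the
#' \eqn{e^{+i\omega t}} convention a passive modulus has
#' \eqn{\mathrm{Im}(E) \ge 0} and the wavenumber's imaginary part is
#' non-positive; attenuation is reported as \eqn{|\mathrm{Im}(k)|}
#' [Np/m] so no sign convention leaks into the output.
#'
#' @param E complex dynamic modulus at each frequency [Pa];
#'   \code{Re(E) > 0} required.
#' @param rho mass density [kg/m^3], > 0.
#' @param omega angular frequencies [rad/s], non-negative, same length
#'   as \code{E}.
#' @return A data frame of class \code{"dispersion_curve"} with columns
#'   \code{omega}, \code{E} (complex), \code{k} (complex wavenumber,
#'   1/m), \code{c_p} (phase velocity \eqn{\omega/\mathrm{Re}(k)}, m/s)
#'   and \code{alpha_k} (attenuation, Np/m), plus attribute \code{rho}.
#'   At \eqn{\omega = 0} the phase velocity is the static limit
#'   \eqn{\sqrt{E(0)/\rho}}.
#' @examples
#' om <- 2 * pi * 10^seq(0, 3, 0.25)
#' E <- zener_modulus(zener(5e3, 2e-3, 1e-3), om)
#' disp <- dispersion(E, rho = 1000, omega = om)
#' head(disp)
#' @export
dispersion <- function(E, rho, omega) {
  omega <- as.numeric(omega)
  E <- as.complex(E)
  if (length(E) != length(omega))
    stop("`E` and `omega` must have the same length")
  if (!is.finite(rho) || rho <= 0) stop("`rho` must be positive")
  if (any(omega < 0)) stop("`omega` must be non-negative")
  if (any(Re(E) <= 0))
    stop("dynamic modulus must have positive real part at every frequency")
  k <- omega * sqrt(rho / E)
  k[Re(k) < 0] <- -k[Re(k) < 0]
  c_p <- ifelse(omega > 0, omega / Re(k), sqrt(Re(E) / rho))
  out <- data.frame(omega = omega, E = E, k = k,
                    c_p = c_p, alpha_k = abs(Im(k)))
  attr(out, "rho") <- rho
  class(out) <- c("dispersion_curve", class(out))
  out
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat("Shear-wave dispersion curve (", nrow(x), " frequencies, rho = ",
      attr(x, "rho"), " kg/m^3)\n", sep = "")
  NextMethod()
}

#' Logarithmic angular-frequency grid
#'
#' @param omega_min,omega_max band edges [rad/s], both > 0.
#' @param n number of points (log-uniform, inclusive).
#' @return numeric vector of angular frequencies.
#' @export
log_omega_grid <- function(omega_min, omega_max, n = 200) {
  stopifnot(omega_min > 0, omega_max > omega_min, n >= 2)
  10^seq(log10(omega_min), log10(omega_max), length.out = n)
}
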