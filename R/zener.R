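#' Zener (standard linear solid) and Kelvin-Voigt parameters
#'
#' The Zener solid is parameterized by its equilibrium modulus
#' \eqn{E_e} [Pa] and two time constants: the strain relaxation time
#' \eqn{\tau_\epsilon} and the stress relaxation time
#' \eqn{\tau_\sigma}, with \eqn{0 \le \tau_\sigma \le \tau_\epsilon}.
#' \eqn{\tau_\sigma = 0} degenerates to the Kelvin-Voigt solid (spring
#' and damper in parallel).
#'
#' In terms of the three-element spring-damper realization (equilibrium
#' spring \eqn{E_e} in parallel with a Maxwell arm of spring \eqn{E}
#' and damper \eqn{\eta}):
#' \deqn{\tau_\sigma = \eta/E \le \tau_\epsilon = \eta/E', \qquad
#'       1/E' = 1/E_e + 1/E.}
#'
#' @param E_e equilibrium modulus [Pa], > 0.
#' @param tau_eps strain relaxation time \eqn{\tau_\epsilon} [s], > 0.
#' @param tau_sig stress relaxation time \eqn{\tau_\sigma} [s], in
#'   \code{[0, tau_eps]}.
#' @return object of class \code{"zener_params"}.
#' @examples
#' zener(E_e = 1, tau_eps = 2, tau_sig = 1)
#' @export
zener <- function(E_e, tau_eps, tau_sig) {
  stopifnot(is.finite(E_e), E_e > 0, is.finite(tau_eps), tau_eps > 0,
            is.finite(tau_sig), tau_sig >= 0)
  if (tau_sig > tau_eps)
    stop("Zener ordering violated: need tau_sig <= tau_eps")
  structure(list(E_e = E_e, tau_eps = tau_eps, tau_sig = tau_sig),
            class = "zener_params")
}

#' @rdname zener
#' @param eta damper viscosity [Pa s] of the Kelvin-Voigt solid.
#' @export
kelvin_voigt <- function(E_e, eta) {
  stopifnot(is.finite(eta), eta >= 0, E_e > 0)
  zener(E_e = E_e, tau_eps = eta / E_e, tau_sig = 0)
}

#' @export
print.zener_params <- function(x, ...) {
  kind <- if (x$tau_sig == 0) "Kelvin-Voigt" else "Zener"
  cat(kind, "parameters\n")
  cat("  E_e     =", format(x$E_e), "Pa\n")
  cat("  tau_eps =", format(x$tau_eps), "s\n")
  cat("  tau_sig =", format(x$tau_sig), "s\n")
  if (x$tau_sig > 0)
    cat("  E(inf)  =", format(x$E_e * x$tau_eps / x$tau_sig), "Pa\n")
  invisible(x)
}

#' Dynamic modulus of the Zener / Kelvin-Voigt solid
#'
#' \deqn{E(\omega) = E_e \frac{1 + i\omega\tau_\epsilon}
#'                            {1 + i\omega\tau_\sigma},}
#' which for \eqn{\tau_\sigma = 0} reduces to the Kelvin-Voigt modulus
#' \eqn{E_e(1 + i\omega\tau_\epsilon) = E_e + i\omega\eta}.
#'
#' @param p a [zener()] parameter object.
#' @param omega angular frequencies [rad/s], non-negative.
#' @return complex vector.
#' @examples
#' zener_modulus(zener(1, 2, 1), c(0, 1, 1e6))
#' @export
zener_modulus <- function(p, omega) {
  stopifnot(inherits(p, "zener_params"))
  omega <- as.numeric(omega)
  if (any(omega < 0)) stop("`omega` must be non-negative")
  p$E_e * (1 + 1i * omega * p$tau_eps) / (1 + 1i * omega * p$tau_sig)
}

#' Convert Zener parameters to their three-element network
#'
#' Inverts the time-constant map: \eqn{\eta = E_e(\tau_\epsilon -
#' \tau_\sigma)}, \eqn{E = \eta/\tau_\sigma}.  For
#' \eqn{\tau_\sigma = 0} the Maxwell-arm spring is infinitely stiff and
#' the arm degenerates to a terminal damper (Kelvin-Voigt).
#' \eqn{\tau_\sigma = \tau_\epsilon} leaves a zero damper, i.e. a purely
#' elastic medium, and is rejected.
#'
#' @param p a [zener()] parameter object with \code{tau_sig < tau_eps}.
#' @return a Maxwell-Wiechert [sdnet()].
#' @examples
#' zener_to_network(zener(1, 2, 1))
#' @export
zener_to_network <- function(p) {
  stopifnot(inherits(p, "zener_params"))
  if (p$tau_sig == p$tau_eps)
    stop("tau_sig = tau_eps gives a purely elastic (zero-damper) degenerate network")
  eta <- p$E_e * (p$tau_eps - p$tau_sig)
  if (p$tau_sig == 0)
    return(sdnet("maxwell_wiechert", E = 0, eta = eta, E_e = p$E_e))
  sdnet("maxwell_wiechert", E = eta / p$tau_sig, eta = eta, E_e = p$E_e)
}

#' Recover Zener parameters from a three-element network
#'
#' Accepts either realization of the Zener/Kelvin-Voigt solid: the
#' Maxwell-Wiechert form (equilibrium spring plus one Maxwell arm or
#' terminal damper) or the Kelvin form (series glass spring plus one
#' Kelvin unit, or a single Kelvin unit).  Round trip with
#' [zener_to_network()] is the identity on the valid domain.
#'
#' @param net an [sdnet()] of Zener/Kelvin-Voigt topology.
#' @return a [zener()] parameter object.
#' @export
network_to_zener <- function(net) {
  stopifnot(inherits(net, "sdnet"))
  if (net$topology == "kelvin_chain") net <- conjugate_network(net)
  if (length(net$E) != 1 || net$E_e <= 0)
    stop("not a Zener/Kelvin-Voigt topology (need equilibrium spring + one arm)")
  eta <- net$eta[1]
  if (eta == 0) stop("arm damper is zero: purely elastic, no Zener parameters")
  if (net$E[1] == 0)                      # Kelvin-Voigt
    return(zener(net$E_e, tau_eps = eta / net$E_e, tau_sig = 0))
  tau_sig <- eta / net$E[1]
  tau_eps <- eta * (1 / net$E_e + 1 / net$E[1])
  zener(net$E_e, tau_eps = tau_eps, tau_sig = tau_sig)
}

#' Rational dynamic modulus
#'
#' The frequency-domain form of a linear stress-strain differential
#' equation with constant coefficients:
#' \deqn{E(\omega) = \frac{E_e + \sum_{k=1}^q b_k (i\omega)^k}
#'                        {1 + \sum_{k=1}^p a_k (i\omega)^k},}
#' stored as real coefficient vectors.  \code{b_coeffs[1]} is the static
#' modulus \eqn{E_e = E(0)}; the denominator's leading 1 is implicit.
#'
#' @param b_coeffs numerator coefficients \eqn{b_0 \dots b_q}
#'   [Pa s^k]; \code{b_coeffs[1]} = \eqn{E_e}.
#' @param a_coeffs denominator coefficients \eqn{a_1 \dots a_p} [s^k]
#'   (may be empty).
#' @return object of class \code{"rational_modulus"}.
#' @examples
#' # unit Zener (E_e = 1, tau_eps = 2, tau_sig = 1)
#' rm <- rational_modulus(b_coeffs = c(1, 2), a_coeffs = 1)
#' eval_modulus(rm, c(0, 1))
#' @export
rational_modulus <- function(b_coeffs, a_coeffs = numeric()) {
  b_coeffs <- as.numeric(b_coeffs)
  a_coeffs <- as.numeric(a_coeffs)
  if (length(b_coeffs) < 1 || any(!is.finite(b_coeffs)) || any(!is.finite(a_coeffs)))
    stop("coefficients must be finite and include b_0")
  structure(list(b_coeffs = b_coeffs, a_coeffs = a_coeffs),
            class = "rational_modulus")
}

#' @rdname rational_modulus
#' @param rm a \code{rational_modulus} object.
#' @param omega angular frequencies [rad/s].
#' @export
eval_modulus <- function(rm, omega) {
  stopifnot(inherits(rm, "rational_modulus"))
  omega <- as.numeric(omega)
  iw <- 1i * omega
  num <- rep(complex(real = rm$b_coeffs[1]), length(omega))
  for (k in seq_along(rm$b_coeffs)[-1])
    num <- num + rm$b_coeffs[k] * iw^(k - 1)
  den <- rep(complex(real = 1), length(omega))
  for (k in seq_along(rm$a_coeffs))
    den <- den + rm$a_coeffs[k] * iw^k
  num / den
}
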