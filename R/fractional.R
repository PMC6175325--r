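#' Fractional Zener / Kelvin-Voigt parameters
#'
#' Replaces the first-order stress/strain derivatives of the Zener
#' constitutive law by fractional derivatives of order
#' \eqn{\alpha \in (0, 1]}.  \eqn{\alpha = 1} recovers the classical
#' Zener solid exactly; \eqn{\tau_\sigma = 0} gives the fractional
#' Kelvin-Voigt solid, whose loss element is a spring-pot with modulus
#' \eqn{\propto (i\omega)^\alpha}.
#'
#' @param E_e equilibrium modulus [Pa], > 0.
#' @param tau_eps strain relaxation time [s], > 0.
#' @param tau_sig stress relaxation time [s], in \code{[0, tau_eps)}.
#' @param alpha fractional order, in \code{(0, 1]}.
#' @return object of class \code{"frac_params"}.
#' @examples
#' fractional_zener(1, 1, 1e-3, alpha = 0.8)
#' fractional_kv(1, 1, alpha = 0.3)
#' @export
fractional_zener <- function(E_e, tau_eps, tau_sig, alpha) {
  stopifnot(is.finite(E_e), E_e > 0, is.finite(tau_eps), tau_eps > 0,
            is.finite(tau_sig), tau_sig >= 0,
            is.finite(alpha), alpha > 0, alpha <= 1)
  if (tau_sig >= tau_eps)
    stop("need tau_sig < tau_eps")
  structure(list(E_e = E_e, tau_eps = tau_eps, tau_sig = tau_sig,
                 alpha = alpha),
            class = "frac_params")
}

#' @rdname fractional_zener
#' @export
fractional_kv <- function(E_e, tau_eps, alpha) {
  fractional_zener(E_e, tau_eps, tau_sig = 0, alpha = alpha)
}

#' @export
print.frac_params <- function(x, ...) {
  kind <- if (x$tau_sig == 0) "fractional Kelvin-Voigt" else "fractional Zener"
  cat(kind, "parameters\n")
  cat("  E_e     =", format(x$E_e), "Pa\n")
  cat("  tau_eps =", format(x$tau_eps), "s\n")
  cat("  tau_sig =", format(x$tau_sig), "s\n")
  cat("  alpha   =", format(x$alpha), "\n")
  invisible(x)
}

#' Dynamic modulus of the fractional Zener / Kelvin-Voigt solid
#'
#' \deqn{E(\omega) = E_e \frac{1 + (i\omega\tau_\epsilon)^\alpha}
#'                            {1 + (i\omega\tau_\sigma)^\alpha},}
#' with the principal branch
#' \eqn{(i\omega\tau)^\alpha = (\omega\tau)^\alpha e^{i\alpha\pi/2}}
#' for \eqn{\omega \ge 0}.  \eqn{\tau_\sigma = 0} reduces the
#' denominator to 1 (fractional Kelvin-Voigt); at large
#' \eqn{\omega\tau_\epsilon} that modulus approaches
#' \eqn{(i\omega\eta)^\alpha} with phase \eqn{\alpha\pi/2}.
#'
#' @param p a [fractional_zener()] parameter object.
#' @param omega angular frequencies [rad/s], non-negative.
#' @return complex vector.
#' @export
frac_modulus <- function(p, omega) {
  stopifnot(inherits(p, "frac_params"))
  omega <- as.numeric(omega)
  if (any(omega < 0)) stop("`omega` must be non-negative")
  rot <- complex(modulus = 1, argument = p$alpha * pi / 2)
  num <- 1 + (omega * p$tau_eps)^p$alpha * rot
  den <- 1 + (omega * p$tau_sig)^p$alpha * rot
  p$E_e * num / den
}

#' Hysteretic (structural damping) modulus
#'
#' The idealized frequency-independent loss model
#' \eqn{E(\omega) = K + iH}: constant storage \eqn{K} and constant loss
#' \eqn{H} at every frequency.  It coincides with the
#' \eqn{\alpha \to 0^+} limit of the fractional Kelvin-Voigt modulus,
#' whose loss varies only as \eqn{\omega^\alpha} across a band;
#' [hysteresis_limit_check()] quantifies how flat that loss actually is
#' for a small order.
#'
#' @param K storage constant [Pa], > 0.
#' @param H loss constant [Pa], >= 0.
#' @return object of class \code{"hysteresis_modulus_params"}.
#' @export
hysteresis <- function(K, H) {
  stopifnot(is.finite(K), K > 0, is.finite(H), H >= 0)
  structure(list(K = K, H = H), class = "hysteresis_modulus_params")
}

#' @rdname hysteresis
#' @param h a [hysteresis()] object.
#' @param omega angular frequencies [rad/s] (values are ignored beyond
#'   their length: the modulus is frequency independent).
#' @export
hysteresis_modulus <- function(h, omega) {
  stopifnot(inherits(h, "hysteresis_modulus_params"))
  rep(complex(real = h$K, imaginary = h$H), length(omega))
}

#' How close is a small-order fractional Kelvin-Voigt loss to hysteresis?
#'
#' Evaluates the fractional Kelvin-Voigt modulus with order
#' \code{eps_order} over a frequency band and returns the ratio
#' \eqn{\max \mathrm{Im}(E) / \min \mathrm{Im}(E)}.  Since the loss
#' varies as \eqn{\omega^\alpha}, the ratio equals
#' (band width)^\code{eps_order} and approaches 1 (frequency-independent
#' loss, i.e. hysteresis) as the order tends to 0.
#'
#' @param E_e equilibrium modulus [Pa].
#' @param tau_eps time constant [s].
#' @param eps_order small fractional order, in \code{(0, 0.05]} for the
#'   hysteresis regime (larger values are allowed and simply report an
#'   honest, larger ratio).
#' @param band length-2 angular frequency band [rad/s], spanning at
#'   least 2 decades.
#' @param n number of evaluation points across the band.
#' @return the max/min loss ratio (>= 1).
#' @examples
#' hysteresis_limit_check(1, 1, eps_order = 0.01, band = c(1, 100))
#' @export
hysteresis_limit_check <- function(E_e, tau_eps, eps_order, band, n = 200) {
  stopifnot(eps_order > 0, length(band) == 2, all(band > 0))
  band <- sort(band)
  if (band[2] / band[1] < 100)
    stop("`band` must span at least 2 decades")
  om <- log_omega_grid(band[1], band[2], n)
  p <- fractional_kv(E_e, tau_eps, alpha = eps_order)
  loss <- Im(frac_modulus(p, om))
  max(loss) / min(loss)
}
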