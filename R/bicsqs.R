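#' Non-standard four-parameter (BICSQS shear) model
#'
#' Extending the Biot frame with a relaxing shear modulus
#' \eqn{\mu' = \mu(1 + i\omega/\omega_\mu)} (squirt flow and viscous
#' drag, "BICSQS") turns the Zener shear equivalent into the
#' non-standard four-parameter model
#' \deqn{E(\omega) = \mu\,\frac{(1 + i\omega/\omega_\mu)
#'       (1 + i\omega/\omega_\epsilon)}{1 + i\omega/\omega_\sigma},}
#' with \eqn{E(0) = \mu} and \eqn{|E| \to \infty} (linearly in
#' \eqn{\omega}) at high frequency.  As \eqn{\omega_\mu \to \infty} the
#' Zener modulus is recovered.
#'
#' @param mu static shear modulus [Pa], > 0.
#' @param omega_mu frame-relaxation angular frequency [rad/s], > 0.
#' @param omega_eps,omega_sig Zener crossover angular frequencies
#'   [rad/s], \code{omega_sig >= omega_eps > 0}.
#' @return object of class \code{"fourparam_model"}.
#' @examples
#' four_param_model(mu = 5e3, omega_mu = 1e6, omega_eps = 4e4,
#'                  omega_sig = 5.1e4)
#' @export
four_param_model <- function(mu, omega_mu, omega_eps, omega_sig) {
  vals <- c(mu = mu, omega_mu = omega_mu, omega_eps = omega_eps,
            omega_sig = omega_sig)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all four parameters must be positive and finite")
  if (omega_sig < omega_eps)
    stop("need omega_sig >= omega_eps (Zener ordering)")
  structure(as.list(vals), class = "fourparam_model")
}

#' @export
print.fourparam_model <- function(x, ...) {
  cat("Non-standard four-parameter (BICSQS shear) model\n")
  cat(sprintf("  mu = %g Pa; omega_mu = %g, omega_eps = %g, omega_sig = %g rad/s\n",
              x$mu, x$omega_mu, x$omega_eps, x$omega_sig))
  invisible(x)
}

#' @rdname four_param_model
#' @param m a \code{fourparam_model}.
#' @param omega angular frequencies [rad/s], non-negative.
#' @export
bicsqs_modulus <- function(m, omega) {
  stopifnot(inherits(m, "fourparam_model"))
  omega <- as.numeric(omega)
  if (any(omega < 0)) stop("`omega` must be non-negative")
  m$mu * (1 + 1i * omega / m$omega_mu) * (1 + 1i * omega / m$omega_eps) /
    (1 + 1i * omega / m$omega_sig)
}

#' Kelvin-chain realization of the four-parameter model
#'
#' Expands the compliance \eqn{1/E(\omega)} of the four-parameter model
#' into partial fractions over its two poles \eqn{\omega_\mu},
#' \eqn{\omega_\epsilon}:
#' \deqn{\frac{1}{E} = \frac{A}{1 + i\omega/\omega_\mu}
#'                   + \frac{C}{1 + i\omega/\omega_\epsilon},
#'   \quad A = \frac{1 - \omega_\mu/\omega_\sigma}
#'                  {\mu(1 - \omega_\mu/\omega_\epsilon)},
#'   \quad C = \frac{1 - \omega_\epsilon/\omega_\sigma}
#'                  {\mu(1 - \omega_\epsilon/\omega_\mu)}.}
#' Each non-negative term is one Kelvin-Voigt unit (spring \eqn{1/A},
#' damper \eqn{1/(A\omega_\mu)}), giving two Kelvin units in series —
#' no lone series spring, because the glass compliance is zero.  A
#' negative weight means the parameters are not realizable as a passive
#' two-unit chain and is reported as an error.
#'
#' The conjugate Maxwell-Wiechert realization (equilibrium spring
#' \eqn{\mu}, one Maxwell arm, one terminal damper) is produced by
#' [conjugate_network()] on the returned chain; it exists when
#' \eqn{\omega_\epsilon \le \omega_\sigma \le \omega_\mu}.
#'
#' @param m a [four_param_model()] with
#'   \code{omega_mu != omega_eps}.
#' @return a Kelvin-chain [sdnet()] with two units.
#' @examples
#' m <- four_param_model(5e3, 1e6, 4e4, 5.1e4)
#' net <- fourparam_to_network(m)
#' om <- 10^seq(2, 7, 0.5)
#' max(Mod(network_modulus(net, om) / bicsqs_modulus(m, om) - 1))
#' @export
fourparam_to_network <- function(m) {
  stopifnot(inherits(m, "fourparam_model"))
  if (m$omega_mu == m$omega_eps)
    stop("omega_mu = omega_eps is a double pole; not supported")
  A <- (1 - m$omega_mu / m$omega_sig) / (m$mu * (1 - m$omega_mu / m$omega_eps))
  C <- (1 - m$omega_eps / m$omega_sig) / (m$mu * (1 - m$omega_eps / m$omega_mu))
  if (A < 0 || C < 0)
    stop(sprintf(paste0("non-realizable parameters: partial-fraction ",
                        "weight %s = %.6g is negative"),
                 if (A < 0) "A (omega_mu pole)" else "C (omega_eps pole)",
                 min(A, C)))
  sdnet("kelvin_chain",
        E = c(1 / A, 1 / C),
        eta = c(1 / (A * m$omega_mu), 1 / (C * m$omega_eps)))
}

# Maxwell-Wiechert realization: E(s) = mu + E1 * s tau1 / (1 + s tau1)
# + s eta_d, with tau1 = 1/omega_sig.  Exists for
# omega_eps <= omega_sig <= omega_mu.
fourparam_maxwell_network <- function(m) {
  stopifnot(inherits(m, "fourparam_model"))
  eta_d <- m$mu * m$omega_sig / (m$omega_mu * m$omega_eps)
  E1 <- m$mu * (m$omega_sig / m$omega_eps - 1) * (1 - m$omega_sig / m$omega_mu)
  if (E1 < 0)
    stop("non-realizable as Maxwell-Wiechert form: need omega_sig <= omega_mu")
  if (E1 == 0)   # omega_sig == omega_eps: pure Kelvin-Voigt + damper
    return(sdnet("maxwell_wiechert", E = 0, eta = eta_d, E_e = m$mu))
  sdnet("maxwell_wiechert", E = c(E1, 0),
        eta = c(E1 / m$omega_sig, eta_d), E_e = m$mu)
}

# Identify the four-parameter model realized by a 4-element network in
# either topology.
network_to_fourparam <- function(net) {
  stopifnot(inherits(net, "sdnet"))
  if (net$topology == "kelvin_chain") {
    units <- which(net$E > 0 & net$eta > 0)
    if (length(units) != 2 || length(net$E) != 2)
      stop("not a two-Kelvin-unit chain")
    J <- 1 / net$E[units]
    tau <- net$eta[units] / net$E[units]
    mu <- 1 / sum(J)
    omega_sig <- sum(J) / (J[1] * tau[2] + J[2] * tau[1])
    omega_eps <- 1 / max(tau)
    omega_mu <- 1 / min(tau)
    return(four_param_model(mu, omega_mu, omega_eps, omega_sig))
  }
  arm <- which(net$E > 0 & net$eta > 0)
  dmp <- which(net$E == 0 & net$eta > 0)
  if (net$E_e <= 0 || length(arm) != 1 || length(dmp) != 1 ||
      length(net$E) != 2)
    stop("not a four-parameter Maxwell-Wiechert topology")
  mu <- net$E_e
  omega_sig <- net$E[arm] / net$eta[arm]
  q <- net$eta[dmp] * omega_sig / mu
  r <- net$E[arm] / mu
  s <- q + r + 1
  disc <- s^2 - 4 * q
  if (disc < 0) stop("inconsistent four-parameter network")
  u <- (s + sqrt(disc)) / 2     # omega_sig / omega_eps  (>= 1)
  v <- q / u                    # omega_sig / omega_mu   (<= 1)
  four_param_model(mu, omega_mu = omega_sig / v,
                   omega_eps = omega_sig / u, omega_sig = omega_sig)
}
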