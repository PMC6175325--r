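#' Finite spring-damper networks
#'
#' A spring-damper network is the universal realization target of every
#' model in this package: a finite collection of spring/damper pairs in
#' one of two conjugate topologies.
#'
#' \describe{
#'   \item{\code{maxwell_wiechert}}{pairs of a spring (stiffness
#'     \code{E[n]}, Pa) and a damper (viscosity \code{eta[n]}, Pa s) in
#'     series, all pairs in parallel, plus an optional equilibrium spring
#'     \code{E_e} across the terminals.  A pair with \code{E[n] = 0} and
#'     \code{eta[n] > 0} encodes a damper placed directly across the
#'     terminals (its relaxation response is an impulse at t = 0).}
#'   \item{\code{kelvin_chain}}{pairs of a spring and damper in parallel
#'     (Kelvin-Voigt units), all units in series.  A unit with
#'     \code{eta[n] = 0} is a lone series spring, a unit with
#'     \code{E[n] = 0} a lone series damper.}
#' }
#'
#' Physical realizability requires every stiffness and viscosity to be
#' non-negative; the constructor enforces this.  Pairs with both elements
#' zero contribute nothing and are dropped with a message.
#'
#' @param topology \code{"maxwell_wiechert"} or \code{"kelvin_chain"}.
#' @param E numeric vector of pair stiffnesses [Pa], one per pair.
#' @param eta numeric vector of pair viscosities [Pa s], same length.
#' @param E_e equilibrium spring stiffness [Pa]; Maxwell-Wiechert
#'   topology only (must be 0 for a Kelvin chain).
#'
#' @return An object of class \code{"sdnet"}: a list with elements
#'   \code{topology}, \code{E_e}, \code{E}, \code{eta}.
#' @examples
#' # the unit Zener solid: equilibrium spring 1 Pa, Maxwell arm (1 Pa, 1 Pa s)
#' net <- sdnet("maxwell_wiechert", E = 1, eta = 1, E_e = 1)
#' network_modulus(net, c(0, 1, 1e6))
#' @seealso [network_modulus()], [conjugate_network()], [relaxation_modulus()]
#' @export
sdnet <- function(topology = c("maxwell_wiechert", "kelvin_chain"),
                  E = numeric(), eta = numeric(), E_e = 0) {
  topology <- match.arg(topology)
  E <- as.numeric(E)
  eta <- as.numeric(eta)
  if (length(E) != length(eta))
    stop("`E` and `eta` must have the same length (one value per pair)")
  if (any(!is.finite(E)) || any(!is.finite(eta)) || !is.finite(E_e))
    stop("network elements must be finite numbers")
  if (any(E < 0) || any(eta < 0) || E_e < 0)
    stop("all stiffnesses and viscosities must be non-negative")
  if (topology == "kelvin_chain" && E_e != 0)
    stop("a Kelvin chain has no equilibrium spring; use a lone series spring (eta = 0 pair)")
  dead <- E == 0 & eta == 0
  if (any(dead)) {
    message(sum(dead), " degenerate pair(s) with E = 0 and eta = 0 dropped")
    E <- E[!dead]
    eta <- eta[!dead]
  }
  structure(list(topology = topology, E_e = E_e, E = E, eta = eta),
            class = "sdnet")
}

#' @export
print.sdnet <- function(x, ...) {
  lab <- c(maxwell_wiechert = "Maxwell-Wiechert (parallel)",
           kelvin_chain = "Kelvin chain (series)")[[x$topology]]
  cat("Spring-damper network:", lab, "\n")
  if (x$topology == "maxwell_wiechert")
    cat("  equilibrium spring E_e =", format(x$E_e), "Pa\n")
  if (length(x$E) == 0) {
    cat("  (no spring-damper pairs)\n")
  } else {
    cat(sprintf("  %d pair(s):\n", length(x$E)))
    for (n in seq_along(x$E))
      cat(sprintf("    E = %-12g Pa   eta = %-12g Pa s\n", x$E[n], x$eta[n]))
  }
  invisible(x)
}

n_elements <- function(net) {
  # count of physical elements (springs + dampers), used to dispatch the
  # supported conjugation cases
  (net$E_e > 0) + sum(net$E > 0) + sum(net$eta > 0)
}

#' Dynamic modulus of a spring-damper network
#'
#' Evaluates the complex dynamic modulus E(omega) of a network by direct
#' series/parallel impedance algebra, with the e^{+i omega t} time
#' convention (loss terms carry +i).  For the Maxwell-Wiechert topology
#'
#' \deqn{E(\omega) = E_e + \sum_n \frac{i\omega\eta_n E_n}{E_n + i\omega\eta_n},}
#'
#' where a pair with \eqn{E_n = 0} contributes \eqn{i\omega\eta_n}
#' (terminal damper).  For the Kelvin chain the unit compliances
#' \eqn{1/(E_n + i\omega\eta_n)} are summed and inverted.
#'
#' This evaluation is deliberately closed-form-free: it is the oracle
#' against which all closed-form moduli in this package are checked.
#'
#' @param net an [sdnet()] network.
#' @param omega angular frequencies [rad/s], non-negative.
#' @return complex vector, same length as \code{omega}.
#' @examples
#' net <- sdnet("maxwell_wiechert", E = 1, eta = 1, E_e = 1)
#' network_modulus(net, 10^seq(-2, 2, 0.5))
#' @export
network_modulus <- function(net, omega) {
  stopifnot(inherits(net, "sdnet"))
  omega <- as.numeric(omega)
  if (any(omega < 0)) stop("`omega` must be non-negative")
  iw <- 1i * omega
  if (net$topology == "maxwell_wiechert") {
    Ew <- rep(complex(real = net$E_e), length(omega))
    for (n in seq_along(net$E)) {
      if (net$E[n] == 0) {
        Ew <- Ew + iw * net$eta[n]        # terminal damper
      } else if (net$eta[n] == 0) {
        # damper of zero viscosity shorts the arm: no contribution
      } else {
        Ew <- Ew + iw * net$eta[n] * net$E[n] / (net$E[n] + iw * net$eta[n])
      }
    }
    Ew
  } else {
    if (length(net$E) == 0 || all(net$E == 0 & net$eta == 0))
      stop("degenerate Kelvin chain: no unit with non-zero compliance")
    Jw <- rep(complex(real = 0), length(omega))
    for (n in seq_along(net$E))
      Jw <- Jw + 1 / (net$E[n] + iw * net$eta[n])
    1 / Jw
  }
}

#' Relaxation modulus of a network
#'
#' Stress response to a unit step in strain.  For a Maxwell-Wiechert
#' network this is the Prony series
#' \deqn{G(t) = E_e + \sum_n E_n e^{-t/\tau_n}, \quad \tau_n = \eta_n/E_n,}
#' plus an impulse \eqn{G_-\,\delta(t)} carried by any terminal damper
#' (pair with \eqn{E_n = 0}); the impulse weight is returned separately
#' and never sampled.  A Kelvin chain is first conjugated to its
#' Maxwell-Wiechert form (supported sizes only).
#'
#' @param net an [sdnet()] network.
#' @param t times [s], strictly positive unless the impulse weight is zero.
#' @return A list of class \code{"relaxation_result"} with \code{t},
#'   \code{G} (sampled modulus, Pa), \code{G_minus} (impulse weight,
#'   Pa s) and \code{G_e} (equilibrium modulus, Pa).
#' @examples
#' net <- zener_to_network(zener(E_e = 1, tau_eps = 2, tau_sig = 1))
#' relaxation_modulus(net, c(0.5, 1, 10))  # 1 + exp(-t)
#' @export
relaxation_modulus <- function(net, t) {
  stopifnot(inherits(net, "sdnet"))
  if (net$topology == "kelvin_chain") net <- conjugate_network(net)
  t <- as.numeric(t)
  G_minus <- sum(net$eta[net$E == 0])
  if (any(t < 0)) stop("`t` must be non-negative")
  if (any(t == 0) && G_minus > 0)
    stop("t = 0 is not samplable: the response contains an impulse G_- delta(t)")
  G <- rep(net$E_e, length(t))
  keep <- net$E > 0 & net$eta > 0
  for (n in which(keep))
    G <- G + net$E[n] * exp(-t * net$E[n] / net$eta[n])
  # arms with eta = 0 are shorted and contribute nothing
  structure(list(t = t, G = G, G_minus = G_minus, G_e = net$E_e),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat("Relaxation modulus G(t): ", length(x$t), " sample(s)\n", sep = "")
  cat("  equilibrium G_e =", format(x$G_e), "Pa;  impulse weight G_- =",
      format(x$G_minus), "Pa s\n")
  print(utils::head(data.frame(t = x$t, G = x$G), 10))
  invisible(x)
}

#' Conjugate network (opposite topology, identical modulus)
#'
#' Every realizable modulus has realizations in both topologies; this
#' converts between them for the sizes used in this package: a single
#' element, the two-element Kelvin-Voigt solid, the three-element Zener
#' solid and the four-element non-standard four-parameter model.  General
#' N-element conjugation is not implemented.
#'
#' @param net an [sdnet()] network of a supported size.
#' @return an [sdnet()] with the opposite topology tag and the same
#'   dynamic modulus at every frequency.
#' @examples
#' z <- sdnet("maxwell_wiechert", E = 1, eta = 1, E_e = 1)
#' conjugate_network(z)
#' @export
conjugate_network <- function(net) {
  stopifnot(inherits(net, "sdnet"))
  other <- if (net$topology == "maxwell_wiechert") "kelvin_chain" else "maxwell_wiechert"
  npair <- length(net$E)
  nel <- n_elements(net)

  if (net$topology == "maxwell_wiechert") {
    if (npair == 0)                       # lone spring E_e
      return(sdnet(other, E = net$E_e, eta = 0))
    if (npair == 1 && net$E_e == 0 && net$E[1] == 0)   # lone damper
      return(sdnet(other, E = 0, eta = net$eta[1]))
    if (npair == 1 && net$E_e == 0 && net$eta[1] == 0) # lone spring as pair
      return(sdnet(other, E = net$E[1], eta = 0))
    if (npair == 1 && net$E_e > 0 && net$E[1] == 0)    # Kelvin-Voigt
      return(sdnet(other, E = net$E_e, eta = net$eta[1]))
    if (npair == 1 && net$E_e > 0 && net$E[1] > 0 && net$eta[1] > 0) {
      # Zener: series glass spring + one Kelvin unit
      k1 <- net$E_e + net$E[1]
      k2 <- net$E_e * k1 / net$E[1]
      tau_eps <- net$eta[1] * (1 / net$E_e + 1 / net$E[1])
      return(sdnet(other, E = c(k1, k2), eta = c(0, tau_eps * k2)))
    }
    if (npair == 2 && net$E_e > 0 && nel == 4) {
      m <- network_to_fourparam(net)
      return(fourparam_to_network(m))
    }
    stop("conjugation implemented only for 1-4 element Kelvin-Voigt/Zener/four-parameter topologies")
  }

  # kelvin_chain -> maxwell_wiechert
  springs <- which(net$eta == 0 & net$E > 0)
  dampers <- which(net$E == 0 & net$eta > 0)
  units <- which(net$E > 0 & net$eta > 0)
  if (npair == 1 && length(springs) == 1)
    return(sdnet(other, E = numeric(), eta = numeric(), E_e = net$E[1]))
  if (npair == 1 && length(dampers) == 1)
    return(sdnet(other, E = 0, eta = net$eta[1]))
  if (npair == 1 && length(units) == 1)  # Kelvin-Voigt unit
    return(sdnet(other, E = 0, eta = net$eta[1], E_e = net$E[1]))
  if (npair == 2 && length(springs) == 1 && length(units) == 1) {
    # Zener in Kelvin form: invert the glass-spring + Kelvin-unit map
    k1 <- net$E[springs]
    k2 <- net$E[units]
    c2 <- net$eta[units]
    E_e <- k1 * k2 / (k1 + k2)
    tau_eps <- c2 / k2
    tau_sig <- c2 / (k1 + k2)
    eta <- E_e * (tau_eps - tau_sig)
    return(sdnet(other, E = eta / tau_sig, eta = eta, E_e = E_e))
  }
  if (npair == 2 && length(units) == 2) {
    m <- network_to_fourparam(net)
    return(fourparam_maxwell_network(m))
  }
  stop("conjugation implemented only for 1-4 element Kelvin-Voigt/Zener/four-parameter topologies")
}
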