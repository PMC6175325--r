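#' Long-tailed creep spectral densities of the fractional models
#'
#' A fractional Zener (or Kelvin-Voigt) solid is equivalent to a
#' continuum of elementary spring-damper units weighted by a long-tailed
#' density of time constants (retardation spectrum) or, equivalently, of
#' relaxation frequencies.  The creep time-spectral density is
#' \deqn{R_\epsilon(\tau) = \frac{1}{\pi\tau}\,
#'   \frac{\sin\alpha\pi}
#'        {(\tau/\tau_\epsilon)^\alpha + (\tau/\tau_\epsilon)^{-\alpha}
#'         + 2\cos\alpha\pi},}
#' normalized so that \eqn{\int_0^\infty R_\epsilon\, d\tau = 1}; the
#' transient creep is \eqn{J_\tau(t) = a \int R_\epsilon(\tau)
#' (1 - e^{-t/\tau})\, d\tau} with compliance weight
#' \eqn{a = (1/E_e)\,(1 - (\tau_\sigma/\tau_\epsilon)^\alpha)}.
#' Its log-log asymptotes are \eqn{\tau^{\alpha-1}} well below
#' \eqn{\tau_\epsilon} and \eqn{\tau^{-\alpha-1}} well above: for
#' \eqn{\alpha < 1} the variance of the distribution does not exist
#' (scale-free tail).
#'
#' The conjugate frequency-spectral density over relaxation rates
#' \eqn{\Omega} is
#' \deqn{S_\epsilon(\Omega) = \frac{\tau_\epsilon^\alpha -
#'   \tau_\sigma^\alpha}{\pi E_e}\,
#'   \frac{\Omega^{\alpha-1} \sin\alpha\pi}
#'        {(\Omega\tau_\epsilon)^{2\alpha} + 1 +
#'         2(\Omega\tau_\epsilon)^\alpha \cos\alpha\pi},}
#' related pointwise to the time density by
#' \eqn{S_\epsilon(\Omega) = a\, R_\epsilon(1/\Omega)/\Omega^2} and
#' integrating to \eqn{a}.  For \eqn{\alpha = 1} both densities collapse
#' to an atom (a single relaxation process at \eqn{\tau_\epsilon}),
#' returned as a flagged atom rather than a sampled curve.
#'
#' @param p a [fractional_zener()] or [fractional_kv()] parameter
#'   object (\code{alpha < 1} for a sampled density).
#' @param tau grid of time constants [s], > 0.
#' @param Omega grid of relaxation rates [rad/s], > 0.
#' @return object of class \code{"spectral_density"}: a list with
#'   \code{kind} (\code{"time"} or \code{"freq"}), \code{grid},
#'   \code{values}, the compliance weight \code{a} [1/Pa], the
#'   generating parameters, and \code{atom} (\code{NULL}, or the atom
#'   location when \code{alpha = 1}).
#' @examples
#' p <- fractional_kv(1, 1, alpha = 0.5)
#' time_spectral(p, 1)$values  # 1/(2*pi) at tau = tau_eps
#' @export
time_spectral <- function(p, tau) {
  stopifnot(inherits(p, "frac_params"))
  a <- compliance_weight(p)
  if (p$alpha == 1)
    return(new_spectral_density("time", grid = as.numeric(tau),
                                values = rep(0, length(tau)), a = a, p = p,
                                atom = p$tau_eps))
  tau <- as.numeric(tau)
  if (any(tau <= 0)) stop("`tau` must be positive")
  x <- (tau / p$tau_eps)^p$alpha
  vals <- sin(p$alpha * pi) / (pi * tau) / (x + 1 / x + 2 * cos(p$alpha * pi))
  new_spectral_density("time", grid = tau, values = vals, a = a, p = p)
}

#' @rdname time_spectral
#' @export
freq_spectral <- function(p, Omega) {
  stopifnot(inherits(p, "frac_params"))
  a <- compliance_weight(p)
  if (p$alpha == 1)
    return(new_spectral_density("freq", grid = as.numeric(Omega),
                                values = rep(0, length(Omega)), a = a, p = p,
                                atom = 1 / p$tau_eps))
  Omega <- as.numeric(Omega)
  if (any(Omega <= 0)) stop("`Omega` must be positive")
  al <- p$alpha
  xe <- (Omega * p$tau_eps)^al
  vals <- (p$tau_eps^al - p$tau_sig^al) / (pi * p$E_e) *
    Omega^(al - 1) * sin(al * pi) / (xe^2 + 1 + 2 * xe * cos(al * pi))
  new_spectral_density("freq", grid = Omega, values = vals, a = a, p = p)
}

compliance_weight <- function(p) {
  (1 / p$E_e) * (1 - (p$tau_sig / p$tau_eps)^p$alpha)
}

new_spectral_density <- function(kind, grid, values, a, p, atom = NULL) {
  structure(list(kind = kind, grid = grid, values = values, a = a,
                 alpha = p$alpha, tau_eps = p$tau_eps, tau_sig = p$tau_sig,
                 E_e = p$E_e, atom = atom),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  lab <- c(time = "time-spectral density R_eps(tau)",
           freq = "frequency-spectral density S_eps(Omega)")[[x$kind]]
  cat("Creep", lab, "\n")
  cat("  alpha =", x$alpha, " tau_eps =", x$tau_eps, "s  tau_sig =",
      x$tau_sig, "s\n")
  cat("  compliance weight a =", format(x$a), "1/Pa\n")
  if (!is.null(x$atom)) {
    cat("  degenerate atom (single relaxation) at", format(x$atom), "\n")
  } else {
    cat("  sampled on", length(x$grid), "points in [",
        format(min(x$grid)), ",", format(max(x$grid)), "]\n")
  }
  invisible(x)
}

#' Transient creep compliance from a frequency-spectral density
#'
#' Superposes the elementary exponential creep processes weighted by the
#' frequency-spectral density:
#' \deqn{J_\tau(t) = \int_0^\infty S_\epsilon(\Omega)\,
#'       (1 - e^{-\Omega t})\, d\Omega,}
#' evaluated by adaptive quadrature in \eqn{u = \ln\Omega} over the band
#' the density was sampled on (the analytic density is integrated; the
#' stored samples define the coverage).  The band must span at least 12
#' decades around \eqn{1/\tau_\epsilon} so that both power-law tails are
#' negligible.  \eqn{J_\tau(0^+) = 0} and \eqn{J_\tau(\infty) = a}.
#'
#' For the fractional Zener/Kelvin-Voigt solid the exact answer is the
#' Mittag-Leffler creep \eqn{a\,(1 -
#' E_\alpha(-(t/\tau_\epsilon)^\alpha))}, which serves as the
#' independent cross-check of this quadrature.
#'
#' @param S a \code{"freq"}-kind [freq_spectral()] density.
#' @param t times [s], > 0.
#' @return numeric vector of transient compliances [1/Pa].
#' @export
creep_from_spectrum <- function(S, t) {
  stopifnot(inherits(S, "spectral_density"))
  if (S$kind != "freq")
    stop("creep superposition needs the frequency-spectral density")
  t <- as.numeric(t)
  if (any(t <= 0)) stop("`t` must be positive")
  if (!is.null(S$atom))
    return(S$a * (1 - exp(-S$atom * t)))
  lo <- min(S$grid)
  hi <- max(S$grid)
  w0 <- 1 / S$tau_eps
  if (hi / lo < 1e12 || lo > w0 * 1e-2 || hi < w0 * 1e2)
    stop("insufficient spectral coverage: need >= 12 decades around 1/tau_eps")
  al <- S$alpha
  ca <- cos(al * pi)
  pref <- (S$tau_eps^al - S$tau_sig^al) / (pi * S$E_e) * sin(al * pi)
  dens_u <- function(u) {
    # S_eps(e^u) * e^u  (log-substituted density)
    Om <- exp(u)
    xe <- (Om * S$tau_eps)^al
    pref * Om^al / (xe^2 + 1 + 2 * xe * ca)
  }
  ulo <- log(lo)
  uhi <- log(hi)
  vapply(t, function(tt) {
    f <- function(u) dens_u(u) * (-expm1(-exp(u) * tt))
    breaks <- sort(unique(pmin(pmax(c(ulo, log(w0), log(1 / tt), uhi),
                                    ulo), uhi)))
    total <- 0
    for (j in seq_len(length(breaks) - 1)) {
      if (breaks[j + 1] <= breaks[j]) next
      total <- total + stats::integrate(f, breaks[j], breaks[j + 1],
                                        rel.tol = 1e-11,
                                        abs.tol = 1e-13 * S$a,
                                        subdivisions = 1000L)$value
    }
    total
  }, numeric(1))
}

#' Discretize a fractional model into a finite Kelvin chain
#'
#' Approximates the continuum of creep processes of a fractional
#' Zener/Kelvin-Voigt solid by a finite Kelvin chain: unit relaxation
#' rates \eqn{\Omega_m} are placed log-uniformly across the requested
#' band (padded on both sides so that band edges stay accurate), each
#' unit receiving the compliance \eqn{J_m = S_\epsilon(\Omega_m)\,
#' \Delta\Omega_m} of its midpoint cell, i.e. spring \eqn{E_m = 1/J_m}
#' and damper \eqn{\eta_m = E_m/\Omega_m}.  A lone series spring carries
#' the residual static compliance so the chain's long-time compliance
#' equals \eqn{1/E_e} exactly.  For \eqn{\alpha = 1} the density is an
#' atom and the exact finite realization (one Kelvin unit, plus a glass
#' spring for the Zener case) is returned instead.
#'
#' The chain's dynamic modulus approaches [frac_modulus()] on the band
#' as \code{n_per_decade} grows; all elements are non-negative because
#' the density is.
#'
#' @param p a [fractional_zener()] / [fractional_kv()] object.
#' @param n_per_decade Kelvin units per decade of relaxation rate.
#' @param band length-2 vector \code{c(Omega_lo, Omega_hi)} [rad/s],
#'   spanning at least 2 decades.
#' @param pad_decades padding added on each side of the band before
#'   placing units (default 3).
#' @return a Kelvin-chain [sdnet()].
#' @examples
#' p <- fractional_kv(1, 1, alpha = 0.5)
#' net <- discretize_spectrum(p, n_per_decade = 8, band = c(1e-2, 1e2))
#' max(Mod(network_modulus(net, c(0.5, 1, 2)) / frac_modulus(p, c(0.5, 1, 2)) - 1))
#' @export
discretize_spectrum <- function(p, n_per_decade, band, pad_decades = 3) {
  stopifnot(inherits(p, "frac_params"), length(band) == 2, all(band > 0),
            n_per_decade >= 1, pad_decades >= 0)
  band <- sort(band)
  if (band[2] / band[1] < 100)
    stop("`band` must span at least 2 decades")
  if (p$alpha == 1) {
    # atom: exact Zener/Kelvin-Voigt realization
    a <- compliance_weight(p)
    E1 <- 1 / a
    unit <- c(E = E1, eta = E1 * p$tau_eps)
    if (p$tau_sig == 0)
      return(sdnet("kelvin_chain", E = unit["E"], eta = unit["eta"]))
    Jg <- p$tau_sig / (p$E_e * p$tau_eps)      # glass compliance
    return(sdnet("kelvin_chain", E = c(1 / Jg, unit["E"]),
                 eta = c(0, unit["eta"])))
  }
  ulo <- log10(band[1]) - pad_decades
  uhi <- log10(band[2]) + pad_decades
  n <- max(2L, ceiling(n_per_decade * (uhi - ulo)))
  edges <- 10^seq(ulo, uhi, length.out = n + 1)
  mids <- sqrt(edges[-1] * edges[-(n + 1)])
  dOm <- diff(edges)
  Jm <- freq_spectral(p, mids)$values * dOm
  # the truncated low-rate tail acts as one slow unit at its centroid
  # rate; the high-rate tail is spring-like at band frequencies and is
  # absorbed (with the glass compliance) by the lone series spring
  Sfun <- function(Om) freq_spectral(p, Om)$values
  tail_lo <- spectral_tail_moments(Sfun, p$alpha, edges[1], lower = TRUE)
  if (tail_lo$mass > 0) {
    Jm <- c(tail_lo$mass, Jm)
    mids <- c(tail_lo$centroid, mids)
  }
  keep <- Jm > 0
  Jm <- Jm[keep]
  mids <- mids[keep]
  J_res <- 1 / p$E_e - sum(Jm)      # exact static compliance balance
  if (J_res > 0) {
    E <- c(1 / J_res, 1 / Jm)
    eta <- c(0, 1 / (Jm * mids))
  } else {
    # cell weights already exhaust the static compliance: rescale
    Jm <- Jm / (p$E_e * sum(Jm))
    E <- 1 / Jm
    eta <- 1 / (Jm * mids)
  }
  sdnet("kelvin_chain", E = E, eta = eta)
}

#' Relaxation modulus from a user-supplied frequency-spectral density
#'
#' Generic superposition of decaying exponentials weighted by a
#' relaxation-side frequency-spectral density:
#' \deqn{G_\tau(t) = \int_0^\infty S_\sigma(\Omega)\, e^{-\Omega t}\,
#'       d\Omega,}
#' the relaxation-side counterpart of [creep_from_spectrum()].  Unlike
#' the creep densities of the fractional solids, no closed-form
#' relaxation-side density is provided here, so the density is supplied
#' by the caller as a plain function of the relaxation rate
#' \eqn{\Omega} [rad/s] (e.g. a Prony comb smoothed into a continuum,
#' or the time-side density \eqn{b R_\sigma(1/\Omega)/\Omega^2}).
#'
#' @param S_fun vectorized function of \eqn{\Omega} returning the
#'   non-negative density \eqn{S_\sigma(\Omega)} [Pa s].
#' @param t times [s], > 0.
#' @param band length-2 integration band \code{c(Omega_lo, Omega_hi)}
#'   [rad/s] outside which the density is treated as negligible.
#' @return numeric vector \eqn{G_\tau(t)} [Pa].
#' @examples
#' # S(Omega) = exp(-Omega) has G_tau(t) = 1/(1 + t) exactly
#' relaxation_from_spectrum(function(Om) exp(-Om), t = c(0.5, 1, 4),
#'                          band = c(1e-8, 1e3))
#' @export
relaxation_from_spectrum <- function(S_fun, t, band) {
  stopifnot(is.function(S_fun), length(band) == 2, all(band > 0),
            band[2] > band[1])
  t <- as.numeric(t)
  if (any(t <= 0)) stop("`t` must be positive")
  ulo <- log(band[1])
  uhi <- log(band[2])
  vapply(t, function(tt) {
    f <- function(u) S_fun(exp(u)) * exp(u) * exp(-exp(u) * tt)
    breaks <- sort(unique(pmin(pmax(c(ulo, log(1 / tt), uhi), ulo), uhi)))
    total <- 0
    for (j in seq_len(length(breaks) - 1)) {
      if (breaks[j + 1] <= breaks[j]) next
      total <- total + stats::integrate(f, breaks[j], breaks[j + 1],
                                        rel.tol = 1e-10, abs.tol = 1e-14,
                                        subdivisions = 1000L)$value
    }
    total
  }, numeric(1))
}

# Mass and rate centroid of a spectral tail, by log-substituted
# quadrature; `edge` is the truncation edge, `lower` selects the
# (0, edge] tail.  The tail decays like Omega^(alpha -+ 1), so 60/alpha
# log-units of range bound the remainder below 1e-25 relative.
spectral_tail_moments <- function(Sfun, alpha, edge, lower = TRUE) {
  span <- 60 / alpha
  lims <- if (lower) log(edge) + c(-span, 0) else log(edge) + c(0, span)
  m0 <- stats::integrate(function(u) Sfun(exp(u)) * exp(u),
                         lims[1], lims[2], rel.tol = 1e-10,
                         subdivisions = 600L)$value
  m1 <- stats::integrate(function(u) Sfun(exp(u)) * exp(2 * u),
                         lims[1], lims[2], rel.tol = 1e-10,
                         subdivisions = 600L)$value
  list(mass = m0, centroid = if (m0 > 0) m1 / m0 else edge)
}

#' Ordinary least-squares slope on log-log axes
#'
#' Fits \code{log10(y) ~ log10(x)} and returns the slope; the helper
#' used to measure power-law asymptotes of spectral densities.
#'
#' @param x,y positive numeric vectors.
#' @return fitted slope (dimensionless).
#' @export
loglog_slope <- function(x, y) {
  stopifnot(length(x) == length(y), all(x > 0), all(y > 0))
  unname(stats::coef(stats::lm(log10(y) ~ log10(x)))[2])
}
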