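#' Mittag-Leffler function on the completely monotone branch
#'
#' Evaluates \eqn{E_\alpha(z) = \sum_{n \ge 0} z^n/\Gamma(\alpha n + 1)}
#' for order \eqn{\alpha \in (0, 1]} and real argument \eqn{z \le 0},
#' the branch on which \eqn{E_\alpha(-x)} is completely monotone and
#' governs fractional relaxation and creep.
#'
#' Three regimes are used, switched on \eqn{x = -z}:
#' \itemize{
#'   \item small \eqn{x}: the defining Taylor series (no cancellation
#'     for \eqn{x \le 1/2});
#'   \item moderate \eqn{x}: the spectral (Titchmarsh) integral
#'     \deqn{E_\alpha(-x) = \int_0^\infty
#'       \frac{\sin(\alpha\pi)}{\pi}
#'       \frac{r^{\alpha-1}\, e^{-r x^{1/\alpha}}}
#'            {r^{2\alpha} + 2 r^\alpha \cos(\alpha\pi) + 1}\, dr,}
#'     integrated adaptively in \eqn{u = \ln r} (piecewise around the
#'     spectral peak, which sharpens as \eqn{\alpha \to 1});
#'   \item large \eqn{x}: the asymptotic series
#'     \eqn{\sum_{k\ge 1} (-1)^{k+1} x^{-k}/\Gamma(1 - \alpha k)}.
#' }
#' Relative accuracy is about 1e-10 across the supported branch;
#' \eqn{\alpha = 1} returns \eqn{e^z} exactly.
#'
#' @param alpha order, in \code{(0, 1]}.
#' @param z real argument(s), \code{z <= 0}.
#' @return numeric vector of \eqn{E_\alpha(z)} values in \code{(0, 1]}.
#' @examples
#' mittag_leffler(1, -1)          # exp(-1)
#' mittag_leffler(0.5, -1)        # exp(1) * erfc(1)
#' @export
mittag_leffler <- function(alpha, z) {
  stopifnot(is.finite(alpha), alpha > 0, alpha <= 1)
  z <- as.numeric(z)
  if (any(!is.finite(z)) || any(z > 0))
    stop("only the completely monotone branch z <= 0 is supported")
  if (alpha == 1) return(exp(z))
  vapply(-z, function(x) ml_neg(alpha, x), numeric(1))
}

ml_neg <- function(alpha, x) {
  if (x == 0) return(1)
  if (x <= 0.5) return(ml_taylor(alpha, x))
  if (x >= 1e8) return(ml_asymptotic(alpha, x))
  ml_integral(alpha, x)
}

ml_taylor <- function(alpha, x) {
  s <- 1
  term <- 1
  for (n in 1:200) {
    term <- term * (-x)
    incr <- term / gamma(alpha * n + 1)
    s <- s + incr
    if (abs(incr) < 1e-17 * abs(s)) break
  }
  s
}

ml_asymptotic <- function(alpha, x) {
  k <- 1:6
  g <- 1 - alpha * k
  rg <- numeric(length(g))                # reciprocal gamma, 0 at the poles
  ok <- !(g == round(g) & g <= 0)
  rg[ok] <- 1 / gamma(g[ok])
  sum((-1)^(k + 1) * x^(-k) * rg)
}

ml_integral <- function(alpha, x) {
  t <- x^(1 / alpha)
  sa <- sin(alpha * pi)
  ca <- cos(alpha * pi)
  f <- function(u) {
    r <- exp(u)
    ra <- r^alpha
    sa / pi * ra * exp(-r * t) / (ra^2 + 2 * ra * ca + 1)
  }
  u_lo <- -69 / alpha                       # below this the r^alpha tail is < 1e-30
  u_hi <- min(69 / alpha, log(746 / t))     # exp underflows beyond 746/t
  if (u_hi <= u_lo) return(0)
  w <- max(1 - alpha, 0.05)                 # spectral peak half-width near r = 1
  breaks <- sort(unique(pmin(pmax(c(u_lo, -5 * w, -w, 0, w, 5 * w, u_hi),
                                  u_lo), u_hi)))
  total <- 0
  for (j in seq_len(length(breaks) - 1)) {
    if (breaks[j + 1] <= breaks[j]) next
    total <- total + stats::integrate(f, breaks[j], breaks[j + 1],
                                      rel.tol = 1e-12, abs.tol = 1e-15,
                                      subdivisions = 500L)$value
  }
  total
}
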