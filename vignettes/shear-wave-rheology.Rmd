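---
title: "Shear-wave rheology: spring-damper, fractional and poroelastic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-wave rheology: spring-damper, fractional and poroelastic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheowave)
```

# The modelling problem

Elastography infers tissue mechanics from shear waves of, typically,
1-1000 Hz.  The simplest reading assumes a purely elastic medium; more
realistic readings use linear viscoelastic solids (Kelvin-Voigt,
Zener), their fractional generalizations (which capture the power-law
frequency dependence widely observed in liver, breast and brain), or
biphasic poroelastic media (which distinguish the solid matrix from the
pore fluid).  These families look unrelated, but for the one wave type
elastography measures — the shear wave — they can all be expressed as
spring-damper networks, and `rheowave` implements exactly that unified
view: every model in the package produces a complex dynamic modulus
$E(\omega)$, every modulus feeds the same dispersion relation, and the
conversions between families are implemented where they are exact.

Conventions used throughout: strict SI units; angular frequency
$\omega$ [rad/s] internally, plain Hz at every file/CLI boundary
($\times 2\pi$ on read); time dependence $e^{+i\omega t}$, so passivity
means $\mathrm{Im}\,E(\omega) \ge 0$ and the complex wavenumber

$$ \left(\frac{k}{\omega}\right)^2 = \frac{\rho}{E(\omega)} $$

is taken on the principal branch with $\mathrm{Re}\,k > 0$; attenuation
is reported sign-free as $|\mathrm{Im}\,k|$ [Np/m].

# Spring-damper networks as the common currency

`sdnet()` stores a finite network in either of two conjugate
topologies: Maxwell-Wiechert (spring-damper pairs in series, pairs in
parallel, optional equilibrium spring $E_e$) or a Kelvin chain
(spring-damper pairs in parallel, units in series).
`network_modulus()` evaluates $E(\omega)$ by raw impedance algebra and
serves as the package's internal oracle: every closed form (Zener,
fractional limit cases, the Biot-Zener map, the four-parameter
realization) is tested against it at relative $10^{-12}$ or better.

A Maxwell-Wiechert pair with zero spring encodes a damper directly
across the terminals; its relaxation response is an impulse
$G_-\delta(t)$, which `relaxation_modulus()` reports as a separate
scalar and never samples (sampling at $t = 0$ with $G_- > 0$ is an
error, not a number).  Pairs with both elements zero are dropped with a
message.  `conjugate_network()` converts between the topologies for the
sizes this package synthesizes — one element, Kelvin-Voigt, Zener, and
the four-element non-standard four-parameter model; general $N$-element
resynthesis is out of scope by design.

```{r}
z <- zener(E_e = 1, tau_eps = 2, tau_sig = 1)
net <- zener_to_network(z)            # E_e = 1 Pa, arm (1 Pa, 1 Pa s)
om <- log_omega_grid(1e-3, 1e3, 25)
max(Mod(network_modulus(net, om) / zener_modulus(z, om) - 1))
```

# Fractional solids and their spectral decomposition

The fractional Zener modulus
$E(\omega) = E_e\,(1 + (i\omega\tau_\epsilon)^\alpha)/(1 +
(i\omega\tau_\sigma)^\alpha)$ uses the principal branch
$(i\omega\tau)^\alpha = (\omega\tau)^\alpha e^{i\alpha\pi/2}$ for
$\omega \ge 0$ (negative frequencies follow by conjugate symmetry and
are not evaluated).  $\alpha = 1$ reproduces the classical Zener to
machine precision; $\tau_\sigma = 0$ gives the fractional Kelvin-Voigt
solid whose loss element is a spring-pot, and $\alpha \to 0$
approaches structural damping ($E = K + iH$):
`hysteresis_limit_check()` reports the in-band loss variation
$(\omega_{hi}/\omega_{lo})^\alpha$, about 1.047 for $\alpha = 0.01$
over two decades.

The physical content of the fractional order is carried by the creep
spectral functions: the transient creep compliance is a superposition
of elementary exponential processes with the long-tailed density

$$ R_\epsilon(\tau) = \frac{1}{\pi\tau}
   \frac{\sin\alpha\pi}{(\tau/\tau_\epsilon)^\alpha +
   (\tau/\tau_\epsilon)^{-\alpha} + 2\cos\alpha\pi},
   \qquad \int_0^\infty R_\epsilon \, d\tau = 1, $$

equivalently, over relaxation rates, $S_\epsilon(\Omega) = a\,
R_\epsilon(1/\Omega)/\Omega^2$ with compliance weight
$a = (1/E_e)(1 - (\tau_\sigma/\tau_\epsilon)^\alpha)$.  Both functions
are implemented independently from their printed closed forms and their
mutual consistency is tested to $10^{-14}$ relative.  The tails fall
off as $\tau^{\alpha-1}$ and $\tau^{-\alpha-1}$: slower than
$\tau^{-2}$ for $\alpha < 1$, so the distribution has no variance —
the scale-free signature that distinguishes fractional from classical
relaxation.  For $\alpha = 1$ both densities collapse to an atom
(single relaxation process) and are returned as a flagged atom rather
than a sampled curve.

Two numerical notes on measuring those tails.  First, the densities
approach their power laws at rate $(\tau/\tau_\epsilon)^{\mp\alpha}$,
so a log-log slope fitted a fixed distance from the peak converges
slowly for small $\alpha$; the package's tests fit on windows
$\max(4, \lceil 2/\alpha \rceil)$ decades out (20 points per decade,
ordinary least squares via `loglog_slope()`), which keeps the fitted
slopes within $\pm 0.01$ of $\alpha - 1$ and $-\alpha - 1$ for every
tested order.  Second, integrals over the densities (normalization,
creep superposition) are computed by adaptive quadrature in
$u = \ln\Omega$; when creep from `creep_from_spectrum()` is compared
with the exact Mittag-Leffler creep
$a(1 - E_\alpha(-(t/\tau_\epsilon)^\alpha))$ at relative $10^{-6}$,
the spectral band must be wide enough that the truncated tail mass
($\propto (\Omega\tau_\epsilon)^{-\alpha}$) stays below that level —
$\max(18, \lceil 8/\alpha \rceil)$ decades each side in the tests.

`mittag_leffler()` itself switches between the defining Taylor series
($x \le 1/2$), the spectral (Titchmarsh) integral over the
completely monotone density (evaluated piecewise around the peak that
sharpens as $\alpha \to 1$), and the asymptotic inverse-power series
($x \ge 10^8$); it is validated against $E_{1/2}(-x) = e^{x^2}
\mathrm{erfc}(x)$ and $E_1(-x) = e^{-x}$.

## Discretizing the continuum into a Prony-type chain

`discretize_spectrum()` converts a fractional model into a finite
Kelvin chain: unit relaxation rates are placed log-uniformly across the
requested band, padded by 3 decades on each side, each unit receiving
the compliance $S_\epsilon(\Omega_m)\Delta\Omega_m$ of its midpoint
cell.  Two boundary choices matter and were made once:

* the *low*-rate tail beyond the padded band is integrated exactly and
  assigned to one extra slow unit at the tail's rate centroid — slow
  processes are nearly rigid at band frequencies, and folding their
  mass into a series spring instead visibly corrupts the band for
  small $\alpha$;
* the *high*-rate tail, which is spring-like at band frequencies, is
  absorbed together with the glass compliance by a lone series spring
  sized so the chain's static compliance equals $1/E_e$ exactly.

With 8 units per decade the chain reproduces the fractional
Kelvin-Voigt modulus within 1% over the central band, and the error is
non-increasing in unit density:

```{r}
p <- fractional_kv(E_e = 1, tau_eps = 1, alpha = 0.5)
net <- discretize_spectrum(p, n_per_decade = 8, band = c(1e-2, 1e2))
om_mid <- log_omega_grid(1e-1, 1e1, 15)
max(Mod(network_modulus(net, om_mid) / frac_modulus(p, om_mid) - 1))
```

Only the creep-side densities have closed forms here; relaxation-side
spectra are supported generically through
`relaxation_from_spectrum()`, which superposes a user-supplied density.

# The Biot shear wave and its exact Zener equivalent

`biot_medium()` carries the ten low-frequency Biot parameters
(porosity, solid/fluid densities and bulk moduli, fluid viscosity,
permeability, tortuosity, frame bulk and shear moduli); the model
assumes laminar Darcy flow in the pores, so no pore-size correction
appears and the high-frequency regime is out of scope.  The shear
branch is implemented twice, deliberately: the original-formulation
dispersion in terms of normalized effective densities
$\gamma_{ij}$ and the characteristic frequency $f_c$, and the Stoll
form in terms of the mass-coupling density
$\rho_c = \alpha_t\rho_f/\phi$.  The mass-coupling closure
$\rho_{22} = \alpha_t\phi\rho_f$, $\rho_{12} = \phi\rho_f - \rho_{22}$,
$\rho_{11} = (1-\phi)\rho_s - \rho_{12}$ is the standard one; under it
the two formulations agree to rounding error across random media, which
is the package's check on the original-formulation transcription.

Both are exactly a Zener medium:

$$ E_e = \mu_r,\quad
   \omega_\epsilon = \frac{\eta_f}{\rho_c B},\quad
   \omega_\sigma = \frac{\omega_\epsilon}{1 - \rho_f^2/(\rho\rho_c)}
   \ \ge \omega_\epsilon,\quad c_0^2 = \mu_r/\rho, $$

and the effective characteristic frequency satisfies
$f_c' = \omega_\epsilon/(2\pi)$.  The modulus limit
$E(\infty) = E_e\,\omega_\sigma/\omega_\epsilon$ forces
$c_\infty = c_0\sqrt{\omega_\sigma/\omega_\epsilon}$ (the square root
is occasionally dropped in renderings of this relation; the algebra
admits only this form).

```{r}
p <- biot_medium(phi = 0.5, rho_s = 2650, rho_f = 1000, K_s = 3.6e10,
                 K_f = 2.2e9, eta_f = 1e-3, B = 1e-11, tortuosity = 1.25,
                 K_r = 5e7, mu_r = 5e3)
unlist(biot_to_zener(p)[c("omega_eps", "omega_sig", "c0")])
```

## Sensitivity and parameter counting

`shear_sensitivity()` perturbs each of the ten parameters by 10% (both
the step and the $10^{-8}$ decision threshold are arguments) and flags
the ones that move the dispersion: the three bulk moduli produce
*exactly* zero change — they never enter the shear branch — and the
other seven are flagged.

`identifiability_rank()` answers "how many independent numbers does
the shear model really contain?", and the honest answer depends on
what one observes, so the function exposes both readings:

* **`observables = "reduction"`** (default): the rank of the
  numerically differentiated map from the seven raw parameters to the
  sufficient combination vector
  $(\mu_r, \rho, \rho_c, \eta_f/B, \rho_f)$ — the smallest set of
  combinations from which the shear response can be computed exactly.
  The rank is 5, confirming those combinations are functionally
  independent; holding the ratio $\omega_\sigma/\omega_\epsilon$
  fixed (`model = "approximate"` — its denominator
  $1 - \rho_f^2/(\rho\rho_c)$ is typically above 0.8 and barely
  moves) removes the lone role of $\rho_f$ and the count drops to 4,
  the size of a Zener medium description.
* **`observables = "dispersion"`**: the rank of the Jacobian of the
  stacked $\mathrm{Re}/\mathrm{Im}$ wavenumber samples themselves.
  Because $k^2 = (\rho/\mu_r)\,\omega^2(1 + i\omega/\omega_\sigma)/(1 +
  i\omega/\omega_\epsilon)$, a shear-wave measurement alone constrains
  only $(\mu_r/\rho, \omega_\epsilon, \omega_\sigma)$: the rank is 3
  (2 under the approximation), *whatever* the parameter count of the
  medium.  This is worth knowing before fitting a ten-parameter
  poroelastic model to a dispersion curve.

Columns are scaled by parameter magnitude and rows by baseline
observable magnitude before the SVD; singular values below $10^{-6}$
of the leading one count as zero, a tolerance that cleanly separates
the genuine directions (smallest retained singular value
$\gtrsim 10^{-2}$ of the leading) from central-difference noise
($\lesssim 10^{-8}$).

```{r}
c(exact = identifiability_rank(p),
  approximate = identifiability_rank(p, model = "approximate"),
  wave_only = identifiability_rank(p, observables = "dispersion"))
```

## Poroviscoelasticity: the four-parameter model

Letting the frame shear modulus itself relax,
$\mu' = \mu(1 + i\omega/\omega_\mu)$, turns the Zener equivalent into
the non-standard four-parameter model
$E(\omega) = \mu(1 + i\omega/\omega_\mu)(1 + i\omega/\omega_\epsilon)/
(1 + i\omega/\omega_\sigma)$, with $E(0) = \mu$ and $|E|$ growing
linearly at high frequency.  `fourparam_to_network()` realizes it
exactly as two Kelvin units in series by partial fractions of the
compliance over the poles $\omega_\mu, \omega_\epsilon$; a negative
partial-fraction weight (e.g. $\omega_\sigma > \omega_\mu$) means no
passive two-unit chain exists and is reported with the offending
coefficient.  The conjugate Maxwell-Wiechert realization (equilibrium
spring, one Maxwell arm, one terminal damper) exists for
$\omega_\epsilon \le \omega_\sigma \le \omega_\mu$ and is produced by
`conjugate_network()`; since only the modulus identity is testable, the
package commits to the Kelvin-chain layout as primary and treats the
parallel-form drawing as an equivalent alternative.  The sand-coupling
extension in which bulk and shear relaxation couple through
frequency-dependent special functions is out of scope.

# The material generators and what the tests do (and do not) show

`generate_fixtures()` writes five canonical material files with
physically plausible magnitudes: a unit Zener solid (1 Pa, 2 s, 1 s)
kept dimensionless for readability; fractional solids with
elastography-like stiffness (2 kPa) and orders 0.3 (Kelvin-Voigt, the
upper end of the range reported for liver) and 0.8 (Zener, with the
two time constants three decades apart so both crossovers are visible
on one plot); a Biot baseline (porosity 0.5, water-like pore fluid,
quartz-like grain density, tortuosity 1.25, permeability
$10^{-11}$ m$^2$, soft 5 kPa frame) whose crossover lands at
$4\times10^4$ rad/s; and its BICSQS extension with the frame
relaxation placed a decade above $\omega_\sigma$.  `random_biot()`
draws validation media log-uniformly across sediment/soft-tissue-like
ranges (porosity 0.2-0.8, tortuosity 1-3, permeability
$10^{-13}$-$10^{-9}$ m$^2$, frame modulus 1-100 kPa).

These are *synthetic, analytically defined* materials.  What passing
tests demonstrate is internal mathematical correctness — exact
equivalences, correct limits, convergent approximations, consistent
spectral transforms — not that any of these models describes a given
tissue; no measured elastography data enters this package, and model
fitting to data is explicitly out of scope.  Problem sizes were chosen
so the whole suite exercises the mathematics at full stated tolerances
(200-media sweeps, 9 fractional orders, multi-decade grids) while the
complete test run and the acceptance script each finish in seconds.

# Numerical choices, degenerate inputs, limitations

* Quadratures use `stats::integrate` on $u = \ln\Omega$ with interval
  splitting at the structural points (spectral peak, $1/t$ knee);
  tolerances $10^{-10}$-$10^{-12}$ relative.
* The principal square root plus $\mathrm{Re}\,k > 0$ fixes the
  wavenumber branch; no unwinding is ever needed because all moduli
  here have positive real part on $\omega \ge 0$.
* Degenerate networks: zero-zero pairs are dropped with a message; a
  Kelvin chain with no compliant unit is an error;
  $\tau_\sigma = \tau_\epsilon$ (zero damper) is rejected in
  `zener_to_network()`; $\phi \to 0$ makes $\rho_c$ diverge and is an
  explicit error.
* The fractional constitutive law is taken with the same order
  $\alpha$ on the stress and strain derivatives (the dynamic modulus
  used throughout forces this).
* The fixture with three decades between the fractional Zener time
  constants is stated as the ratio
  $\tau_\epsilon/\tau_\sigma = 10^3$; the package enforces
  $\tau_\sigma < \tau_\epsilon$, and every consistency test is
  symmetric in that ratio.
* Known limitations: shear waves only (no fast/slow compressional
  branches), low-frequency laminar Biot regime only, no time-domain
  fractional stepping (creep/relaxation go through the Mittag-Leffler
  function and spectral quadrature), no general $N$-element network
  synthesis, no fitting of measured data.
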