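# rheowave

Spring–damper, fractional and poroelastic models of tissue shear-wave
dispersion, for people who model MR (or ultrasound) elastography data:
given the material parameters of a viscoelastic, fractional
viscoelastic, poroelastic or poroviscoelastic medium, the package
produces its complex dynamic modulus and the resulting shear-wave
dispersion curve, and converts between the model families exactly where
exact equivalences exist.

## The models

All models live in one frame: a complex dynamic modulus `E(ω)` (time
convention `e^{+iωt}`, so passive loss is `Im E ≥ 0`) entering the
dispersion relation

    (k/ω)² = ρ / E(ω),      c_p = ω/Re(k),   attenuation = |Im(k)|  [Np/m]

* **Spring–damper networks** (`sdnet`): finite Maxwell–Wiechert
  (parallel) or Kelvin (series) chains, evaluated by plain impedance
  algebra — the oracle every closed form is tested against.  The Zener
  solid is `E(ω) = E_e (1 + iωτ_ε)/(1 + iωτ_σ)` with `τ_σ ≤ τ_ε`;
  `τ_σ = 0` is Kelvin–Voigt.
* **Fractional solids** (`frac_modulus`): `E(ω) = E_e (1 +
  (iωτ_ε)^α)/(1 + (iωτ_σ)^α)`, `α ∈ (0,1]`.  Their creep decomposes
  into a continuum of elementary spring–damper units weighted by the
  long-tailed density `R_ε(τ) ∝ τ^{α-1}` (below `τ_ε`) and `τ^{-α-1}`
  (above); `discretize_spectrum()` turns that continuum into a finite
  Kelvin chain (a Prony-type approximation), and `mittag_leffler()`
  provides the exact creep for cross-checking.  Structural damping
  (`E = K + iH`) appears as the `α → 0` limit.
* **Biot poroelasticity** (`biot_shear_original`, `biot_shear_stoll`):
  the shear branch of the low-frequency (laminar Darcy flow) two-phase
  medium.  Its dynamic modulus is *identically* a Zener modulus,
  `biot_to_zener()` giving `E_e = μ_r`, `ω_ε = η_f/(ρ_c B)`,
  `ω_σ = ω_ε/(1 − ρ_f²/(ρ ρ_c))` with `ρ_c = tortuosity·ρ_f/φ`.
  `shear_sensitivity()` shows that exactly seven of the ten material
  parameters touch the shear wave, and `identifiability_rank()`
  counts the independent parameter combinations (five exactly, four
  under a mild approximation — and only three are visible to a
  shear-wave measurement alone).
* **Poroviscoelasticity (BICSQS)** (`bicsqs_modulus`): a relaxing frame
  shear modulus upgrades the Zener equivalent to the non-standard
  four-parameter model `E(ω) = μ(1 + iω/ω_μ)(1 + iω/ω_ε)/(1 + iω/ω_σ)`,
  realized exactly as two Kelvin units in series
  (`fourparam_to_network()`).

## Worked example

```r
library(rheowave)

p <- biot_medium(phi = 0.5, rho_s = 2650, rho_f = 1000,
                 K_s = 3.6e10, K_f = 2.2e9, eta_f = 1e-3, B = 1e-11,
                 tortuosity = 1.25, K_r = 5e7, mu_r = 5e3)
bz <- biot_to_zener(p)
bz$omega_eps                 # 40000      (rad/s)
bz$omega_sig / bz$omega_eps  # 1.280702
bz$c0                        # 1.655212   (m/s)

om <- log_omega_grid(4e2, 4e6, 5)
max(Mod(biot_shear_stoll(p, om)$E / zener_modulus(bz$zener, om) - 1))
# 2.220892e-16   -- the Biot/Zener equivalence is exact, not approximate

shear_sensitivity(p)[c(4, 5, 9), ]
#   parameter max_rel_dk affects
# 4       K_s          0   FALSE
# 5       K_f          0   FALSE
# 9       K_r          0   FALSE
```

The 40000 rad/s crossover is where the pore fluid stops moving with the
frame and the phase velocity starts rising from `c0 = √(μ_r/ρ)` toward
`c∞ = c0·√(ω_σ/ω_ε)`; the three bulk moduli never enter the shear wave.

## Command line

A thin wrapper over the same functions
(`inst/cli/rheowave.R`; after installation locate it with
`system.file("cli", "rheowave.R", package = "rheowave")`):

```sh
Rscript rheowave.R fixtures  --out-dir materials
Rscript rheowave.R dispersion --params materials/biot_baseline.yaml --out curve.csv
Rscript rheowave.R biot2zener --params materials/biot_baseline.yaml --report report.json
Rscript rheowave.R spectrum   --alpha 0.8 --tau-eps 1 --kind freq --out spectrum.csv
Rscript rheowave.R prony      --alpha 0.5 --tau-eps 1 --n-per-decade 8 --out chain.json
```

Material files are YAML/JSON in SI units, frequencies are Hz at the
command line; exit codes are 0 (success), 2 (validation error), 1
(numerical error).

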