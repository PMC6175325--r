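Package: rheowave
Title: Spring-Damper, Fractional and Poroelastic Models of Shear-Wave
    Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tissue shear-wave rheology as used in MR
    elastography modelling. Implements finite spring-damper networks
    (Maxwell-Wiechert and Kelvin chains), the classical and fractional
    Kelvin-Voigt and Zener dynamic moduli, Mittag-Leffler relaxation,
    long-tailed time- and frequency-spectral decompositions of the
    fractional models together with their discretization into finite
    Kelvin chains, and the shear-wave branch of Biot poroelasticity in
    both the original and Stoll formulations with its exact Zener
    equivalent.  The poroviscoelastic (BICSQS) extension is provided as
    the non-standard four-parameter model with its spring-damper
    realization.  Dynamic moduli are converted into dispersion curves
    (complex wavenumber, phase velocity, attenuation), and a small
    command-line interface turns material parameter files into curves,
    spectra, Prony chains and sensitivity reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
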