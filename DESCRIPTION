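Package: thetamcf
Title: Matrix-Continued-Fraction Solver for the Theta Neuron with Colored Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the two-dimensional Fokker-Planck equation of a theta
    neuron (quadratic integrate-and-fire in phase representation) driven by
    Ornstein-Uhlenbeck colored noise, using the matrix-continued-fraction
    method in a Fourier-Hermite basis. Computes stationary firing rates,
    phase densities, and the linear and nonlinear firing-rate response to
    one or two periodic signals, with closed-form limits (deterministic,
    quasi-static, weak-noise) and a Langevin spike-train simulator as
    built-in cross-checks. Includes a command-line interface for parameter
    scans written as CSV with JSON sidecars.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
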