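Package: spinpair
Title: Exchange- and Dipolar-Coupled Radical Pairs in Continuous-Wave EPR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact simulation and analysis of continuous-wave EPR spectra of
    exchange- and dipolar-coupled organic radical pairs and triads, such as
    bis- and tris-trityl model compounds. Builds and diagonalizes the
    high-field spin Hamiltonian for two or three coupled electron spins with
    isotropic hyperfine nuclei, enumerates allowed transitions, classifies
    weak/intermediate/strong coupling regimes, simulates liquid-solution
    first-derivative spectra with natural-abundance 13C satellite lines and
    frozen-solution (Pake) powder patterns, converts dipolar couplings to
    inter-spin distances with the regime-dependent correction, extracts
    exchange couplings from satellite positions or full-spectrum fits, and
    extrapolates the temperature dependence of the exchange coupling to the
    glass transition. A seeded synthetic-spectrum generator emulating the
    model compounds makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
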