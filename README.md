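# spinpair

Exact simulation and analysis of continuous-wave EPR spectra of
exchange- and dipolar-coupled organic radical pairs and triads — the
situation encountered with bis- and tris-trityl model compounds used to
benchmark EPR distance measurements.

Trityl (tetrathiaaryl methyl) radicals have extremely narrow EPR lines, so
when two of them sit a few nanometres apart the spectrum reports directly on
the electron–electron couplings: the isotropic exchange coupling *J* and the
dipolar coupling *D* ∝ 1/r³. `spinpair` is built around the high-field spin
Hamiltonian for 2–3 coupled S = 1/2 electrons with secular isotropic
hyperfine nuclei (energies in MHz):

    H = Σᵢ (13.9962 gᵢ B₀ + Σₖ aₖ m_I,k) S_iz
      + Σ_i<j [ (J + d) S_iz S_jz + (J/2 − d/4)(S_i+ S_j− + S_i− S_j+) ],
    d = D (1 − 3 cos²θ)

which it diagonalizes exactly. On top of that it provides:

* **Coupling-regime classification** by the ratio |J − D/2| / |Δω|
  (weak ≤ 0.1, strong ≥ 10), with Δω = a_iso(¹³C)/2 for the ¹³C-satellite
  problem.
* **Liquid-solution simulation** of first-derivative spectra: α-proton
  multiplets, natural-abundance ¹³C satellite lines from an isotopomer
  expansion, and the strong-coupling halving of apparent hyperfine
  couplings.
* **Frozen-solution (powder) simulation**: Pake patterns with exchange
  shifts, the 1.5× strong-coupling stretch, axial g anisotropy, three-spin
  (60°-tilted) geometry and monoradical admixture; singularity extraction.
* **Regime-correct distance conversion**: r = (52.01/D)^(1/3) nm in the
  weak regime, r = (1.5·52.01/D)^(1/3) for couplings read off a stretched
  strong-coupling pattern, and the 87% apparent-distance bias when the wrong
  formula is used.
* **Fitting**: J from satellite positions (grid + refinement over exact
  diagonalization), full-spectrum Levenberg–Marquardt parameter recovery,
  and linear J(T) fitting with extrapolation to the glass transition
  (T_g ≈ ⅔ T_m).
* **A seeded synthetic-spectrum generator** (`make_fixture()`,
  `generate_spectrum()`) emulating the six model-compound parameter sets,
  so every analysis stage is testable without experimental data.

## Worked example

```r
library(spinpair)

# Which regime is a J = 77 MHz pair in, for the ipso-13C satellite problem?
classify_regime(J = 77, D = 0, delta_omega = delta_omega_13C(31.25))
#> <regime_report> |J - D/2|/|delta_omega| = 4.928 -> intermediate coupling

# Apparent alpha-proton splitting of that pair (localized coupling 0.3 MHz):
effective_satellite_splitting(J = 77, a_iso = 0.3)
#> [1] 0.15

# Distance from a 7.0 MHz coupling read off a strong-coupling Pake pattern:
distance_from_D(7.0, "strong")
#> <distance_result> D = 7 MHz (strong coupling) -> r = 2.234 nm

# Generate a noisy synthetic spectrum of the exchange-coupled biradical
# fixture and recover its parameters:
fx  <- make_fixture("4a")
sp  <- generate_spectrum(fx, axis = make_axis(12, 8192L),
                         noise_sd = 0.02, seed = 42)
fit_spectrum(sp, fx, seed = 42)
#> <fit_result> converged (objective 102.7)
#>   J_MHz = 76.1763 +- 1.72
#>   a_H_MHz = 0.300001 +- 0.000287
#>   gaussian_pp = 0.0820256 +- 0.00242
#>   lorentzian_pp = 0.0774116 +- 0.00258
#>   mono_fraction = 0.149293 +- 0.00272
#>   amplitude = 0.990205

# Temperature dependence of J, extrapolated to the glass transition:
fit_T <- fit_J_temperature(synthetic_jt_series("4a"))
extrapolate_J(fit_T, estimate_Tg(175))$J_MHz
#> [1] 22.00005
```

The fit recovers the generating truth (J = 77 MHz, a = 0.3 MHz, widths
0.08/0.08 MHz, 15% monoradical) within the reported uncertainties; the J(T)
line extrapolates from the room-temperature coupling (77 MHz) down to
22 MHz at the ~117 K glass transition.

A thin command-line wrapper is installed at `inst/cli/spinpair`:

```sh
spinpair distance --D 1.2 --regime weak      # r_nm: 3.512652618
spinpair regime --J 300 --a13C 31.25         # regime: strong
spinpair fixture --name 4a --simulate liquid --out 4a.dat --seed 1
```

## Documentation

The methods vignette (`vignettes/coupled-trityl-epr.Rmd`) describes the
model and its assumptions, the coupling-regime logic, the two meanings of
"D" in stretched patterns, the synthetic-data generator and its limits, and
every numerical choice (quadrature, kernels, tolerances, tie-breaks).
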