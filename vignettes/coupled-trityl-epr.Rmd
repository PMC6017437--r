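---
title: "Modelling exchange- and dipolar-coupled trityl radicals in cw EPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exchange- and dipolar-coupled trityl radicals in cw EPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinpair)
```

## The physical model

`spinpair` simulates and analyses continuous-wave EPR spectra of molecules
carrying two or three coupled carbon-centred (trityl) radicals. The model is
the high-field spin Hamiltonian, in frequency units (MHz), on the product
basis of the electron spins:

$$
H = \sum_i \left( \frac{\mu_B B_0}{h} g_i + \sum_{k \in i} a_k m_{I,k} \right) S_{iz}
  + \sum_{i<j} \left[ (J_{ij} + d_{ij})\, S_{iz} S_{jz}
  + \left( \frac{J_{ij}}{2} - \frac{d_{ij}}{4} \right)
    (S_{i+} S_{j-} + S_{i-} S_{j+}) \right],
$$

with $d_{ij} = D_{ij}\,(1 - 3\cos^2\theta_{ij})$ the orientation-dependent
dipolar coupling and $J_{ij}$ the isotropic exchange coupling
($J > 0$ antiferromagnetic). The assumptions built into this form are:

* **High field.** The electron Zeeman interaction (~9.4 GHz at X-band)
  dominates every other term, so non-secular dipolar terms are dropped. The
  zero-field / weak-field case is outside the model.
* **Secular hyperfine.** Nuclei enter only through $a_{\rm iso}\, m_I S_z$:
  no nuclear Zeeman, no nuclear flip-flops, no hyperfine anisotropy or
  quadrupole terms. A group of $n$ equivalent spin-1/2 nuclei is therefore
  fully described by its total projection, which is enumerated with binomial
  weights.
* **Boltzmann factors ignored.** $|J| \ll kT$ for all couplings considered
  (tens of MHz vs. thermal energies), so singlet and triplet manifolds are
  equally populated.
* **Pairwise couplings only.** The three-spin system is described by its
  three pair couplings; no three-spin exchange term is included.

`build_hamiltonian()` constructs this matrix exactly (dimension $2^n$,
$n \le 3$) and `transitions()` diagonalizes it with a dense symmetric
eigensolver. Transition intensities are squared matrix elements of the total
transverse spin operator $S_x = \sum_i S_{ix}$ between eigenstates; lines
below $10^{-6}$ of the strongest (configurable) are classed as forbidden.
All internal energies are MHz; the field axis is mT with
$\nu[\mathrm{MHz}] = 13.9962\, g\, B[\mathrm{mT}]$ (the $g$-dependent
conversion, not the free-electron shortcut).

The exchange Hamiltonian is diagonalized numerically throughout; no
perturbative closed form is used in the simulator itself. The closed AB-pair
expressions (line positions centre $\pm(C \pm J/2)$ with
$2C = \sqrt{\Delta\nu^2 + J^2}$) appear **only** in the test suite, as an
independent oracle against which the numerical eigensolutions are checked to
$10^{-9}$ MHz.

## Coupling regimes

The behaviour of a coupled pair is governed by the ratio
$|J - D/2| / |\Delta\omega|$, where $\Delta\omega$ is the difference of the
two spins' resonance frequencies. `classify_regime()` applies the
conventional thresholds: *weak* for ratio $\le 0.1$, *strong* for
$\ge 10$, *intermediate* in between. For a molecule carrying a single
$^{13}$C, $\Delta\omega = a_{\rm iso}(^{13}\mathrm{C})/2$
(`delta_omega_13C()`). When $\Delta\omega = 0$ the spins are equivalent and
the pair is strongly coupled by convention (ratio $\infty$).

In the strong limit, apparent hyperfine couplings halve and multiplicities
double: a pair with six 0.3 MHz protons on each centre shows the multiplet
of twelve equivalent 0.15 MHz protons (this equivalence is verified
numerically in the tests to 2% of peak amplitude). In the intermediate
regime no shortcut exists and the satellite pattern must come from
diagonalization; `effective_satellite_splitting()` provides a continuous
scalar summary (twice the intensity-weighted mean $|$offset$|$ of allowed
transitions outside the central region $|\nu| < a/8$), which reproduces
$a$ at $J = 0$ and $a/2$ for $|J| \gg a$. The line-resolved observable —
what one actually reads off a spectrum — is `satellite_positions()` plus
`satellite_doublet()`.

The sign of $J$ is never determined by cw lineshapes of this kind; all
fixture values are treated as magnitudes, and the API accepts signed values.

## Liquid-solution spectra and ¹³C satellites

`simulate_isotropic()` accumulates the exact stick spectrum over all nuclear
configurations and convolves it with the line shape. Natural-abundance
$^{13}$C satellites come from `isotopomer_expansion()`: the all-$^{12}$C
molecule plus one component per aryl-carbon site (ipso/ortho/meta/para, with
hyperfine constants 31.25/25.00/6.20/8.40 MHz), each weighted
$n\,p\,(1-p)^{N-1}$ with $p = 0.0107$. Multi-$^{13}$C isotopomers
($O(p^2)$, about 7% of molecules here) are discarded and the discarded
weight is reported in the spectrum metadata. The default equivalent-carbon
counts per trityl (3/6/6/3 for ipso/ortho/meta/para, three aryl rings per
unit) affect satellite intensities only, never positions, and are
configurable.

Line shapes are Voigt-by-convolution: a Gaussian of peak-to-peak derivative
width $\Delta_{pp}^G$ ($\sigma = \Delta_{pp}^G/2$) convolved with a
Lorentzian of width $\Delta_{pp}^L$ (HWHM $= \sqrt{3}\,\Delta_{pp}^L/2$).
Both kernels are sampled on the axis grid and renormalized to unit area;
first-derivative detection is applied analytically through the kernel, not
by numerical differentiation of the trace. Field-modulation distortion is
not modelled. The frequency axis is native; `spectrum_to_field()` performs
the first-order conversion to mT, adequate over the < 10 mT sweeps of
trityl spectra.

## Frozen-solution (powder) spectra

`simulate_powder()` averages over orientations with Gauss–Legendre
quadrature in $\cos\theta$ (default 256 nodes; doubling the grid moves
singularity estimates by $< 0.5\%$). Two modes exist:

* `mode = "full"`: exact diagonalization at every orientation. This is the
  regime-free route: with a large detuning $\Delta\omega$ between the spins
  it converges to the weak-coupling pattern
  ($\nu_\perp = |D \pm J|/2$, $\nu_\parallel = |{-2D} \pm J|/2$) and with
  equivalent spins to the strong-coupling pattern
  ($\nu_\perp = |1.5 D|/2$, $\nu_\parallel = |{-3D}|/2$), each verified to
  2% or better in the tests.
* `mode = "weak"`: the first-order secular treatment (each spin split by
  $\sum_j (d_{ij} + J_{ij}) m_j$ over partner projections), valid in the
  weak regime and cheap for the three-spin system.

For the three-spin (tris-trityl) geometry the three inter-spin axes are
placed in a plane at 60° to one another (equilateral triangle); the grid is
then expanded azimuthally (24 nodes) because the problem is no longer axial.
Axial $g$ anisotropy is evaluated at the same polar angle as the dipolar
term, i.e. the $g$ unique axis is taken along the inter-spin vector — at
X-band the trityl $g$ spread is a few MHz, so the residual correlation error
is far below the line width. Mixtures (biradical plus monoradical
contaminant) are combined after normalizing each component to unit
absorption area, so fractions are *signal* fractions; the mixture trace is
exactly the fraction-weighted component sum.

`pake_singularities()` reads the perpendicular singularities as the dominant
absorption maxima on each side of the pattern centre (parabolic sub-grid
refinement) and the parallel shoulders as the outermost local extrema of the
absorption gradient beyond the peaks. Convolution pulls the singularity
maxima inward by an amount proportional to the kernel width; where an
unbiased position is needed (the stretch ratio below), the extraction is
repeated at two kernel widths and extrapolated linearly to zero width.

## Distances and the two meanings of "D"

The point-dipole relation $D = 52.01\ \mathrm{MHz\,nm^3} / r^3$ links the
dipolar coupling to the inter-spin distance; the constant is used verbatim
(a $g_1 g_2/g_e^2$-scaled variant is available via `dipolar_constant()`),
and no spin-density delocalization correction is applied — the trityl spin
density is nearly symmetric about the central carbon, so delocalization
largely cancels.

In the strong-coupling regime the powder singularities appear 50% further
out than for an uncoupled pair at the same distance. The coupling constant
*read from the pattern* is therefore $1.5\times$ the point-dipole value, and
`distance_from_D(D, "strong")` applies $r = (1.5 \cdot 52.01 / D)^{1/3}$ to
that apparent value. This double meaning matters when building spin systems:
`pair_coupling()`'s `D_MHz` is always the *point-dipole* coupling entering
the Hamiltonian, so the strongly coupled fixtures carry
$D_{\rm dip} = D_{\rm apparent}/1.5$ (e.g. 7.0/1.5 ≈ 4.67 MHz), which makes
the simulated pattern, the printed apparent coupling and the printed
distance mutually consistent. Misreading a stretched pattern with the weak
formula biases distances to $1.5^{-1/3} \approx 87.4\%$ of truth
(`apparent_distance_bias()`); the simulated check in the test suite
reproduces this from an actual powder simulation. The intermediate regime
deliberately has **no** closed-form conversion — the functions raise an
error pointing to full simulation.

## Fitting

* `fit_J_from_satellites()` matches observed satellite line offsets to the
  nearest diagonalization-predicted allowed line per site, with a 1 MHz grid
  search over 0–500 MHz followed by local refinement; the standard error
  comes from the curvature of the objective. In the deep strong-coupling
  limit all satellite positions become $J$-independent; a flat objective is
  detected and reported as a lower bound $J \ge 10 \max \Delta\omega$
  rather than a sham estimate.
* `fit_spectrum()` is a bounded Levenberg–Marquardt fit of the full
  first-derivative trace over $J$, the localized proton coupling, both line
  widths and the monoradical fraction, with the amplitude profiled out
  analytically at every step. Initialization is staged (coarse
  data-independent grids over $J$ and $a$, then refinement) and
  deterministic; the seed argument is recorded for provenance. Standard
  errors are curvature-based; no bootstrap is attempted.
* `fit_J_temperature()` / `extrapolate_J()` fit the (approximately linear)
  temperature dependence of $J$ by ordinary least squares and evaluate the
  line at a target temperature, flagging extrapolation outside the measured
  range. `estimate_Tg()` implements the empirical two-thirds rule
  $T_g \approx \tfrac{2}{3} T_m$; for the MeOD/DCM-type glass with
  $T_m \approx 175$ K this gives $\approx 117$ K.

## The synthetic-data generator

`make_fixture()` encodes the six model-compound parameter sets:

| fixture | electrons | α-H (localized) | J (RT) | D read from pattern | monoradical |
|---|---|---|---|---|---|
| 1a | 1 | – | – | – | – |
| 2a | 2 | 6 × 0.3 MHz per centre | 0 | 1.2 MHz | 0 |
| 2b | 2 | 4 × 0.3 MHz | 0 | 1.2 MHz | 0 |
| 3a | 3 | 6 × 0.3 MHz | 0 | 3 × 1.2 MHz, 60° | 0 |
| 4a | 2 | 6 × 0.3 MHz | 77 MHz | 7.0 MHz (apparent) | 15% |
| 4b | 2 | 4 × 0.26 MHz | 75 MHz | 7.0 MHz (apparent) | 5% |

The localized couplings are stored; under strong exchange the simulation
itself produces the apparent halved-coupling doubled-multiplicity patterns
(0.15 MHz × 12 for 4a; 0.13 MHz × 8 for 4b, which is why 4b's localized
value is 0.26 MHz — it is fitted independently, not forced to 0.3/2).
Frozen-solution exchange couplings use the glass-transition extrapolations
(22/20 MHz). Frozen line widths are 2.36 MHz Gaussian + 1.00 MHz Lorentzian
peak-to-peak; liquid widths are not independently documented for these
compounds, so the generator uses 0.08 + 0.08 MHz, typical of
room-temperature trityl lines (~0.1–0.2 MHz) and consistent with partially
resolved 0.15 MHz multiplets inside a ≤ 0.03 mT envelope. The frozen
$g$ tensor is axial, (2.00370, 2.00370, 2.00310), mean 2.0035 — inside the
observed isotropic window with a few-MHz spread ("small anisotropy"); the
exact principal values are a config input, not a claim.

`generate_spectrum()` adds seeded white Gaussian noise scaled to the
peak-to-peak amplitude of the clean trace (noise_sd = 1/SNR) and an
optional low-order polynomial baseline. What the generator does **not**
emulate: conformer distributions of $J$ and $r$ (single values only),
$g$/hyperfine strain beyond the axial tensor, viscosity line broadening in
the supercooled range, field-modulation distortion, and multi-$^{13}$C
isotopomers. Passing the recovery tests therefore demonstrates correctness
of the estimation machinery under the stated noise model, not robustness to
every artefact of real spectra.

`synthetic_jt_series()` produces linear $J(T)$ series anchored at the
room-temperature and glass-transition couplings; the underlying measured
series is not tabulated anywhere, so these anchors are illustrative
fixtures for the fitting API, clearly non-authoritative.

## Numerical choices and problem sizes

* Dense symmetric `eigen()` on $4 \times 4$ / $8 \times 8$ matrices;
  degenerate eigenvectors are returned orthonormal by LAPACK, never an
  error. Nuclear configurations reuse a cached coupling matrix and update
  only the diagonal.
* Stick spectra are area-preservingly binned onto the axis (linear
  weight-sharing between neighbouring grid points); convolution is
  zero-padded FFT with power-of-two padding. Default axis: 4096 points,
  at least four points per 0.1 MHz feature over typical sweeps; an
  undersampled axis triggers a warning.
* Transitions closer than 0.1 MHz are merged (intensity-weighted) in
  reported summaries — "accidentally almost degenerate" lines count as one;
  the tolerance is an argument. Ties between equally intense satellite
  lines are resolved by merging, not by arbitrary index order.
* The parameter-recovery experiment (4a at SNR 50, ten seeds) runs on an
  oversampled ±12 MHz, 32768-point grid. The choice follows a Cramér–Rao
  analysis: at SNR 50 the two Voigt width components are identifiable to
  only ~6% (1σ) on a 4096-point axis, but to ~1.4% on the dense grid, which
  is what a 5% recovery requirement demands of the measurement design.
* Powder averages use 256 Gauss–Legendre nodes (×24 azimuthal nodes when
  non-axial); the stretch-ratio computation extrapolates singularity
  positions to zero kernel width from two widths (0.2 and 0.4 MHz).
* Degenerate inputs: $\Delta\omega = 0$ classifies as strong (ratio
  $\infty$); `D = 0, J = 0` powder collapses exactly to the
  single-orientation spectrum; a single temperature point refuses to fit.

## Command-line interface

The functions, scripts and this vignette are the primary interface; a thin
dispatcher (`run_cli()`, wrapped by the `inst/cli/spinpair` Rscript) exposes
`simulate`, `powder`, `regime`, `distance`, `fitj`, `jtemp` and `fixture`
subcommands with structured `key: value` output for shell pipelines. All
runs log their parameters, seed and package version to standard error and
are bit-for-bit reproducible at a fixed seed.

## Known limitations

Two or three electrons only (dimension $2^n$ with exact diagonalization);
isotropic $g$ in liquid and axial $g$ in frozen solution; no relaxation
($T_1$/$T_2$) or viscosity regime; no hyperfine anisotropy, so frozen
simulations absorb unresolved hyperfine into the line widths; point-dipole
distances only (no delocalization correction); single-conformer parameters
rather than distributions; no vendor raw-file formats (two-column ASCII with
headers only).
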