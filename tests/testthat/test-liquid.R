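# Liquid-solution simulation: isotopomer expansion, multiplets, satellites
# and line-shape handling.

test_that("isotopomer expansion reproduces the binomial single-13C weights", {
  sys <- spin_system(list(electron_spin()))
  # single site with 3 equivalent carbons, N = 3
  comps <- isotopomer_expansion(sys, site_counts = c(ipso = 3), abundance = 0.0107)
  w <- vapply(comps, `[[`, numeric(1), "weight")
  expect_equal(w[2], 3 * 0.0107 * (1 - 0.0107)^2, tolerance = 1e-12)
  expect_equal(sum(w) + attr(comps, "discarded"), 1, tolerance = 1e-9)
})

test_that("zero abundance collapses the expansion to one full-weight component", {
  sys <- spin_system(list(electron_spin()))
  comps <- isotopomer_expansion(sys, abundance = 0)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$weight, 1)
})

test_that("weights plus discarded remainder close to unity for the biradical", {
  fx <- make_fixture("4a")
  comps <- isotopomer_expansion(fx$system)
  w <- vapply(comps, `[[`, numeric(1), "weight")
  expect_equal(sum(w) + attr(comps, "discarded"), 1, tolerance = 1e-9)
  # one all-12C component plus one per site
  expect_length(comps, 1L + length(trityl_site_counts()))
})

test_that("six equivalent protons give the 1:6:15:20:15:6:1 septet", {
  sys <- spin_system(
    electrons = list(electron_spin()),
    nuclei = list(hyperfine_nucleus("1H", a_iso_MHz = 0.3, n_equivalent = 6))
  )
  st <- spinpair:::.stick_spectrum(sys)
  m <- merge_transitions(data.frame(offset_MHz = st$offset, intensity = st$weight),
                         tol = 0.01)
  expect_equal(nrow(m), 7L)
  expect_equal(m$offset_MHz, 0.3 * seq(-3, 3), tolerance = 1e-9)
  expect_equal(m$intensity / min(m$intensity), c(1, 6, 15, 20, 15, 6, 1),
               tolerance = 1e-9)
})

test_that("convolution kernels are normalized to unit area", {
  dx <- 0.01
  for (k in list(spinpair:::.gauss_kernel(dx, 0.2),
                 spinpair:::.lorentz_kernel(dx, 0.2, n_axis = 8192L)))
    expect_equal(sum(k) * dx, 1, tolerance = 1e-6)
  # derivative kernels integrate to zero
  expect_equal(sum(spinpair:::.gauss_kernel(dx, 0.2, derivative = TRUE)) * dx, 0,
               tolerance = 1e-8)
})

test_that("absorption integral equals the accumulated transition weight", {
  sys <- spin_system(
    electrons = list(electron_spin()),
    nuclei = list(hyperfine_nucleus("1H", a_iso_MHz = 0.3, n_equivalent = 6))
  )
  sp <- simulate_isotropic(sys, axis = make_axis(5), isotopomers = FALSE,
                           ls = lineshape(0.08, 0.08), derivative_order = 0L)
  expect_equal(sum(sp$intensity) * (sp$axis[2] - sp$axis[1]),
               sp$metadata$total_weight, tolerance = 1e-3)
})

test_that("double integral is invariant under J, D and line widths", {
  base <- NULL
  for (J in c(0, 75)) for (g in c(0.06, 0.12)) {
    sys <- spin_system(
      electrons = list(electron_spin("A"), electron_spin("B")),
      nuclei = list(hyperfine_nucleus("1H", a_iso_MHz = 0.3, n_equivalent = 4,
                                      attached_to = 1L)),
      couplings = list(pair_coupling(c(1, 2), J_MHz = J))
    )
    sp <- simulate_isotropic(sys, axis = make_axis(10), isotopomers = FALSE,
                             ls = lineshape(g, 0.05))
    di <- double_integral(sp)
    if (is.null(base)) base <- di
    expect_equal(di, base, tolerance = 5e-3)
  }
})

test_that("strongly coupled pair mimics a single spin with halved couplings", {
  # 6+6 protons at 0.3 MHz under J = 77 MHz vs 12 equivalent protons at
  # 0.15 MHz on a monoradical: the apparent multiplets must agree.
  axis <- make_axis(3)
  fx <- make_fixture("4a")
  pair <- spinpair:::.fixture_liquid_mixture(fx, mono_fraction = 0)$components[[1]]
  sp_pair <- simulate_isotropic(pair, axis, isotopomers = FALSE,
                                ls = lineshape(0.08, 0.08))
  mono <- spin_system(
    electrons = list(electron_spin(g_iso = fx$truth$g_iso)),
    nuclei = list(hyperfine_nucleus("1H", a_iso_MHz = 0.15, n_equivalent = 12))
  )
  sp_mono <- simulate_isotropic(mono, axis, isotopomers = FALSE,
                                ls = lineshape(0.08, 0.08))
  y1 <- sp_pair$intensity / max(abs(sp_pair$intensity))
  y2 <- sp_mono$intensity / max(abs(sp_mono$intensity))
  expect_lt(max(abs(y1 - y2)), 0.02)
})

test_that("satellite doublets move from the full to the half splitting with J", {
  hf <- trityl_hfcc()
  # no exchange: full doublet at +- a/2
  d0 <- satellite_doublet(satellite_positions(J = 0, site = "ipso"))
  expect_equal(unname(d0["upper"] - d0["lower"]), hf[["ipso"]], tolerance = 1e-9)
  # strong coupling: half splitting (meta site is deep in the strong regime)
  dm <- satellite_doublet(satellite_positions(J = 77, site = "meta"),
                          merge_tol = 0.2)
  expect_equal(unname(dm["upper"] - dm["lower"]), hf[["meta"]] / 2,
               tolerance = 1e-6)
  # J = 300 ipso: within 2% of a/2
  d300 <- satellite_doublet(satellite_positions(J = 300, site = "ipso"),
                            merge_tol = 0.5)
  expect_equal(unname(d300["upper"] - d300["lower"]), hf[["ipso"]] / 2,
               tolerance = 0.02 * hf[["ipso"]])
  # intermediate J = 75 ipso: all four AB lines present, matching the oracle
  lines <- satellite_positions(J = 75, site = "ipso")
  oracle <- ab_oracle(hf[["ipso"]] / 2, 0, 75)
  expect_equal(sort(lines$offset_MHz[lines$m13C == 0.5]), sort(oracle$freq),
               tolerance = 1e-9)
})

test_that("satellite offsets are symmetric about the central line", {
  for (J in c(0, 75, 300)) {
    lines <- satellite_positions(J = J, site = "ortho")
    expect_equal(sort(lines$offset_MHz), sort(-lines$offset_MHz), tolerance = 1e-8)
  }
})

test_that("satellite line positions are continuous in J", {
  Js <- seq(0, 200, by = 2)
  prev <- NULL
  for (J in Js) {
    pos <- sort(satellite_positions(J = J, site = "ipso",
                                    intensity_floor = 0)$offset_MHz)
    if (!is.null(prev))
      expect_lt(max(abs(pos - prev)), 2.5)  # |d nu / d J| <= 1 per line
    prev <- pos
  }
})

test_that("an unknown satellite site is rejected with the known sites listed", {
  expect_error(satellite_positions(J = 0, site = "gamma"), "unknown site")
})

test_that("a too-coarse axis triggers a resolution warning", {
  sys <- spin_system(list(electron_spin()),
                     nuclei = list(hyperfine_nucleus("1H", a_iso_MHz = 0.3)))
  expect_warning(
    simulate_isotropic(sys, axis = make_axis(30, 256L), isotopomers = FALSE,
                       ls = lineshape(0.08, 0.08)),
    "resolution")
})
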