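# Spin Hamiltonian construction, exact diagonalization and coupling-regime
# classification.

test_that("uncoupled limit: secular 13C shift appears on the diagonal only", {
  sys <- pair_with_nucleus(J = 0, a = 31.25)
  B0 <- resonance_field_mT(sys)
  H_up <- build_hamiltonian(sys, B0, nuclear_config = 0.5)
  H_dn <- build_hamiltonian(sys, B0, nuclear_config = -0.5)
  expect_true(all(H_up[upper.tri(H_up)] == 0))
  # basis order: |uu>, |ud>, |du>, |dd>; electron-1 projection +-1/2
  shift <- H_up - H_dn
  expect_equal(diag(shift), 31.25 * c(0.5, 0.5, -0.5, -0.5))
})

test_that("pseudo-secular exchange puts J/2 on the flip-flop element", {
  sys <- pair_with_nucleus(J = 75, a = 31.25)
  H <- build_hamiltonian(sys, nuclear_config = 0.5)
  expect_equal(H[2, 3], 75 / 2)
  expect_equal(H[3, 2], 75 / 2)
})

test_that("Hamiltonian is Hermitian and its trace ignores pseudo-secular terms", {
  set.seed(42)
  for (rep in 1:20) {
    J <- runif(1, -300, 300); D <- runif(1, 0, 50); th <- runif(1, 0, pi)
    sys <- spin_system(
      electrons = list(electron_spin("A", g_iso = 2.0030),
                       electron_spin("B", g_iso = 2.0040)),
      nuclei = list(hyperfine_nucleus("13C", a_iso_MHz = runif(1, 1, 40))),
      couplings = list(pair_coupling(c(1, 2), J_MHz = J, D_MHz = D, theta = th))
    )
    H <- build_hamiltonian(sys, nuclear_config = sample(c(-0.5, 0.5), 1))
    expect_identical(H, t(H))
    H0 <- build_hamiltonian(bare_pair(J = 0, D = 0))
    HJ <- build_hamiltonian(bare_pair(J = J, D = D))
    expect_equal(sum(diag(HJ)), sum(diag(H0)), tolerance = 1e-12)
  }
})

test_that("more than three electrons is rejected as unsupported", {
  els <- lapply(1:4, function(i) electron_spin(paste0("e", i)))
  expect_error(spin_system(els), "unsupported")
})

test_that("a single electron with one 13C gives an equal-intensity doublet", {
  sys <- spin_system(
    electrons = list(electron_spin()),
    nuclei = list(hyperfine_nucleus("13C", a_iso_MHz = 31.25))
  )
  up <- transitions(sys, nuclear_config = 0.5)
  dn <- transitions(sys, nuclear_config = -0.5)
  expect_equal(nrow(up), 1L)
  expect_equal(up$offset_MHz - dn$offset_MHz, 31.25, tolerance = 1e-9)
  expect_equal(up$intensity, dn$intensity)
})

test_that("the intermediate-regime pair shows exactly four allowed transitions", {
  sys <- pair_with_nucleus(J = 75, a = 31.25)
  ts <- transitions(sys, nuclear_config = 0.5)
  expect_equal(nrow(ts), 4L)
})

test_that("numerical transitions match the AB closed form to 1e-9 MHz", {
  sys0 <- pair_with_nucleus(J = 0, a = 1)
  nu0 <- sys0$mw_frequency_GHz * 1000
  set.seed(7)
  for (rep in 1:100) {
    J <- runif(1, 0, 500); a <- runif(1, 0.5, 40)
    ts <- transitions(pair_with_nucleus(J = J, a = a), nuclear_config = 0.5,
                      intensity_floor = 0)
    oracle <- ab_oracle(a / 2, 0, J)
    expect_equal(sort(ts$offset_MHz), sort(oracle$freq), tolerance = 1e-9)
    ord_n <- order(ts$offset_MHz); ord_o <- order(oracle$freq)
    expect_equal(ts$intensity[ord_n] / sum(ts$intensity),
                 oracle$intensity[ord_o] / sum(oracle$intensity),
                 tolerance = 1e-9)
  }
})

test_that("total transition intensity is conserved across J and D", {
  totals <- c()
  for (J in c(0, 10, 75, 300))
    for (D in c(0, 5, 20)) {
      ts <- transitions(pair_with_nucleus(J = J, a = 31.25, D = D),
                        nuclear_config = 0.5, intensity_floor = 0)
      totals <- c(totals, attr(ts, "total_intensity"))
    }
  expect_equal(totals, rep(totals[1], length(totals)), tolerance = 1e-12)
})

test_that("J = 0, D = 0 reproduces the first-order stick spectrum exactly", {
  sys <- spin_system(
    electrons = list(electron_spin("A"), electron_spin("B")),
    nuclei = list(hyperfine_nucleus("1H", a_iso_MHz = 0.3, n_equivalent = 6,
                                    attached_to = 1L))
  )
  for (M in seq(-3, 3)) {
    ts <- transitions(sys, nuclear_config = M, intensity_floor = 0)
    expect_equal(sort(unique(round(ts$offset_MHz, 9))), sort(unique(c(0.3 * M, 0))),
                 tolerance = 1e-9)
  }
})

test_that("weak-coupling lines shift by J/2 to first order", {
  a <- 31.25
  J <- 0.1   # |J| << delta_omega = a/2
  ts0 <- transitions(pair_with_nucleus(J = 0, a = a), nuclear_config = 0.5)
  tsJ <- transitions(pair_with_nucleus(J = J, a = a), nuclear_config = 0.5)
  shifts <- sort(tsJ$offset_MHz) - sort(ts0$offset_MHz)
  # second-order corrections are bounded by J^2 / delta_omega
  expect_lt(max(abs(abs(shifts) - J / 2)), J^2 / (a / 2))
})

test_that("coupling-regime classification follows the |J - D/2|/|dw| thresholds", {
  r_strong <- classify_regime(J = 300, D = 0, delta_omega = delta_omega_13C(31.25))
  expect_equal(r_strong$ratio, 19.2)
  expect_identical(r_strong$regime, "strong")
  r_mid <- classify_regime(J = 75, D = 0, delta_omega = delta_omega_13C(31.25))
  expect_equal(r_mid$ratio, 4.8)
  expect_identical(r_mid$regime, "intermediate")
  expect_identical(classify_regime(0, 0, 10)$regime, "weak")
  # equivalent spins: strong by convention
  r_eq <- classify_regime(J = 0, D = 7, delta_omega = 0)
  expect_identical(r_eq$regime, "strong")
  expect_identical(r_eq$ratio, Inf)
  # boundary values belong to the closed regimes
  expect_identical(classify_regime(1, 0, 10)$regime, "weak")
  expect_identical(classify_regime(100, 0, 10)$regime, "strong")
})

test_that("apparent satellite splitting interpolates from a to a/2 with J", {
  a <- 0.3
  expect_equal(effective_satellite_splitting(0, a), a, tolerance = 1e-9)
  expect_equal(effective_satellite_splitting(77, a), a / 2, tolerance = 1e-6)
  mid <- effective_satellite_splitting(75, 31.25)
  expect_gt(mid, 31.25 / 2)
  expect_lt(mid, 31.25)
  # monotone approach of the 50% reduction as |J|/a grows
  ratios <- effective_satellite_splitting(c(5, 10, 20, 50, 100, 300), a = 1) / 1
  expect_true(all(diff(ratios) < 0))
  expect_equal(ratios[length(ratios)], 0.5, tolerance = 1e-3)
})

test_that("nearly degenerate transitions merge at the reporting tolerance", {
  ts <- data.frame(offset_MHz = c(-0.05, 0.0, 0.04, 5), intensity = c(1, 1, 2, 1))
  m <- merge_transitions(ts, tol = 0.1)
  expect_equal(nrow(m), 2L)
  expect_equal(m$intensity, c(4, 1))
  expect_equal(m$offset_MHz[1], (-0.05 + 0 + 2 * 0.04) / 4)
})
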