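# Frozen-solution (powder) simulation: orientation quadrature, dipolar
# splittings in each regime, Pake singularities and mixtures.

test_that("powder grid weights are a probability measure", {
  for (g in list(powder_grid(64), powder_grid(64, n_phi = 8))) {
    expect_true(all(g$weights >= 0))
    expect_equal(sum(g$weights), 1, tolerance = 1e-9)
    expect_equal(rowSums(g$directions^2), rep(1, nrow(g$directions)),
                 tolerance = 1e-12)
  }
})

test_that("closed-form dipolar splittings reproduce the regime formulas", {
  expect_equal(dipolar_splitting(pi / 2, D = 10, J = 0, regime = "weak"), 5)
  expect_equal(abs(dipolar_splitting(0, D = 10, J = 0, regime = "weak")), 10)
  expect_equal(dipolar_splitting(pi / 2, D = 7, regime = "strong"), 5.25)
  expect_equal(abs(dipolar_splitting(0, D = 7, regime = "strong")), 10.5)
  # perpendicular weak shift carries the exchange: |D + J|/2
  expect_equal(dipolar_splitting(pi / 2, D = 10, J = 4, regime = "weak"), 7)
  expect_error(dipolar_splitting(pi / 2, D = 10, regime = "intermediate"),
               "diagonalization")
})

test_that("full diagonalization converges to the weak and strong closed forms", {
  thetas <- c(0.2, 0.7, pi / 2, 2.1)
  D <- 10; J <- 3
  # weak: large detuning
  full_w <- dipolar_splitting(thetas, D, J, regime = "full", delta_omega = 2000)
  weak <- dipolar_splitting(thetas, D, J, regime = "weak")
  expect_equal(abs(full_w), abs(weak), tolerance = 0.02)
  # strong: equivalent spins, any J
  full_s <- dipolar_splitting(thetas, D, J = 100, regime = "full", delta_omega = 0)
  strong <- dipolar_splitting(thetas, D, regime = "strong")
  expect_equal(abs(full_s), abs(strong), tolerance = 1e-6)
})

test_that("with no anisotropy the powder equals the single orientation", {
  sys <- bare_pair(J = 0, D = 0)
  axis <- make_axis(5, 2048L)
  sp_pow <- simulate_powder(sys, grid = powder_grid(32), ls = lineshape(0.5, 0.2),
                            axis = axis, mode = "full")
  sp_one <- simulate_isotropic(sys, axis, ls = lineshape(0.5, 0.2),
                               isotopomers = FALSE)
  y1 <- sp_pow$intensity / max(abs(sp_pow$intensity))
  y2 <- sp_one$intensity / max(abs(sp_one$intensity))
  expect_lt(max(abs(y1 - y2)), 1e-6)
})

test_that("weak-coupling Pake pattern has nu_par = 2 nu_perp at J = 0", {
  sys <- bare_pair(J = 0, D = 10, frozen_axis = TRUE)
  sp <- simulate_powder(sys, grid = powder_grid(256), ls = lineshape(0.5, 0.2),
                        axis = make_axis(25, 8192L), mode = "weak",
                        derivative_order = 0L)
  s <- pake_singularities(sp)
  expect_equal(s$nu_perp, 5, tolerance = 0.08)   # inward kernel bias ~ sigma
  expect_equal(s$nu_par, 10, tolerance = 0.02)
  expect_equal(s$nu_par / s$nu_perp, 2, tolerance = 0.08)
})

test_that("doubling the orientation grid moves singularities by < 0.5%", {
  sys <- bare_pair(J = 100, D = 10)
  est <- vapply(c(256L, 512L), function(nt) {
    sp <- simulate_powder(sys, grid = powder_grid(nt), ls = lineshape(0.4, 0.1),
                          axis = make_axis(25, 8192L), mode = "full",
                          derivative_order = 0L)
    pake_singularities(sp)$nu_perp
  }, numeric(1))
  expect_lt(abs(est[2] - est[1]) / est[1], 0.005)
})

test_that("a mixture spectrum is the exact fraction-weighted component sum", {
  pair <- make_fixture("4a")$system_frozen
  mono <- make_fixture("4a")$mono_system_frozen
  axis <- make_axis(25, 2048L)
  grid <- powder_grid(64)
  ls <- lineshape(2.36, 1.00)
  sp_mix <- simulate_powder(mixture_model(list(pair, mono), c(0.85, 0.15)),
                            grid = grid, ls = ls, axis = axis)
  sp_a <- simulate_powder(pair, grid = grid, ls = ls, axis = axis)
  sp_b <- simulate_powder(mono, grid = grid, ls = ls, axis = axis)
  manual <- 0.85 * sp_a$intensity / double_integral(sp_a) +
    0.15 * sp_b$intensity / double_integral(sp_b)
  expect_equal(sp_mix$intensity, manual, tolerance = 1e-12)
})

test_that("the strong-coupling frozen pair shows the stretched Pake doublet plus monoradical line", {
  fx <- make_fixture("4a")
  # at a narrow probe width the singularities sit at half the apparent
  # 7.0 MHz splitting even though the Hamiltonian carries D/1.5
  sp_narrow <- simulate_powder(fx$system_frozen, grid = powder_grid(256),
                               ls = lineshape(0.5, 0.2),
                               axis = make_axis(15, 8192L),
                               derivative_order = 0L)
  s <- pake_singularities(sp_narrow)
  expect_equal(s$nu_perp, 7.0 / 2, tolerance = 0.1)
  # the monoradical admixture raises the centre of the area-normalized
  # full-width spectrum relative to the pure biradical
  axis <- make_axis(25, 4096L)
  grid <- powder_grid(128)
  sp_mix <- generate_spectrum(fx, mode = "frozen", seed = 1, axis = axis,
                              grid = grid)
  sp_pure <- simulate_powder(fx$system_frozen, grid = grid,
                             ls = fx$frozen_lineshape, axis = axis)
  a_mix <- integrate_spectrum(sp_mix)$intensity
  a_pure <- integrate_spectrum(sp_pure)$intensity
  mid <- which.min(abs(axis))
  expect_gt(a_mix[mid] / double_integral(sp_mix),
            a_pure[mid] / double_integral(sp_pure))
})

test_that("the three-spin triangle broadens the line relative to one pair at equal D", {
  ls <- lineshape(2.36, 1.00)
  axis <- make_axis(15, 2048L)
  sp2 <- simulate_powder(make_fixture("2a")$system_frozen,
                         grid = powder_grid(96), ls = ls, axis = axis,
                         mode = "weak", derivative_order = 0L)
  sp3 <- simulate_powder(make_fixture("3a")$system_frozen,
                         grid = powder_grid(48, n_phi = 16), ls = ls,
                         axis = axis, mode = "weak", derivative_order = 0L)
  width_of <- function(sp) {
    y <- sp$intensity / max(sp$intensity)
    range_x <- range(sp$axis[y > 0.5])
    diff(range_x)
  }
  expect_gt(width_of(sp3), width_of(sp2))
})

test_that("unresolved singularities raise an extraction error", {
  sys <- bare_pair(J = 0, D = 0.5, frozen_axis = TRUE)
  sp <- simulate_powder(sys, grid = powder_grid(64), ls = lineshape(3, 1),
                        axis = make_axis(15, 2048L), mode = "weak",
                        derivative_order = 0L)
  expect_error(pake_singularities(sp), "not resolved")
})

test_that("noisy singularities stay within one kernel width of noiseless values", {
  sys <- bare_pair(J = 100, D = 10)
  sp <- simulate_powder(sys, grid = powder_grid(256), ls = lineshape(1.0, 0.3),
                        axis = make_axis(25, 4096L), derivative_order = 0L)
  s0 <- pake_singularities(sp)
  set.seed(20)
  noisy <- sp
  noisy$intensity <- sp$intensity + rnorm(length(sp$intensity),
                                          0, diff(range(sp$intensity)) / 20)
  sn <- pake_singularities(noisy, smooth = 15L)
  kernel_w <- 1.0 + 0.3
  expect_lt(abs(sn$nu_perp - s0$nu_perp), kernel_w)
})
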