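# Independent closed-form oracles and small builders shared by the tests.

# AB spin-pair oracle (textbook closed form, independent of the package's
# numerical diagonalization): two spins at Larmor frequencies nu1, nu2
# coupled by J (all MHz) give four lines at centre +- (C +- J/2) with
# 2C = sqrt((nu1 - nu2)^2 + J^2); outer lines carry intensity
# (1 - sin 2phi)/4 and inner lines (1 + sin 2phi)/4, sin 2phi = J / 2C.
ab_oracle <- function(nu1, nu2, J) {
  dnu <- nu1 - nu2
  C <- sqrt(dnu^2 + J^2) / 2
  centre <- (nu1 + nu2) / 2
  s <- if (C > 0) J / (2 * C) else 0
  data.frame(
    freq = centre + c(C + J / 2, C - J / 2, -(C - J / 2), -(C + J / 2)),
    intensity = c(1 - s, 1 + s, 1 + s, 1 - s) / 4
  )
}

# Bare coupled pair with one spin-1/2 nucleus of coupling `a` on electron 1.
pair_with_nucleus <- function(J = 0, a = 31.25, D = 0, theta = pi / 2) {
  spin_system(
    electrons = list(electron_spin("A"), electron_spin("B")),
    nuclei = list(hyperfine_nucleus("13C", a_iso_MHz = a, attached_to = 1L)),
    couplings = list(pair_coupling(c(1, 2), J_MHz = J, D_MHz = D, theta = theta))
  )
}

# Bare coupled pair without nuclei, optionally detuned by delta_omega.
bare_pair <- function(J = 0, D = 0, delta_omega = 0, frozen_axis = FALSE) {
  spin_system(
    electrons = list(electron_spin("A", nu_offset_MHz = delta_omega / 2),
                     electron_spin("B", nu_offset_MHz = -delta_omega / 2)),
    couplings = list(pair_coupling(c(1, 2), J_MHz = J, D_MHz = D,
                                   axis = if (frozen_axis) c(0, 0, 1) else NULL))
  )
}

# Perpendicular Pake singularity with the kernel-width bias removed by
# linear extrapolation of the peak position to zero convolution width.
nu_perp_zero_width <- function(system, D_span, window = NULL,
                               n_theta = 256L, widths = c(0.2, 0.4)) {
  perp <- vapply(widths, function(pp) {
    sp <- simulate_powder(system, grid = powder_grid(n_theta),
                          ls = lineshape(gaussian_pp = pp),
                          axis = make_axis(D_span, 16384L),
                          mode = "full", derivative_order = 0L)
    pake_singularities(sp, window = window)$nu_perp
  }, numeric(1))
  2 * perp[1] - perp[2]
}
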