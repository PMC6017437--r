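# Frozen-solution spectra: orientation-averaged dipolar (Pake) patterns with
# exchange shifts, g anisotropy, three-spin geometry and monoradical
# admixture; singularity extraction for distance analysis.

#' Orientation grid for powder averaging
#'
#' Gauss-Legendre quadrature in cos(theta) over the hemisphere (exact sin
#' theta weighting), optionally crossed with a uniform azimuthal grid for
#' non-axial problems (three-spin geometries).
#'
#' @param n_theta Number of polar nodes (default 256).
#' @param n_phi Number of azimuthal nodes (default 1: axial problem).
#' @param scheme Quadrature label; only `"gauss_legendre"` is implemented.
#' @return Object of class `powder_grid` with unit vectors `directions`
#'   (n x 3) and `weights` summing to 1.
#' @export
#' @examples
#' g <- powder_grid(256)
#' sum(g$weights)
powder_grid <- function(n_theta = 256L, n_phi = 1L, scheme = "gauss_legendre") {
  if (scheme != "gauss_legendre") stop_validation("unknown quadrature scheme: ", scheme)
  gl <- pracma::gaussLegendre(n_theta, 0, 1)
  u <- gl$x                      # cos(theta) on the hemisphere
  wu <- gl$w                     # integrates du exactly
  st <- sqrt(pmax(0, 1 - u^2))
  if (n_phi <= 1L) {
    dirs <- cbind(st, 0, u)
    w <- wu
  } else {
    phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
    dirs <- do.call(rbind, lapply(seq_len(n_phi), function(j)
      cbind(st * cos(phi[j]), st * sin(phi[j]), u)))
    w <- rep(wu / n_phi, times = n_phi)
  }
  structure(list(directions = dirs, weights = w / sum(w),
                 n_theta = as.integer(n_theta), n_phi = as.integer(n_phi),
                 scheme = scheme),
            class = "powder_grid")
}

#' Define a mixture of spin systems
#'
#' @param components List of [spin_system()] objects.
#' @param fractions Numeric fractions in `[0, 1]` summing to 1 (within 1e-9).
#'   Fractions are signal (double-integral) fractions.
#' @return Object of class `mixture_model`.
#' @export
mixture_model <- function(components, fractions) {
  if (inherits(components, "spin_system")) components <- list(components)
  if (length(components) != length(fractions))
    stop_validation("components and fractions must have equal length")
  if (any(fractions < 0 | fractions > 1))
    stop_validation("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_validation("fractions must sum to 1 within 1e-9")
  for (s in components)
    if (!inherits(s, "spin_system")) stop_validation("components must be spin_system objects")
  structure(list(components = components, fractions = as.numeric(fractions)),
            class = "mixture_model")
}

#' Orientation-dependent dipolar line offset
#'
#' Signed frequency offset (MHz) of one line of the dipolar doublet at
#' orientation `theta`, in one of three modes. Weak coupling:
#' `(d + J) / 2` with `d = D (1 - 3 cos^2 theta)` — at theta = pi/2 this is
#' `|D + J| / 2` and at theta = 0 `|-2D + J| / 2` (J > 0 convention). Strong
#' coupling: `1.5 d / 2`, the exchange-independent stretched pattern. Full:
#' exact diagonalization of the pair with detuning `delta_omega`; converges
#' to the weak form for large detuning and to the strong form for
#' `delta_omega = 0`.
#'
#' @param theta Angle (rad) between inter-spin vector and field.
#' @param D Dipolar coupling constant in MHz.
#' @param J Exchange coupling constant in MHz.
#' @param regime `"weak"`, `"strong"` or `"full"`. The intermediate regime
#'   has no closed form; request `"full"`.
#' @param delta_omega Resonance-frequency difference (MHz) of the two spins,
#'   used by the full mode.
#' @return Signed offset in MHz (vectorized over `theta`).
#' @export
#' @examples
#' dipolar_splitting(pi / 2, D = 10, J = 0, regime = "weak")    # 5
#' dipolar_splitting(pi / 2, D = 7, regime = "strong")          # 5.25
dipolar_splitting <- function(theta, D, J = 0,
                              regime = c("weak", "strong", "full"),
                              delta_omega = 0) {
  regime <- as.character(regime[1])
  if (regime == "intermediate")
    stop("no closed form exists in the intermediate regime; the spectrum must be ",
         "obtained by diagonalization of the complete spin Hamiltonian ",
         "(use regime = \"full\")")
  regime <- match.arg(regime)
  d <- D * (1 - 3 * cos(theta)^2)
  if (regime == "weak") return((d + J) / 2)
  if (regime == "strong") return(STRONG_COUPLING_STRETCH * d / 2)
  vapply(seq_along(d), function(k) {
    sys <- spin_system(
      electrons = list(electron_spin("A", nu_offset_MHz = delta_omega / 2),
                       electron_spin("B", nu_offset_MHz = -delta_omega / 2)),
      couplings = list(pair_coupling(c(1, 2), J_MHz = J, D_MHz = D,
                                     theta = theta[min(k, length(theta))]))
    )
    ts <- transitions(sys, intensity_floor = 1e-6)
    off <- sort(ts$offset_MHz, decreasing = TRUE)
    mag <- if (length(off) >= 2) (off[1] - off[2]) / 2 else 0
    s <- sign(d[k] + J)
    if (s == 0) s <- 1
    mag * s
  }, numeric(1))
}

# Stick spectrum of one component over a powder grid.
.powder_sticks <- function(system, grid, mode = "full",
                           intensity_floor = 1e-6) {
  n <- n_electrons(system)
  g_ref <- mean_g(system)
  B0 <- resonance_field_mT(system)
  pos <- numeric(0); wt <- numeric(0)
  for (o in seq_along(grid$weights)) {
    dir <- grid$directions[o, ]
    w <- grid$weights[o]
    if (mode == "full" || n == 1L) {
      ts <- transitions(system, B0_mT = B0, nuclear_config = NULL,
                        intensity_floor = intensity_floor,
                        field_direction = dir)
      pos <- c(pos, ts$offset_MHz)
      wt <- c(wt, ts$intensity * w)
    } else if (mode == "weak") {
      # First-order secular treatment: each spin's line is split by the sum
      # of its couplings with the partner projections m_j = +-1/2.
      nu_off <- vapply(seq_len(n), function(i) {
        e <- system$electrons[[i]]
        MHZ_PER_MT_G * (.g_eff(e, dir) - g_ref) * B0 + e$nu_offset_MHz
      }, numeric(1))
      for (i in seq_len(n)) {
        partners <- setdiff(seq_len(n), i)
        coups <- Filter(function(cp) i %in% cp$spins, system$couplings)
        sec <- vapply(partners, function(j) {
          cp <- Filter(function(cp) all(sort(c(i, j)) == cp$spins), coups)
          if (!length(cp)) return(0)
          .dip_weight(cp[[1]], dir) + cp[[1]]$J_MHz
        }, numeric(1))
        signs <- as.matrix(expand.grid(rep(list(c(-0.5, 0.5)), length(partners))))
        for (r in seq_len(nrow(signs))) {
          pos <- c(pos, nu_off[i] + sum(sec * signs[r, ]))
          wt <- c(wt, w * 0.25)
        }
      }
    } else stop_validation("unknown powder mode: ", mode)
  }
  list(offset = pos, weight = wt)
}

#' Simulate a frozen-solution (powder) cw spectrum
#'
#' Per orientation, either full diagonalization with the theta-dependent
#' dipolar term (`mode = "full"`) or the first-order secular treatment valid
#' in the weak-coupling regime (`mode = "weak"`), accumulated with sin-theta
#' quadrature weights and convolved with the line shape. Components are
#' normalized to unit absorption area and weighted by their mixture
#' fractions, so a monoradical component adds an unsplit central line scaled
#' by its fraction.
#'
#' @param mixture A [mixture_model()] or single [spin_system()].
#' @param grid A [powder_grid()]. When any component carries couplings with
#'   non-collinear axes (three-spin geometry) and `n_phi = 1`, the grid is
#'   expanded azimuthally (24 nodes).
#' @param ls A [lineshape()] in MHz (frozen trityl default: Gaussian 2.36,
#'   Lorentzian 1.00 peak-to-peak).
#' @param axis Frequency-offset axis in MHz (default auto).
#' @param mode `"full"` (exact diagonalization) or `"weak"` (first-order).
#' @param derivative_order 0 or 1.
#' @param intensity_floor Relative floor for allowed transitions.
#' @param check_convergence If `TRUE`, re-simulate at twice `n_theta` and
#'   warn when the two traces differ by more than 1% of the peak (grid too
#'   coarse).
#' @return An [epr_spectrum()].
#' @export
#' @examples
#' pair <- spin_system(list(electron_spin(), electron_spin()),
#'                     couplings = list(pair_coupling(c(1, 2), D_MHz = 10)))
#' sp <- simulate_powder(pair, grid = powder_grid(128), mode = "weak",
#'                       axis = make_axis(20, 2048))
simulate_powder <- function(mixture, grid = powder_grid(),
                            ls = lineshape(gaussian_pp = 2.36, lorentzian_pp = 1.00),
                            axis = NULL, mode = c("full", "weak"),
                            derivative_order = 1L, intensity_floor = 1e-6,
                            check_convergence = FALSE) {
  mode <- match.arg(mode)
  if (inherits(mixture, "spin_system")) mixture <- mixture_model(mixture, 1)
  stopifnot(inherits(mixture, "mixture_model"))
  needs_phi <- any(vapply(mixture$components, function(s)
    sum(vapply(s$couplings, function(cp) !is.null(cp$axis), logical(1))) > 1,
    logical(1)))
  if (needs_phi && grid$n_phi == 1L)
    grid <- powder_grid(grid$n_theta, n_phi = 24L, scheme = grid$scheme)
  all_sticks <- lapply(mixture$components, .powder_sticks, grid = grid,
                       mode = mode, intensity_floor = intensity_floor)
  if (is.null(axis)) {
    span <- max(abs(unlist(lapply(all_sticks, `[[`, "offset")))) +
      20 * max(ls$gaussian_pp, ls$lorentzian_pp)
    axis <- make_axis(max(span, 1))
  }
  y <- numeric(length(axis))
  for (k in seq_along(all_sticks)) {
    density <- .bin_sticks(axis, all_sticks[[k]]$offset, all_sticks[[k]]$weight)
    yk <- .apply_lineshape(axis, density, ls, derivative_order)
    spk <- epr_spectrum(axis, yk, "MHz", derivative_order,
                        mixture$components[[k]]$mw_frequency_GHz)
    y <- y + mixture$fractions[k] * yk / double_integral(spk)
  }
  out <- epr_spectrum(axis, y, "MHz", derivative_order,
                      mixture$components[[1]]$mw_frequency_GHz,
                      metadata = list(mode = paste0("powder_", mode),
                                      n_theta = grid$n_theta,
                                      n_phi = grid$n_phi,
                                      lineshape = ls,
                                      fractions = mixture$fractions))
  if (check_convergence) {
    fine <- simulate_powder(mixture, powder_grid(2L * grid$n_theta, grid$n_phi),
                            ls, axis, mode, derivative_order, intensity_floor,
                            check_convergence = FALSE)
    if (max(abs(fine$intensity - out$intensity)) > 0.01 * max(abs(out$intensity)))
      warning("powder grid may be too coarse: doubling n_theta changes the trace by > 1% of peak",
              call. = FALSE)
  }
  out
}

# Parabolic refinement of an extremum on a regular grid.
.refine_peak <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(x[i])
  x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (x[2] - x[1])
}

#' Extract Pake-pattern singularities
#'
#' Locates the perpendicular singularities (the dominant absorption maxima on
#' either side of the pattern centre) and the parallel shoulders (the
#' outermost steep edges of the absorption) of a powder spectrum. Offsets are
#' reported relative to the spectrum centre. In the weak-coupling regime at
#' J = 0, `nu_par = 2 * nu_perp`.
#'
#' @param spectrum An [epr_spectrum()]; first-derivative input is integrated
#'   to absorption mode internally.
#' @param window Optional axis range `c(lo, hi)` restricting the analysis
#'   (sub-pattern extraction for detuned pairs).
#' @param centre Pattern centre; default: intensity-weighted mean of the
#'   absorption within the window.
#' @param smooth Odd integer width of a running-mean filter applied before
#'   analysis (for noisy spectra; 0 = none).
#' @return List with `nu_perp`, `nu_par` (MHz, positive offsets) and
#'   `centre`.
#' @export
pake_singularities <- function(spectrum, window = NULL, centre = NULL,
                               smooth = 0L) {
  absn <- integrate_spectrum(spectrum)
  x <- absn$axis; y <- absn$intensity
  if (!is.null(window)) {
    keep <- x >= window[1] & x <= window[2]
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 16L) stop("singularity extraction failed: window too narrow")
  y <- y - stats::median(y[c(seq_len(8L), length(y) - seq_len(8L) + 1L)])
  if (smooth >= 3L) {
    k <- rep(1 / smooth, smooth)
    ys <- stats::filter(y, k, sides = 2)
    y[!is.na(ys)] <- ys[!is.na(ys)]
  }
  if (is.null(centre)) centre <- sum(x * pmax(y, 0)) / sum(pmax(y, 0))
  i_int <- 2:(length(y) - 1)
  is_max <- y[i_int] >= y[i_int - 1] & y[i_int] >= y[i_int + 1] &
    y[i_int] > 0.2 * max(y)
  peaks <- i_int[is_max]
  lo <- peaks[x[peaks] < centre]; hi <- peaks[x[peaks] > centre]
  if (!length(lo) || !length(hi))
    stop("singularity extraction failed: perpendicular singularities not resolved")
  i_lo <- lo[which.max(y[lo])]; i_hi <- hi[which.max(y[hi])]
  x_lo <- .refine_peak(x, y, i_lo); x_hi <- .refine_peak(x, y, i_hi)
  nu_perp <- (x_hi - x_lo) / 2
  # Parallel shoulders: the absorption ends in a smeared step at +-nu_par,
  # i.e. the outermost local extremum of the gradient beyond the
  # perpendicular peaks (the peak tail itself has no interior slope
  # extremum, so only quadrature ripple needs thresholding out).
  grad <- c(0, diff(y) / diff(x))
  exclusion <- max(0.4 * nu_perp, 4 * (x[2] - x[1]))
  edge_on_side <- function(right) {
    g <- if (right) -grad else grad     # edges become positive maxima of g
    reg <- if (right) which(x > x_hi + exclusion) else which(x < x_lo - exclusion)
    reg <- reg[reg > 2L & reg < length(x) - 1L]
    if (length(reg) < 5L) return(NA_real_)
    is_ext <- g[reg] >= g[reg - 1L] & g[reg] >= g[reg + 1L] &
      g[reg] >= 0.2 * max(g[reg])
    cand <- reg[is_ext]
    if (!length(cand)) return(NA_real_)
    i <- if (right) max(cand) else min(cand)
    .refine_peak(x, g, i)
  }
  e_hi <- edge_on_side(TRUE); e_lo <- edge_on_side(FALSE)
  nu_par <- if (is.na(e_hi) || is.na(e_lo)) NA_real_ else (e_hi - e_lo) / 2
  list(nu_perp = nu_perp, nu_par = nu_par, centre = centre)
}
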