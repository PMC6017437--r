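# Room-temperature isotropic cw spectra: alpha-proton multiplets plus
# natural-abundance 13C satellite lines, accumulated from exact
# diagonalization over nuclear spin configurations and isotopomers.

#' Expand a spin system into its 13C isotopomer components
#'
#' Natural-abundance 13C satellite analysis considers the all-12C molecule
#' plus every single-13C isotopomer; multi-13C species (probability of order
#' p^2) are discarded and reported. The single-substitution weight at a site
#' with `n` equivalent carbons is `n * p * (1 - p)^(N - 1)` with `N` the
#' total number of carbons considered. Symmetric placement on either trityl
#' unit is handled by multiplying the weight by the number of units, not by
#' separate components; the 13C is attached to electron 1.
#'
#' @param system A [spin_system()]; one trityl unit is assumed per electron.
#' @param site_counts Named vector of equivalent carbons per site per trityl
#'   unit (default [trityl_site_counts()]).
#' @param abundance 13C abundance in (0, 0.05] (or exactly 0 for a
#'   single-component expansion).
#' @param hfcc Named vector of site hyperfine constants in MHz
#'   (default [trityl_hfcc()]).
#' @param min_weight Components below this weight are dropped.
#' @return List of components, each `list(system, weight, site)`, with
#'   attribute `discarded` (multi-13C remainder plus dropped components).
#' @export
#' @examples
#' sys <- spin_system(list(electron_spin(), electron_spin()),
#'                    couplings = list(pair_coupling(c(1, 2), J_MHz = 77)))
#' comps <- isotopomer_expansion(sys)
#' sum(vapply(comps, `[[`, numeric(1), "weight")) + attr(comps, "discarded")
isotopomer_expansion <- function(system, site_counts = trityl_site_counts(),
                                 abundance = C13_ABUNDANCE,
                                 hfcc = trityl_hfcc(), min_weight = 1e-6) {
  stopifnot(inherits(system, "spin_system"))
  if (abundance < 0 || abundance > 0.05)
    stop_validation("abundance must lie in [0, 0.05]")
  if (any(site_counts <= 0)) stop_validation("site carbon counts must be positive")
  n_units <- n_electrons(system)
  if (abundance == 0) {
    out <- list(list(system = system, weight = 1, site = NA_character_))
    attr(out, "discarded") <- 0
    return(out)
  }
  sites <- names(site_counts)
  if (is.null(sites) || !all(sites %in% names(hfcc)))
    stop_validation("site_counts names must have matching entries in hfcc")
  N <- sum(site_counts) * n_units
  p <- abundance
  comps <- list(list(system = system, weight = (1 - p)^N, site = NA_character_))
  for (s in sites) {
    w <- n_units * site_counts[[s]] * p * (1 - p)^(N - 1)
    nuc <- hyperfine_nucleus("13C", spin = 0.5, a_iso_MHz = hfcc[[s]],
                             n_equivalent = 1L, attached_to = 1L, site = s,
                             natural_abundance = p)
    sys_s <- spin_system(system$electrons, c(system$nuclei, list(nuc)),
                         system$couplings, system$mw_frequency_GHz)
    comps <- c(comps, list(list(system = sys_s, weight = w, site = s)))
  }
  weights <- vapply(comps, `[[`, numeric(1), "weight")
  keep <- weights >= min_weight
  discarded <- 1 - sum(weights[keep])
  out <- comps[keep]
  attr(out, "discarded") <- discarded
  out
}

# Enumerate nuclear configurations of a system: the Cartesian product of the
# total projections of each hyperfine group, with binomial (spin-1/2 groups)
# or uniform (single nucleus of any spin) weights.
.nuclear_configs <- function(system) {
  if (!length(system$nuclei))
    return(list(configs = matrix(numeric(0), nrow = 1), weights = 1))
  per_group <- lapply(system$nuclei, function(nu) {
    if (nu$n_equivalent == 1L) {
      m <- seq(-nu$spin, nu$spin, by = 1)
      list(m = m, w = rep(1 / length(m), length(m)))
    } else {
      n <- nu$n_equivalent
      k <- 0:n
      list(m = k - n / 2, w = choose(n, k) / 2^n)
    }
  })
  grids <- lapply(per_group, `[[`, "m")
  cfg <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  wgrids <- lapply(per_group, `[[`, "w")
  wcfg <- as.matrix(expand.grid(wgrids, KEEP.OUT.ATTRS = FALSE))
  list(configs = cfg, weights = apply(wcfg, 1, prod))
}

# Stick spectrum (offset vs weight) of one system: exact transitions
# accumulated over all nuclear configurations. The Hamiltonian is built once
# without nuclei; each configuration only shifts the diagonal (secular
# hyperfine), so the per-config cost is a single small eigen() call.
.stick_spectrum <- function(system, intensity_floor = 1e-6) {
  cfgs <- .nuclear_configs(system)
  n <- n_electrons(system)
  ops <- .electron_ops(n)
  bare <- spin_system(system$electrons, list(), system$couplings,
                      system$mw_frequency_GHz)
  H0 <- build_hamiltonian(bare)
  sz_diag <- lapply(ops$sz, diag)
  nu0 <- system$mw_frequency_GHz * 1000
  acc_pos <- vector("list", length(cfgs$weights))
  acc_wt <- vector("list", length(cfgs$weights))
  for (i in seq_along(cfgs$weights)) {
    H <- H0
    if (ncol(cfgs$configs)) {
      shift <- numeric(2^n)
      for (k in seq_along(system$nuclei)) {
        nu <- system$nuclei[[k]]
        shift <- shift + nu$a_iso_MHz * cfgs$configs[i, k] * sz_diag[[nu$attached_to]]
      }
      diag(H) <- diag(H) + shift
    }
    tr <- .transitions_raw(H, ops$sx, intensity_floor)
    acc_pos[[i]] <- tr$freq - nu0
    acc_wt[[i]] <- tr$inten * cfgs$weights[i]
  }
  list(offset = unlist(acc_pos), weight = unlist(acc_wt))
}

#' Default frequency axis for a simulation
#'
#' @param span Half-range in MHz.
#' @param n Number of points (default 4096, at least four points per 0.1 MHz
#'   feature over typical trityl sweeps).
#' @param centre Axis centre in MHz.
#' @return Numeric axis vector.
#' @export
make_axis <- function(span, n = 4096L, centre = 0) {
  seq(centre - span, centre + span, length.out = n)
}

#' Simulate an isotropic (liquid-solution) cw spectrum
#'
#' Builds the stick spectrum from exact diagonalization over all nuclear
#' configurations (binomial weights for equivalent protons) and, optionally,
#' over the natural-abundance 13C isotopomer expansion, then convolves with
#' the line shape. The integral of the absorption-mode spectrum equals the
#' total transition weight times the component weights (sticks falling
#' outside the axis are lost).
#'
#' @param system A [spin_system()].
#' @param axis Frequency-offset axis in MHz (default: auto-spanned,
#'   4096 points).
#' @param ls A [lineshape()] (widths in MHz).
#' @param derivative_order 0 or 1 (cw convention).
#' @param isotopomers If `TRUE`, expand natural-abundance 13C satellites.
#' @param abundance 13C abundance used when `isotopomers = TRUE`.
#' @param site_counts,hfcc Passed to [isotopomer_expansion()].
#' @param intensity_floor Relative floor for allowed transitions.
#' @return An [epr_spectrum()] (frequency axis, MHz offsets).
#' @export
#' @examples
#' sys <- spin_system(list(electron_spin()),
#'   nuclei = list(hyperfine_nucleus("1H", a_iso_MHz = 0.3, n_equivalent = 6)))
#' sp <- simulate_isotropic(sys, axis = make_axis(3), isotopomers = FALSE,
#'                          ls = lineshape(0.08, 0.08))
simulate_isotropic <- function(system, axis = NULL,
                               ls = lineshape(gaussian_pp = 0.08, lorentzian_pp = 0.08),
                               derivative_order = 1L, isotopomers = TRUE,
                               abundance = C13_ABUNDANCE,
                               site_counts = trityl_site_counts(),
                               hfcc = trityl_hfcc(), intensity_floor = 1e-6) {
  stopifnot(inherits(system, "spin_system"))
  comps <- if (isotopomers)
    isotopomer_expansion(system, site_counts, abundance, hfcc)
  else {
    out <- list(list(system = system, weight = 1, site = NA_character_))
    attr(out, "discarded") <- 0
    out
  }
  pos <- numeric(0); wt <- numeric(0)
  for (comp in comps) {
    st <- .stick_spectrum(comp$system, intensity_floor)
    pos <- c(pos, st$offset)
    wt <- c(wt, st$weight * comp$weight)
  }
  if (is.null(axis)) {
    span <- max(abs(pos)) + 20 * max(ls$gaussian_pp, ls$lorentzian_pp)
    axis <- make_axis(span)
  }
  density <- .bin_sticks(axis, pos, wt)
  y <- .apply_lineshape(axis, density, ls, derivative_order)
  epr_spectrum(axis, y, "MHz", derivative_order, system$mw_frequency_GHz,
               metadata = list(mode = "isotropic",
                               total_weight = sum(wt),
                               discarded_isotopomer_weight = attr(comps, "discarded")))
}

#' Simulate a liquid-solution spectrum of a radical mixture
#'
#' Each component spectrum is normalized to unit absorption area and weighted
#' by its fraction, so fractions are signal fractions (double-integral
#' shares); mono- and biradicals carry different raw transition weight per
#' molecule.
#'
#' @param mixture A [mixture_model()].
#' @param axis,ls,derivative_order,isotopomers,abundance,site_counts,hfcc,intensity_floor
#'   As in [simulate_isotropic()].
#' @return An [epr_spectrum()].
#' @export
simulate_isotropic_mixture <- function(mixture, axis,
                                       ls = lineshape(0.08, 0.08),
                                       derivative_order = 1L,
                                       isotopomers = TRUE,
                                       abundance = C13_ABUNDANCE,
                                       site_counts = trityl_site_counts(),
                                       hfcc = trityl_hfcc(),
                                       intensity_floor = 1e-6) {
  stopifnot(inherits(mixture, "mixture_model"))
  # Components are binned separately, normalized to unit stick area inside
  # the axis (equal to the absorption integral, since the kernels have unit
  # area), fraction-weighted, and convolved once.
  density <- numeric(length(axis))
  for (k in seq_along(mixture$components)) {
    sys_k <- mixture$components[[k]]
    comps <- if (isotopomers)
      isotopomer_expansion(sys_k, site_counts, abundance, hfcc)
    else list(list(system = sys_k, weight = 1, site = NA_character_))
    pos <- numeric(0); wt <- numeric(0)
    for (comp in comps) {
      st <- .stick_spectrum(comp$system, intensity_floor)
      pos <- c(pos, st$offset)
      wt <- c(wt, st$weight * comp$weight)
    }
    dk <- .bin_sticks(axis, pos, wt)
    area <- sum(dk) * (axis[2] - axis[1])
    density <- density + mixture$fractions[k] * dk / area
  }
  y <- .apply_lineshape(axis, density, ls, derivative_order)
  epr_spectrum(axis, y, "MHz", derivative_order,
               mixture$components[[1]]$mw_frequency_GHz,
               metadata = list(mode = "isotropic_mixture",
                               fractions = mixture$fractions))
}

#' Satellite line positions of a single-13C isotopomer
#'
#' For a coupled pair with one 13C at the given site on electron 1, returns
#' all allowed transition offsets and intensities from exact diagonalization,
#' for both nuclear projections. At J = 0 the pattern is the full doublet
#' (split `a`); for |J| >> a the dominant lines collapse to the half-split
#' doublet (`a/2`).
#'
#' @param system A two-electron [spin_system()] (its couplings define J); or
#'   pass `J` to build a bare pair.
#' @param site One of the names of `hfcc`.
#' @param J Convenience: if `system` is `NULL`, an equal-g pair with this
#'   exchange constant is used.
#' @param hfcc Site hyperfine table in MHz.
#' @param intensity_floor Relative floor for allowed transitions.
#' @return data.frame with `offset_MHz`, `intensity`, `m13C`.
#' @export
#' @examples
#' satellite_positions(J = 0, site = "ipso")     # doublet split 31.25 MHz
#' satellite_positions(J = 300, site = "ipso")   # split ~15.6 MHz
satellite_positions <- function(system = NULL, site, J = 0,
                                hfcc = trityl_hfcc(), intensity_floor = 1e-6) {
  if (!site %in% names(hfcc))
    stop_validation("unknown site '", site, "'; known: ",
                    paste(names(hfcc), collapse = ", "))
  if (is.null(system)) {
    system <- spin_system(
      electrons = list(electron_spin("A"), electron_spin("B")),
      couplings = list(pair_coupling(c(1, 2), J_MHz = J))
    )
  }
  stopifnot(inherits(system, "spin_system"))
  nuc <- hyperfine_nucleus("13C", spin = 0.5, a_iso_MHz = hfcc[[site]],
                           n_equivalent = 1L, attached_to = 1L, site = site)
  # Strip proton groups: satellite positions are referenced to the multiplet
  # centre, which the (symmetric) proton structure does not move.
  sys13 <- spin_system(system$electrons, list(nuc), system$couplings,
                       system$mw_frequency_GHz)
  out <- do.call(rbind, lapply(c(0.5, -0.5), function(m) {
    ts <- transitions(sys13, nuclear_config = m, intensity_floor = 0)
    data.frame(offset_MHz = ts$offset_MHz, intensity = ts$intensity / 2,
               m13C = m)
  }))
  out <- out[out$intensity >= intensity_floor * max(out$intensity), ]
  out[order(out$offset_MHz), ]
}

#' Dominant satellite doublet of a line list
#'
#' Merges near-degenerate lines and returns the offsets of the strongest
#' merged line on each side of the centre — what one reads off a spectrum as
#' "the satellite position".
#'
#' @param lines data.frame with `offset_MHz` and `intensity` (e.g. from
#'   [satellite_positions()]).
#' @param merge_tol Merging tolerance in MHz.
#' @return Named numeric `c(lower, upper)` offsets in MHz.
#' @export
satellite_doublet <- function(lines, merge_tol = 0.1) {
  m <- merge_transitions(lines, merge_tol)
  lo <- m[m$offset_MHz < 0, ]; hi <- m[m$offset_MHz > 0, ]
  if (!nrow(lo) || !nrow(hi))
    stop("no resolved satellite doublet (lines on one side of the centre only)")
  c(lower = lo$offset_MHz[which.max(lo$intensity)],
    upper = hi$offset_MHz[which.max(hi$intensity)])
}
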