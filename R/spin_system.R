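# Domain types: electron spins, hyperfine nuclei, pair couplings and the
# assembled spin system. Plain lists with S3 classes and eager validation.

stop_validation <- function(...) {
  stop(structure(class = c("spinpair_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Define an electron spin centre
#'
#' @param label Short text label (e.g. `"e1"`).
#' @param g_iso Isotropic g value. Validated against `g_bounds` (organic
#'   radicals cluster tightly around g = 2); widen the bounds for exotic
#'   centres.
#' @param g_principal Optional numeric length-3 vector of principal g values
#'   for frozen-solution anisotropy. Its mean must equal `g_iso` to 1e-6.
#' @param nu_offset_MHz Additional fixed resonance offset in MHz. Used to
#'   model an inequivalence of the two spin centres (g- or hyperfine strain)
#'   without enumerating its microscopic origin.
#' @param g_bounds Length-2 validation window for `g_iso`.
#' @return Object of class `electron_spin`.
#' @export
#' @examples
#' electron_spin("e1", g_iso = 2.0035)
electron_spin <- function(label = "e", g_iso = 2.0035, g_principal = NULL,
                          nu_offset_MHz = 0, g_bounds = c(1.9, 2.1)) {
  if (!is.numeric(g_iso) || length(g_iso) != 1L || !is.finite(g_iso))
    stop_validation("g_iso must be a finite number")
  if (g_iso < g_bounds[1] || g_iso > g_bounds[2])
    stop_validation(sprintf("g_iso = %.5f outside validation bounds [%g, %g]",
                            g_iso, g_bounds[1], g_bounds[2]))
  if (!is.null(g_principal)) {
    if (length(g_principal) != 3L || any(!is.finite(g_principal)))
      stop_validation("g_principal must be three finite principal values")
    if (abs(mean(g_principal) - g_iso) > 1e-6)
      stop_validation("mean(g_principal) must equal g_iso within 1e-6")
  }
  if (!is.finite(nu_offset_MHz)) stop_validation("nu_offset_MHz must be finite")
  structure(list(label = as.character(label), g_iso = g_iso,
                 g_principal = g_principal, nu_offset_MHz = nu_offset_MHz),
            class = "electron_spin")
}

#' Define a group of equivalent hyperfine-coupled nuclei
#'
#' The hyperfine interaction enters the high-field Hamiltonian only through
#' its secular part `a_iso * m_I * S_z`, so a group of `n_equivalent`
#' equivalent nuclei is fully described by its total projection.
#'
#' @param isotope Isotope label, e.g. `"1H"` or `"13C"`.
#' @param spin Nuclear spin quantum number (half-integer). Groups with
#'   `n_equivalent > 1` are supported for spin-1/2 nuclei.
#' @param a_iso_MHz Isotropic hyperfine coupling constant in MHz.
#' @param n_equivalent Number of equivalent nuclei in the group.
#' @param attached_to Index of the electron the group couples to.
#' @param site Optional position label (`"ipso"`, `"ortho"`, `"meta"`,
#'   `"para"`, `"alpha"`).
#' @param natural_abundance Fractional abundance in `[0, 1]` (bookkeeping for
#'   isotopomer expansion; the nucleus itself always couples fully).
#' @return Object of class `hyperfine_nucleus`.
#' @export
hyperfine_nucleus <- function(isotope = "1H", spin = 0.5, a_iso_MHz,
                              n_equivalent = 1L, attached_to = 1L,
                              site = NULL, natural_abundance = 1) {
  if (!is.finite(a_iso_MHz)) stop_validation("a_iso_MHz must be finite")
  if (n_equivalent < 1 || n_equivalent != round(n_equivalent))
    stop_validation("n_equivalent must be a positive integer")
  if (spin <= 0 || abs(2 * spin - round(2 * spin)) > 1e-12)
    stop_validation("spin must be a positive half-integer")
  if (n_equivalent > 1 && abs(spin - 0.5) > 1e-12)
    stop_validation("equivalent-nucleus groups are supported for spin-1/2 only")
  if (natural_abundance < 0 || natural_abundance > 1)
    stop_validation("natural_abundance must lie in [0, 1]")
  structure(list(isotope = as.character(isotope), spin = spin,
                 a_iso_MHz = a_iso_MHz, n_equivalent = as.integer(n_equivalent),
                 attached_to = as.integer(attached_to), site = site,
                 natural_abundance = natural_abundance),
            class = "hyperfine_nucleus")
}

#' Define an electron-electron pair coupling
#'
#' Isotropic exchange `J * S1.S2` (J > 0 antiferromagnetic) plus the
#' high-field dipolar coupling
#' `D (1 - 3 cos^2 theta) (S1z S2z - (S1+S2- + S1-S2+)/4)`.
#'
#' @param spins Integer pair of electron indices.
#' @param J_MHz Isotropic exchange coupling constant in MHz (signed).
#' @param D_MHz Dipolar coupling constant in MHz (`D = 52.01/r^3`, r in nm);
#'   must be non-negative.
#' @param theta Angle (rad) between the inter-spin vector and the external
#'   field, for single-orientation use. Ignored when a powder average
#'   supplies the field direction and `axis` is set.
#' @param axis Optional unit vector of the inter-spin direction in the
#'   molecular frame, for powder or multi-spin use.
#' @return Object of class `pair_coupling`.
#' @export
#' @examples
#' pair_coupling(c(1, 2), J_MHz = 77)
pair_coupling <- function(spins, J_MHz = 0, D_MHz = 0, theta = pi / 2,
                          axis = NULL) {
  spins <- as.integer(spins)
  if (length(spins) != 2L || spins[1] == spins[2])
    stop_validation("spins must be two distinct electron indices")
  if (!is.finite(J_MHz) || !is.finite(D_MHz))
    stop_validation("J_MHz and D_MHz must be finite")
  if (D_MHz < 0) stop_validation("D_MHz must be >= 0")
  if (theta < 0 || theta > pi) stop_validation("theta must lie in [0, pi]")
  if (!is.null(axis)) {
    if (length(axis) != 3L || abs(sqrt(sum(axis^2)) - 1) > 1e-9)
      stop_validation("axis must be a 3-vector of unit norm (1e-9)")
  }
  structure(list(spins = sort(spins), J_MHz = J_MHz, D_MHz = D_MHz,
                 theta = theta, axis = axis),
            class = "pair_coupling")
}

#' Assemble a spin system
#'
#' @param electrons List of [electron_spin()] objects (1 to 3).
#' @param nuclei List of [hyperfine_nucleus()] objects.
#' @param couplings List of [pair_coupling()] objects; at most one per
#'   electron pair.
#' @param mw_frequency_GHz Microwave frequency in GHz (X-band default).
#' @return Object of class `spin_system`.
#' @export
#' @examples
#' sys <- spin_system(
#'   electrons = list(electron_spin("A"), electron_spin("B")),
#'   nuclei = list(hyperfine_nucleus("13C", a_iso_MHz = 31.25, attached_to = 1)),
#'   couplings = list(pair_coupling(c(1, 2), J_MHz = 75))
#' )
spin_system <- function(electrons, nuclei = list(), couplings = list(),
                        mw_frequency_GHz = 9.4) {
  if (inherits(electrons, "electron_spin")) electrons <- list(electrons)
  if (inherits(nuclei, "hyperfine_nucleus")) nuclei <- list(nuclei)
  if (inherits(couplings, "pair_coupling")) couplings <- list(couplings)
  n_e <- length(electrons)
  if (n_e < 1L) stop_validation("at least one electron is required")
  if (n_e > 3L)
    stop("unsupported system: more than 3 electrons (matrix dimension grows as 2^n)")
  for (e in electrons)
    if (!inherits(e, "electron_spin")) stop_validation("electrons must be electron_spin objects")
  for (nu in nuclei) {
    if (!inherits(nu, "hyperfine_nucleus"))
      stop_validation("nuclei must be hyperfine_nucleus objects")
    if (nu$attached_to < 1L || nu$attached_to > n_e)
      stop_validation("nucleus attached_to must index an existing electron")
  }
  seen_pairs <- character(0)
  for (cp in couplings) {
    if (!inherits(cp, "pair_coupling"))
      stop_validation("couplings must be pair_coupling objects")
    if (any(cp$spins < 1L) || any(cp$spins > n_e))
      stop_validation("coupling references a non-existent electron")
    key <- paste(cp$spins, collapse = "-")
    if (key %in% seen_pairs)
      stop_validation("at most one coupling per electron pair (duplicate ", key, ")")
    seen_pairs <- c(seen_pairs, key)
  }
  if (!is.finite(mw_frequency_GHz) || mw_frequency_GHz <= 0)
    stop_validation("mw_frequency_GHz must be positive and finite")
  structure(list(electrons = electrons, nuclei = nuclei, couplings = couplings,
                 mw_frequency_GHz = mw_frequency_GHz),
            class = "spin_system")
}

n_electrons <- function(system) length(system$electrons)

mean_g <- function(system) mean(vapply(system$electrons, `[[`, numeric(1), "g_iso"))

#' Resonance field of a spin system
#'
#' First-order resonance field (mT) of the mean-g electron at the system's
#' microwave frequency.
#'
#' @param system A [spin_system()].
#' @return Field in mT.
#' @export
resonance_field_mT <- function(system) {
  system$mw_frequency_GHz * 1000 / (MHZ_PER_MT_G * mean_g(system))
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %d electron(s), %d hyperfine group(s), %d coupling(s), %.4f GHz\n",
              length(x$electrons), length(x$nuclei), length(x$couplings),
              x$mw_frequency_GHz))
  for (i in seq_along(x$electrons)) {
    e <- x$electrons[[i]]
    cat(sprintf("  e%d '%s': g_iso = %.5f%s%s\n", i, e$label, e$g_iso,
                if (!is.null(e$g_principal))
                  sprintf(", g_principal = (%.5f, %.5f, %.5f)",
                          e$g_principal[1], e$g_principal[2], e$g_principal[3]) else "",
                if (e$nu_offset_MHz != 0)
                  sprintf(", offset = %+.3f MHz", e$nu_offset_MHz) else ""))
  }
  for (nu in x$nuclei)
    cat(sprintf("  %s x%d on e%d: a_iso = %.4g MHz%s\n", nu$isotope,
                nu$n_equivalent, nu$attached_to, nu$a_iso_MHz,
                if (!is.null(nu$site)) paste0(" (", nu$site, ")") else ""))
  for (cp in x$couplings)
    cat(sprintf("  e%d-e%d: J = %.4g MHz, D = %.4g MHz\n",
                cp$spins[1], cp$spins[2], cp$J_MHz, cp$D_MHz))
  invisible(x)
}
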