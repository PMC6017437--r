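# Physical constants and compound-class defaults used throughout the package.

# Electron Zeeman conversion: nu[MHz] = MHZ_PER_MT_G * g * B[mT]
# (mu_B / h = 13.9962 GHz/T).
MHZ_PER_MT_G <- 13.9962

# Point-dipole conversion constant for two g ~ 2 electrons, D = DIP_CONST / r^3
# with D in MHz and r in nm.
DIP_CONST_MHZ_NM3 <- 52.01

# Stretch factor of the powder pattern in the strong-coupling regime.
STRONG_COUPLING_STRETCH <- 1.5

# Free-electron g value, used only for the optional g-scaled dipolar constant.
G_FREE_ELECTRON <- 2.002319

#' Isotropic 13C hyperfine coupling constants of the trityl aryl carbons
#'
#' Isotropic hyperfine coupling constants (MHz) of the ring carbons of
#' tetrathiaaryl (trityl) radicals, as observed in the 13C satellite lines of
#' the main cw EPR absorption: ipso 31.25, ortho 25.00, meta 6.20 and
#' para 8.40 MHz.
#'
#' @return Named numeric vector of a_iso values in MHz.
#' @export
#' @examples
#' trityl_hfcc()
trityl_hfcc <- function() {
  c(ipso = 31.25, ortho = 25.00, meta = 6.20, para = 8.40)
}

#' Equivalent aryl-carbon counts per trityl unit
#'
#' Number of symmetry-equivalent carbons contributing to each 13C satellite
#' site in one trityl moiety (three aryl rings per trityl: 3 ipso, 6 ortho,
#' 6 meta, 3 para). These counts set satellite intensities, not positions,
#' and can be overridden in [isotopomer_expansion()].
#'
#' @return Named integer vector of carbon counts per trityl unit.
#' @export
trityl_site_counts <- function() {
  c(ipso = 3L, ortho = 6L, meta = 6L, para = 3L)
}

# Natural abundance of 13C.
C13_ABUNDANCE <- 0.0107
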