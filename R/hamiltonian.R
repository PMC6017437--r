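# Construction and exact diagonalization of the high-field spin Hamiltonian
# for 2-3 coupled S = 1/2 electrons with secular isotropic hyperfine nuclei.
#
# All energies are in frequency units (MHz); the field axis is in mT with
# nu[MHz] = 13.9962 * g * B[mT].

# Single-spin-1/2 operators.
.sz1 <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
.sp1 <- matrix(c(0, 0, 1, 0), 2, 2)   # S+ |down> = |up>
.sm1 <- t(.sp1)
.id1 <- diag(2)

# Operator acting as `op` on electron `i` of `n`, identity elsewhere.
.embed_op <- function(op, i, n) {
  out <- 1
  for (k in seq_len(n)) out <- kronecker(out, if (k == i) op else .id1)
  out
}

# Per-electron Sz, S+, S- and total Sx for an n-electron product basis.
# Cached by electron count: these small kronecker products are rebuilt
# constantly in config/orientation loops.
.ops_cache <- new.env(parent = emptyenv())

.electron_ops <- function(n) {
  key <- as.character(n)
  if (!is.null(.ops_cache[[key]])) return(.ops_cache[[key]])
  sz <- lapply(seq_len(n), function(i) .embed_op(.sz1, i, n))
  sp <- lapply(seq_len(n), function(i) .embed_op(.sp1, i, n))
  sm <- lapply(seq_len(n), function(i) .embed_op(.sm1, i, n))
  sx <- Reduce(`+`, lapply(seq_len(n), function(i) (sp[[i]] + sm[[i]]) / 2))
  .ops_cache[[key]] <- list(sz = sz, sp = sp, sm = sm, sx = sx)
  .ops_cache[[key]]
}

# Eigen-decompose a Hamiltonian and collect positive-frequency transitions
# weighted by |<f|Sx|i>|^2. Lean internal core shared by transitions() and
# the spectrum engines.
.transitions_raw <- function(H, sx, intensity_floor = 1e-6) {
  eig <- eigen(H, symmetric = TRUE)
  V <- eig$vectors
  lam <- eig$values
  M2 <- crossprod(V, sx %*% V)^2
  dim_h <- length(lam)
  ut <- upper.tri(M2)
  freq <- outer(lam, lam, `-`)[ut]     # lam[i] - lam[j] for i < j (decreasing)
  inten <- M2[ut]
  keep <- freq > 0 & inten > 0
  freq <- freq[keep]; inten <- inten[keep]
  total <- sum(inten)
  if (length(inten)) {
    keep2 <- inten >= intensity_floor * max(inten)
    freq <- freq[keep2]; inten <- inten[keep2]
  }
  list(freq = freq, inten = inten, total = total)
}

# Effective g value of electron e for a unit field direction (molecular frame
# z = unique axis). Axial/rhombic principal values; isotropic fallback.
.g_eff <- function(e, field_direction = NULL) {
  if (is.null(e$g_principal)) return(e$g_iso)
  if (is.null(field_direction)) return(e$g_iso)
  l <- field_direction
  sqrt(sum((e$g_principal * l)^2))
}

# Dipolar angular factor for one coupling and a field direction (or the
# coupling's own theta when no direction is supplied).
.dip_weight <- function(cp, field_direction = NULL) {
  if (!is.null(field_direction) && !is.null(cp$axis)) {
    ct <- sum(field_direction * cp$axis)
  } else if (!is.null(field_direction) && is.null(cp$axis)) {
    ct <- field_direction[3]
  } else {
    ct <- cos(cp$theta)
  }
  cp$D_MHz * (1 - 3 * ct^2)
}

# Validate a vector of per-group total projections; nuclei always require an
# explicit configuration (enumeration is the caller's job).
.check_nuclear_config <- function(system, nuclear_config) {
  n_nuc <- length(system$nuclei)
  if (n_nuc == 0L) return(numeric(0))
  if (is.null(nuclear_config))
    stop_validation("nuclear_config must supply one total projection per hyperfine group")
  if (length(nuclear_config) != n_nuc)
    stop_validation(sprintf("nuclear_config has length %d but the system has %d hyperfine group(s)",
                            length(nuclear_config), n_nuc))
  for (k in seq_len(n_nuc)) {
    nu <- system$nuclei[[k]]
    m <- nuclear_config[k]
    mmax <- nu$spin * nu$n_equivalent
    if (!is.finite(m) || abs(m) > mmax + 1e-9 ||
        abs((m - mmax) - round(m - mmax)) > 1e-9)
      stop_validation(sprintf("projection %g invalid for group %d (|m| <= %g in integer steps)",
                              m, k, mmax))
  }
  as.numeric(nuclear_config)
}

#' Build the high-field spin Hamiltonian matrix
#'
#' Constructs the Hamiltonian (MHz) on the electron product basis for a fixed
#' nuclear spin configuration: electron Zeeman terms
#' `13.9962 * g_i * B0 * S_iz`, secular hyperfine shifts `a_iso * m_I * S_iz`,
#' and for every electron pair the secular plus pseudo-secular exchange
#' `J (S1z S2z) + J/2 (S1+S2- + S1-S2+)` and dipolar
#' `d (S1z S2z - (S1+S2- + S1-S2+)/4)` terms with
#' `d = D (1 - 3 cos^2 theta)`.
#'
#' @param system A [spin_system()] (1-3 electrons).
#' @param B0_mT Static field in mT. Default: the resonance field of the mean
#'   g value at the system's microwave frequency.
#' @param nuclear_config Numeric vector of total spin projections, one per
#'   hyperfine group (a group of n equivalent spin-1/2 nuclei enters only
#'   through its total projection).
#' @param field_direction Optional unit vector of the field in the molecular
#'   frame; activates per-coupling `axis` geometry and g anisotropy.
#' @return Real symmetric matrix (MHz) of dimension `2^n`.
#' @export
#' @examples
#' sys <- spin_system(list(electron_spin(), electron_spin()),
#'                    couplings = list(pair_coupling(c(1, 2), J_MHz = 75)))
#' H <- build_hamiltonian(sys)
build_hamiltonian <- function(system, B0_mT = NULL, nuclear_config = NULL,
                              field_direction = NULL) {
  stopifnot(inherits(system, "spin_system"))
  n <- n_electrons(system)
  if (is.null(B0_mT)) B0_mT <- resonance_field_mT(system)
  if (!is.finite(B0_mT) || B0_mT <= 0) stop_validation("B0_mT must be positive and finite")
  m_I <- .check_nuclear_config(system, nuclear_config)
  ops <- .electron_ops(n)
  H <- matrix(0, 2^n, 2^n)
  # Zeeman + secular hyperfine: nu_i * S_iz
  nu_e <- numeric(n)
  for (i in seq_len(n)) {
    e <- system$electrons[[i]]
    nu_e[i] <- MHZ_PER_MT_G * .g_eff(e, field_direction) * B0_mT + e$nu_offset_MHz
  }
  for (k in seq_along(system$nuclei)) {
    nu <- system$nuclei[[k]]
    nu_e[nu$attached_to] <- nu_e[nu$attached_to] + nu$a_iso_MHz * m_I[k]
  }
  for (i in seq_len(n)) H <- H + nu_e[i] * ops$sz[[i]]
  # Pair couplings
  for (cp in system$couplings) {
    i <- cp$spins[1]; j <- cp$spins[2]
    d <- .dip_weight(cp, field_direction)
    flipflop <- ops$sp[[i]] %*% ops$sm[[j]] + ops$sm[[i]] %*% ops$sp[[j]]
    H <- H + (cp$J_MHz + d) * (ops$sz[[i]] %*% ops$sz[[j]]) +
      (cp$J_MHz / 2 - d / 4) * flipflop
  }
  H
}

#' Allowed EPR transitions of a spin system
#'
#' Diagonalizes the Hamiltonian exactly and returns all transition
#' frequencies (eigenvalue differences) with intensity given by the squared
#' matrix element of the total transverse electron spin operator between
#' eigenstates. Transitions below `intensity_floor` (relative to the
#' strongest) are dropped.
#'
#' @inheritParams build_hamiltonian
#' @param intensity_floor Relative intensity below which transitions are
#'   considered forbidden (default 1e-6).
#' @return A `transition_set`: data.frame with columns `frequency_MHz`,
#'   `offset_MHz` (relative to the microwave frequency) and `intensity`,
#'   with attributes `total_intensity` and `B0_mT`.
#' @export
#' @examples
#' sys <- spin_system(list(electron_spin()),
#'                    nuclei = list(hyperfine_nucleus("13C", a_iso_MHz = 31.25)))
#' transitions(sys, nuclear_config = 0.5)
transitions <- function(system, B0_mT = NULL, nuclear_config = NULL,
                        intensity_floor = 1e-6, field_direction = NULL) {
  if (is.null(B0_mT)) B0_mT <- resonance_field_mT(system)
  H <- build_hamiltonian(system, B0_mT, nuclear_config, field_direction)
  n <- n_electrons(system)
  tr <- .transitions_raw(H, .electron_ops(n)$sx, intensity_floor)
  ord <- order(tr$freq)
  out <- data.frame(frequency_MHz = tr$freq[ord],
                    offset_MHz = tr$freq[ord] - system$mw_frequency_GHz * 1000,
                    intensity = tr$inten[ord])
  structure(out, class = c("transition_set", "data.frame"),
            total_intensity = tr$total, B0_mT = B0_mT)
}

#' Merge near-degenerate transitions
#'
#' Transitions closer than `tol` (MHz) are reported merged, at the
#' intensity-weighted mean position ("accidentally almost degenerate" lines
#' appear as one line in a spectrum).
#'
#' @param ts A `transition_set` or data.frame with `offset_MHz`, `intensity`.
#' @param tol Merging tolerance in MHz (default 0.1).
#' @return data.frame with merged `offset_MHz` and summed `intensity`.
#' @export
merge_transitions <- function(ts, tol = 0.1) {
  x <- ts$offset_MHz; w <- ts$intensity
  if (!length(x)) return(data.frame(offset_MHz = numeric(0), intensity = numeric(0)))
  ord <- order(x); x <- x[ord]; w <- w[ord]
  grp <- cumsum(c(1, diff(x) > tol))
  data.frame(
    offset_MHz = as.numeric(tapply(x * w, grp, sum) / tapply(w, grp, sum)),
    intensity = as.numeric(tapply(w, grp, sum))
  )
}

#' Classify the electron-electron coupling regime
#'
#' Computes the ratio `|J - D/2| / |delta_omega|` and classifies it as weak
#' (ratio <= 0.1), strong (ratio >= 10) or intermediate. A vanishing
#' `delta_omega` makes the spins equivalent, which is strong coupling by
#' convention (ratio = Inf).
#'
#' @param J Exchange coupling constant in MHz.
#' @param D Dipolar coupling constant in MHz (0 for liquid solution).
#' @param delta_omega Difference of the two electrons' resonance frequencies
#'   in MHz; for a single-13C isotopomer use [delta_omega_13C()].
#' @return Object of class `regime_report` with fields `ratio`,
#'   `delta_omega`, `regime` and `thresholds`.
#' @export
#' @examples
#' classify_regime(J = 300, D = 0, delta_omega = 31.25 / 2)
classify_regime <- function(J, D = 0, delta_omega) {
  if (!is.finite(J) || !is.finite(D)) stop_validation("J and D must be finite")
  ratio <- if (delta_omega == 0) Inf else abs(J - D / 2) / abs(delta_omega)
  regime <- if (ratio <= 0.1) "weak" else if (ratio >= 10) "strong" else "intermediate"
  structure(list(ratio = ratio, delta_omega = delta_omega, regime = regime,
                 thresholds = c(weak = 0.1, strong = 10)),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("<regime_report> |J - D/2|/|delta_omega| = %.4g -> %s coupling\n",
              x$ratio, x$regime))
  invisible(x)
}

#' Resonance-frequency difference for a single-13C isotopomer
#'
#' For a molecule carrying a single 13C, the spin on the labelled trityl is
#' detuned from its partner by `delta_omega = a_iso(13C) / 2`.
#'
#' @param a_iso_13C Isotropic 13C hyperfine coupling constant in MHz.
#' @return delta_omega in MHz.
#' @export
delta_omega_13C <- function(a_iso_13C) a_iso_13C / 2

#' Apparent hyperfine splitting of a coupled spin pair
#'
#' Numerically computes the apparent isotropic splitting produced by a single
#' spin-1/2 nucleus (coupling `a_iso`) attached to one electron of an
#' exchange-coupled pair. The two-electron, one-nucleus Hamiltonian is
#' diagonalized for both nuclear projections and the splitting is twice the
#' intensity-weighted mean |offset| of all allowed transitions outside the
#' central region (|offset| >= a_iso/8). Limits: `a_iso` for J -> 0 and
#' `a_iso / 2` for |J| >> a (coupling "reduced by 50%"), continuous in
#' between.
#'
#' @param J Exchange coupling constant in MHz (vectorized).
#' @param a_iso Hyperfine coupling constant in MHz.
#' @param intensity_floor Relative intensity floor for allowed transitions.
#' @return Apparent splitting in MHz (same length as `J`).
#' @export
#' @examples
#' effective_satellite_splitting(J = 77, a_iso = 0.3)  # ~0.15
effective_satellite_splitting <- function(J, a_iso, intensity_floor = 1e-6) {
  stopifnot(is.finite(a_iso), a_iso > 0)
  one <- function(Jv) {
    sys <- spin_system(
      electrons = list(electron_spin("A"), electron_spin("B")),
      nuclei = list(hyperfine_nucleus("X", a_iso_MHz = a_iso, attached_to = 1L)),
      couplings = list(pair_coupling(c(1, 2), J_MHz = Jv))
    )
    sticks <- do.call(rbind, lapply(c(0.5, -0.5), function(m) {
      ts <- transitions(sys, nuclear_config = m, intensity_floor = 0)
      data.frame(offset = ts$offset_MHz, inten = ts$intensity / 2)
    }))
    sticks <- sticks[sticks$inten >= intensity_floor * max(sticks$inten), ]
    sat <- sticks[abs(sticks$offset) >= a_iso / 8, ]
    if (!nrow(sat)) return(0)
    2 * sum(abs(sat$offset) * sat$inten) / sum(sat$inten)
  }
  vapply(J, one, numeric(1))
}
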