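# File interfaces: two-column ASCII spectra with '#' metadata headers, and
# YAML spin-system configuration files. Both round-trip losslessly.

#' Write a spectrum to a two-column ASCII file
#'
#' Format: '#'-prefixed `key: value` header lines (at least `axis_unit`,
#' `mw_frequency_GHz`, `derivative_order`), followed by axis/intensity pairs
#' at 12 significant digits.
#'
#' @param spectrum An [epr_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  hdr <- c(sprintf("# axis_unit: %s", spectrum$axis_unit),
           sprintf("# mw_frequency_GHz: %.12g", spectrum$mw_frequency_GHz),
           sprintf("# derivative_order: %d", spectrum$derivative_order))
  meta <- spectrum$metadata
  scalars <- meta[vapply(meta, function(v)
    is.atomic(v) && length(v) == 1L && !is.na(v), logical(1))]
  for (nm in names(scalars))
    hdr <- c(hdr, sprintf("# %s: %s", nm, format(scalars[[nm]], digits = 12)))
  body <- sprintf("%.15g %.15g", spectrum$axis, spectrum$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a spectrum from a two-column ASCII file
#'
#' Parse errors (ragged rows, a non-monotone axis, missing unit headers)
#' name the offending line.
#'
#' @param path File written by [write_spectrum()] (or compatible).
#' @return An [epr_spectrum()]; extra header keys land in `metadata`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*#", lines)
  hdr <- sub("^\\s*#\\s*", "", lines[is_hdr])
  meta <- list()
  for (h in hdr[nzchar(hdr)]) {
    kv <- regmatches(h, regexec("^([^:]+):\\s*(.*)$", h))[[1]]
    if (length(kv) == 3L) {
      val <- utils::type.convert(kv[3], as.is = TRUE)
      meta[[trimws(kv[2])]] <- val
    }
  }
  for (req in c("axis_unit", "mw_frequency_GHz", "derivative_order"))
    if (is.null(meta[[req]]))
      stop("parse error in ", path, ": missing required header '", req, "'")
  data_idx <- which(!is_hdr & nzchar(trimws(lines)))
  axis <- numeric(length(data_idx)); inten <- numeric(length(data_idx))
  for (k in seq_along(data_idx)) {
    ln <- data_idx[k]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 2L || any(is.na(vals)))
      stop("parse error at line ", ln, " of ", path,
           ": expected two numeric columns, got '", lines[ln], "'")
    axis[k] <- vals[1]; inten[k] <- vals[2]
  }
  d <- diff(axis)
  bad <- which(!(all(d > 0) || all(d < 0)))
  if (length(axis) >= 2L && !(all(d > 0) || all(d < 0))) {
    off <- which(d <= 0)[1]
    stop("parse error at line ", data_idx[off + 1L], " of ", path,
         ": axis is not strictly monotone")
  }
  extra <- meta[setdiff(names(meta), c("axis_unit", "mw_frequency_GHz",
                                       "derivative_order"))]
  epr_spectrum(axis, inten, axis_unit = meta$axis_unit,
               derivative_order = as.integer(meta$derivative_order),
               mw_frequency_GHz = as.numeric(meta$mw_frequency_GHz),
               metadata = extra)
}

#' Write a spin system to a YAML configuration file
#'
#' Schema: top-level keys `mw_frequency_GHz`, `electrons` (list of `label`,
#' `g_iso`, optional `g_principal`, `nu_offset_MHz`), `nuclei` (list of
#' `isotope`, `spin`, `a_iso_MHz`, `n_equivalent`, `attached_to`, optional
#' `site`, `natural_abundance`) and `couplings` (list of `spins`, `J_MHz`,
#' `D_MHz`, `theta`, optional `axis`).
#'
#' @param system A [spin_system()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(system, path) {
  stopifnot(inherits(system, "spin_system"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  obj <- list(
    mw_frequency_GHz = system$mw_frequency_GHz,
    electrons = lapply(system$electrons, strip),
    nuclei = lapply(system$nuclei, strip),
    couplings = lapply(system$couplings, strip)
  )
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' Read a spin system from a YAML configuration file
#'
#' @param path File written by [write_spin_system()] (or hand-written to the
#'   same schema).
#' @return A validated [spin_system()].
#' @export
read_spin_system <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$electrons))
    stop("parse error in ", path, ": missing 'electrons' block")
  electrons <- lapply(obj$electrons, function(e)
    do.call(electron_spin, e[intersect(names(e), names(formals(electron_spin)))]))
  nuclei <- lapply(obj$nuclei, function(e)
    do.call(hyperfine_nucleus, e[intersect(names(e), names(formals(hyperfine_nucleus)))]))
  couplings <- lapply(obj$couplings, function(e) {
    e$spins <- unlist(e$spins)
    if (!is.null(e$axis)) e$axis <- unlist(e$axis)
    do.call(pair_coupling, e[intersect(names(e), names(formals(pair_coupling)))])
  })
  spin_system(electrons, nuclei, couplings,
              mw_frequency_GHz = if (is.null(obj$mw_frequency_GHz)) 9.4
              else obj$mw_frequency_GHz)
}
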