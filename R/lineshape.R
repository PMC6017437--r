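# Line shapes and the stick-to-trace engine: binning of stick spectra onto a
# regular axis and convolution with Gaussian/Lorentzian (Voigt-by-convolution)
# kernels, in absorption or first-derivative mode.

#' Define a Voigt-by-convolution line shape
#'
#' Widths are given as peak-to-peak widths of the first-derivative line, the
#' quantity read off a cw EPR spectrum. Internally Gaussian
#' `sigma = pp/2` and Lorentzian half-width-at-half-maximum
#' `gamma = sqrt(3)/2 * pp`.
#'
#' @param gaussian_pp Gaussian peak-to-peak width (>= 0).
#' @param lorentzian_pp Lorentzian peak-to-peak width (>= 0). At least one of
#'   the two widths must be positive.
#' @param unit Width unit label, `"MHz"` (default) or `"mT"`.
#' @return Object of class `lineshape`.
#' @export
#' @examples
#' lineshape(gaussian_pp = 2.36, lorentzian_pp = 1.00)
lineshape <- function(gaussian_pp = 0, lorentzian_pp = 0, unit = "MHz") {
  if (gaussian_pp < 0 || lorentzian_pp < 0)
    stop_validation("line widths must be >= 0")
  if (gaussian_pp == 0 && lorentzian_pp == 0)
    stop_validation("at least one width must be > 0")
  structure(list(gaussian_pp = gaussian_pp, lorentzian_pp = lorentzian_pp,
                 kind = "voigt-by-convolution", unit = unit),
            class = "lineshape")
}

# Gaussian absorption kernel and its derivative, area-normalized on the grid.
.gauss_kernel <- function(dx, sigma, derivative = FALSE) {
  half <- max(3L, ceiling(6 * sigma / dx))
  x <- seq(-half, half) * dx
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / (sum(g) * dx)
  if (derivative) (-x / sigma^2) * g else g
}

# Lorentzian absorption kernel (long tails: wide support) and derivative.
.lorentz_kernel <- function(dx, gamma, derivative = FALSE, n_axis = NULL) {
  half <- ceiling(60 * gamma / dx)
  if (!is.null(n_axis)) half <- min(half, n_axis)
  half <- max(3L, half)
  x <- seq(-half, half) * dx
  l <- gamma / (pi * (x^2 + gamma^2))
  area <- sum(l) * dx
  if (derivative) (-2 * x * gamma / (pi * (x^2 + gamma^2)^2)) / area else l / area
}

# Linear (area-preserving) binning of sticks onto a regular axis. Returns an
# intensity *density* so that sum(out) * dx = sum of the binned weights.
.bin_sticks <- function(axis, pos, weight) {
  n <- length(axis)
  dx <- axis[2] - axis[1]
  out <- numeric(n)
  inside <- pos >= axis[1] & pos <= axis[n]
  pos <- pos[inside]; weight <- weight[inside]
  if (!length(pos)) return(out)
  fi <- (pos - axis[1]) / dx
  i0 <- pmin(floor(fi), n - 2)
  frac <- fi - i0
  for (k in seq_along(pos)) {
    out[i0[k] + 1] <- out[i0[k] + 1] + weight[k] * (1 - frac[k])
    out[i0[k] + 2] <- out[i0[k] + 2] + weight[k] * frac[k]
  }
  out / dx
}

# Zero-padded FFT convolution returning the full (n + m - 1) sequence.
# Padding to a power of two keeps the FFT plans fast for awkward lengths.
.conv_full <- function(a, b) {
  n <- length(a); m <- length(b)
  N <- stats::nextn(n + m - 1L, 2L)
  fa <- stats::fft(c(a, numeric(N - n)))
  fb <- stats::fft(c(b, numeric(N - m)))
  Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n + m - 1L)] / N
}

# Convolution of a trace with a kernel centred at index (length(k)+1)/2,
# rescaled by dx so unit-area kernels preserve area.
.conv_centered <- function(y, k, dx) {
  n <- length(y); m <- length(k)
  full <- .conv_full(y, k)
  mid <- (m + 1L) %/% 2L
  full[mid:(mid + n - 1L)] * dx
}

# Convolve a binned stick density with the line shape; derivative_order 0 or 1.
# The derivative is applied analytically through the kernel. Gaussian and
# Lorentzian parts are combined into a single Voigt kernel so the long trace
# is convolved only once.
.apply_lineshape <- function(axis, density, ls, derivative_order = 1L) {
  dx <- axis[2] - axis[1]
  sigma <- ls$gaussian_pp / 2
  gamma <- sqrt(3) / 2 * ls$lorentzian_pp
  min_w <- min(c(if (sigma > 0) ls$gaussian_pp, if (gamma > 0) ls$lorentzian_pp))
  if (dx > min_w / 4)
    warning(sprintf("axis resolution %.4g coarser than a quarter of the narrowest width %.4g; spectrum may be undersampled",
                    dx, min_w), call. = FALSE)
  deriv <- derivative_order == 1L
  if (sigma > 0 && gamma > 0) {
    kg <- .gauss_kernel(dx, sigma, derivative = deriv)
    kl <- .lorentz_kernel(dx, gamma, FALSE, length(axis))
    k <- .conv_full(kg, kl) * dx        # both odd-length, centre stays mid
  } else if (sigma > 0) {
    k <- .gauss_kernel(dx, sigma, derivative = deriv)
  } else {
    k <- .lorentz_kernel(dx, gamma, deriv, length(axis))
  }
  .conv_centered(density, k, dx)
}

#' Construct a spectrum object
#'
#' @param axis Strictly monotone numeric axis (frequency offset in MHz, or
#'   field in mT).
#' @param intensity Intensity trace, same length as `axis` (>= 2 points).
#' @param axis_unit `"MHz"` or `"mT"`.
#' @param derivative_order 0 (absorption) or 1 (first derivative).
#' @param mw_frequency_GHz Microwave frequency the spectrum refers to.
#' @param metadata Named list of provenance information.
#' @return Object of class `epr_spectrum`.
#' @export
epr_spectrum <- function(axis, intensity, axis_unit = "MHz",
                         derivative_order = 1L, mw_frequency_GHz = 9.4,
                         metadata = list()) {
  if (length(axis) < 2L || length(axis) != length(intensity))
    stop_validation("axis and intensity must have equal length >= 2")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0)))
    stop_validation("axis must be strictly monotone")
  if (!derivative_order %in% c(0L, 1L))
    stop_validation("derivative_order must be 0 or 1")
  structure(list(axis = as.numeric(axis), intensity = as.numeric(intensity),
                 axis_unit = axis_unit, derivative_order = as.integer(derivative_order),
                 mw_frequency_GHz = mw_frequency_GHz, metadata = metadata),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf("<epr_spectrum> %d points, %.6g to %.6g %s, derivative order %d, %.4f GHz\n",
              length(x$axis), min(x$axis), max(x$axis), x$axis_unit,
              x$derivative_order, x$mw_frequency_GHz))
  invisible(x)
}

#' @export
plot.epr_spectrum <- function(x, ...) {
  xlab <- if (x$axis_unit == "mT") "Field (mT)" else "Offset (MHz)"
  ylab <- if (x$derivative_order == 1L) "dA/dx (arb.)" else "Absorption (arb.)"
  plot(x$axis, x$intensity, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Integrate a first-derivative spectrum to absorption mode
#'
#' @param spectrum An `epr_spectrum` with `derivative_order = 1`.
#' @return An `epr_spectrum` with `derivative_order = 0`.
#' @export
integrate_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  if (spectrum$derivative_order == 0L) return(spectrum)
  dx <- spectrum$axis[2] - spectrum$axis[1]
  absn <- cumsum(spectrum$intensity) * dx
  epr_spectrum(spectrum$axis, absn, spectrum$axis_unit, 0L,
               spectrum$mw_frequency_GHz, spectrum$metadata)
}

#' Double integral of a spectrum
#'
#' Integrates a first-derivative spectrum twice (once for absorption-mode
#' input); proportional to the number of spins and invariant under J, D and
#' line widths.
#'
#' @param spectrum An `epr_spectrum`.
#' @return Scalar double integral.
#' @export
double_integral <- function(spectrum) {
  absn <- integrate_spectrum(spectrum)
  dx <- absn$axis[2] - absn$axis[1]
  sum(absn$intensity) * dx
}

#' Convert a frequency-offset spectrum to a field axis
#'
#' First-order conversion about the mean g value: an offset `+dnu` (MHz)
#' appears at field `B_res - dnu / (13.9962 g)` (mT). Valid across the
#' narrow (< 10 mT) sweeps of trityl spectra. The returned axis increases in
#' field.
#'
#' @param spectrum An `epr_spectrum` with `axis_unit = "MHz"`.
#' @param g_ref Reference g value (default 2.0035).
#' @return An `epr_spectrum` with `axis_unit = "mT"`.
#' @export
spectrum_to_field <- function(spectrum, g_ref = 2.0035) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  if (spectrum$axis_unit != "MHz") return(spectrum)
  b_res <- spectrum$mw_frequency_GHz * 1000 / (MHZ_PER_MT_G * g_ref)
  b <- b_res - spectrum$axis / (MHZ_PER_MT_G * g_ref)
  ord <- order(b)
  epr_spectrum(b[ord], spectrum$intensity[ord], "mT",
               spectrum$derivative_order, spectrum$mw_frequency_GHz,
               c(spectrum$metadata, list(g_ref = g_ref)))
}
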