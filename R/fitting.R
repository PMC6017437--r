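# Parameter extraction: exchange coupling from satellite positions,
# full-spectrum least-squares fits, and the temperature dependence of J.

#' Construct a fit result
#'
#' @param parameters Named numeric vector of estimates.
#' @param se Named numeric vector of standard errors (>= 0, may be NA).
#' @param objective Residual sum of squares at the optimum.
#' @param converged Logical convergence flag.
#' @param seed Seed used for any stochastic path.
#' @param details Free-form diagnostics list.
#' @return Object of class `fit_result`.
#' @export
fit_result <- function(parameters, se = NULL, objective = NA_real_,
                       converged = TRUE, seed = NA_integer_, details = list()) {
  if (converged && !is.finite(objective))
    stop_validation("a converged fit must report a finite objective")
  if (!is.null(se) && any(se < 0, na.rm = TRUE))
    stop_validation("standard errors must be >= 0")
  structure(list(parameters = parameters, se = se, objective = objective,
                 converged = converged, seed = seed, details = details),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
      sprintf("(objective %.4g)\n", x$objective))
  for (nm in names(x$parameters)) {
    s <- if (!is.null(x$se) && nm %in% names(x$se) && is.finite(x$se[[nm]]))
      sprintf(" +- %.3g", x$se[[nm]]) else ""
    cat(sprintf("  %s = %.6g%s\n", nm, x$parameters[[nm]], s))
  }
  invisible(x)
}

# Predicted satellite line offsets for one site at a given J (both nuclear
# projections, allowed lines only).
.predicted_lines <- function(J, a, floor = 1e-3) {
  sp <- satellite_positions(J = J, site = "ipso",
                            hfcc = c(ipso = a), intensity_floor = floor)
  sp$offset_MHz
}

#' Fit the exchange coupling constant to observed satellite positions
#'
#' Minimizes the squared deviation between observed satellite line offsets
#' and the positions predicted by exact diagonalization of the two-electron,
#' one-13C Hamiltonian (each observation is matched to the nearest predicted
#' allowed line of its site). Grid search over J (default 0-500 MHz, 1 MHz
#' steps) followed by local refinement; the standard error is estimated from
#' the curvature of the objective.
#'
#' In the deep strong-coupling limit all satellite positions become
#' J-independent; a flat objective triggers a warning and the result reports
#' a lower bound `J >= 10 * max(delta_omega)` instead of an estimate.
#'
#' @param offsets Observed satellite line offsets from the central line, MHz
#'   (signs are ignored; positions are matched by magnitude pattern).
#' @param sites Character vector (same length) naming each offset's 13C site.
#' @param hfcc Site hyperfine table in MHz.
#' @param J_grid Search grid in MHz.
#' @param line_floor Relative intensity floor for predicted allowed lines.
#' @return A [fit_result()] with parameter `J_MHz` (and `J_lower_bound_MHz`
#'   in the degenerate case).
#' @export
#' @examples
#' obs <- satellite_positions(J = 77, site = "ipso")$offset_MHz
#' fit_J_from_satellites(obs, rep("ipso", length(obs)))
fit_J_from_satellites <- function(offsets, sites, hfcc = trityl_hfcc(),
                                  J_grid = seq(0, 500, by = 1),
                                  line_floor = 1e-3) {
  if (length(offsets) < 2L)
    stop_validation("at least 2 observed satellite offsets are required")
  if (length(sites) != length(offsets))
    stop_validation("sites must name one 13C site per offset")
  if (!all(sites %in% names(hfcc)))
    stop_validation("unknown site(s): ", paste(setdiff(sites, names(hfcc)), collapse = ", "))
  usites <- unique(sites)
  objective <- function(J) {
    tot <- 0
    for (s in usites) {
      pred <- .predicted_lines(J, hfcc[[s]], line_floor)
      obs <- offsets[sites == s]
      tot <- tot + sum(vapply(obs, function(o) min((o - pred)^2), numeric(1)))
    }
    tot
  }
  vals <- vapply(J_grid, objective, numeric(1))
  i_best <- which.min(vals)
  span <- max(vals) - min(vals)
  if (span <= 1e-10 || (vals[length(vals)] - min(vals)) < 1e-6 * max(span, 1)) {
    warning("satellite positions are J-independent here (deep strong coupling); ",
            "reporting a lower bound on J", call. = FALSE)
    jlb <- 10 * max(delta_omega_13C(hfcc[usites]))
    return(fit_result(c(J_MHz = NA_real_, J_lower_bound_MHz = jlb),
                      objective = min(vals), converged = FALSE,
                      details = list(flat_objective = TRUE)))
  }
  lo <- J_grid[max(1L, i_best - 2L)]; hi <- J_grid[min(length(J_grid), i_best + 2L)]
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-6)
  j_hat <- opt$minimum
  h <- 0.5
  curv <- (objective(j_hat + h) - 2 * opt$objective + objective(j_hat - h)) / h^2
  n <- length(offsets)
  sigma2 <- opt$objective / max(1L, n - 1L)
  se <- if (curv > 0) sqrt(2 * sigma2 / curv) else NA_real_
  fit_result(c(J_MHz = j_hat), se = c(J_MHz = se), objective = opt$objective,
             converged = TRUE,
             details = list(grid = range(J_grid), curvature = curv))
}

#' Fit a simulated spectrum model to an observed spectrum
#'
#' Least-squares fit of a liquid-solution mixture model (coupled biradical
#' plus monoradical contaminant) to a first-derivative trace. Free
#' parameters may include the exchange constant `J_MHz`, the localized
#' alpha-proton coupling `a_H_MHz`, the two line widths and the monoradical
#' signal fraction; the overall amplitude is profiled out analytically at
#' every step. Initialization is staged (coarse grids over `J_MHz` and
#' `a_H_MHz`, then Levenberg-Marquardt refinement) and fully deterministic
#' given `seed`.
#'
#' @param spectrum Observed [epr_spectrum()] (frequency axis, derivative 1).
#' @param fixture A [make_fixture()] compound fixture providing the model
#'   template (electron count, proton multiplicities, 13C table, fractions).
#' @param free Character vector of free parameter names, a subset of
#'   `c("J_MHz", "a_H_MHz", "gaussian_pp", "lorentzian_pp", "mono_fraction")`.
#' @param start Optional named numeric vector overriding staged starts.
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A [fit_result()]; parameters include the profiled `amplitude`.
#' @export
fit_spectrum <- function(spectrum, fixture,
                         free = c("J_MHz", "a_H_MHz", "gaussian_pp",
                                  "lorentzian_pp", "mono_fraction"),
                         start = NULL, seed = 1L, max_iter = 50L) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  stopifnot(inherits(fixture, "compound_fixture"))
  all_pars <- c("J_MHz", "a_H_MHz", "gaussian_pp", "lorentzian_pp", "mono_fraction")
  free <- match.arg(free, all_pars, several.ok = TRUE)
  lower <- c(J_MHz = 0, a_H_MHz = 0.01, gaussian_pp = 0.005,
             lorentzian_pp = 0.005, mono_fraction = 0)
  upper <- c(J_MHz = 500, a_H_MHz = 2, gaussian_pp = 2,
             lorentzian_pp = 2, mono_fraction = 1)
  axis <- spectrum$axis
  y_obs <- spectrum$intensity
  model_trace <- function(p) {
    mix <- .fixture_liquid_mixture(fixture,
                                   J = p[["J_MHz"]], a_H = p[["a_H_MHz"]],
                                   mono_fraction = p[["mono_fraction"]])
    sp <- simulate_isotropic_mixture(mix, axis,
                                     ls = lineshape(p[["gaussian_pp"]],
                                                    p[["lorentzian_pp"]]),
                                     derivative_order = spectrum$derivative_order)
    sp$intensity
  }
  resid_fun <- function(theta, fixed) {
    p <- fixed; p[names(theta)] <- theta
    m <- model_trace(p)
    amp <- sum(y_obs * m) / sum(m * m)
    y_obs - amp * m
  }
  p0 <- c(J_MHz = fixture$truth$J_MHz, a_H_MHz = fixture$truth$a_H_MHz,
          gaussian_pp = fixture$liquid_lineshape$gaussian_pp,
          lorentzian_pp = fixture$liquid_lineshape$lorentzian_pp,
          mono_fraction = fixture$monoradical_fraction)
  p0[] <- pmin(pmax(p0, lower), upper)
  # Generic, data-independent staged starts (truth values are NOT used).
  p_start <- c(J_MHz = 60, a_H_MHz = 0.2, gaussian_pp = 0.1,
               lorentzian_pp = 0.1, mono_fraction = 0.2)
  if ("J_MHz" %in% free) {
    jg <- seq(10, 150, by = 10)
    ssq <- vapply(jg, function(j) {
      p <- p_start; p[["J_MHz"]] <- j
      sum(resid_fun(p[free], p)^2)
    }, numeric(1))
    p_start[["J_MHz"]] <- jg[which.min(ssq)]
  }
  if ("a_H_MHz" %in% free) {
    ag <- seq(0.1, 0.6, by = 0.05)
    ssq <- vapply(ag, function(a) {
      p <- p_start; p[["a_H_MHz"]] <- a
      sum(resid_fun(p[free], p)^2)
    }, numeric(1))
    p_start[["a_H_MHz"]] <- ag[which.min(ssq)]
  }
  if (!is.null(start)) p_start[names(start)] <- start
  fixed <- p_start
  fixed[setdiff(all_pars, free)] <- p0[setdiff(all_pars, free)]
  theta0 <- p_start[free]
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun, fixed = fixed,
                            lower = lower[free], upper = upper[free],
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ptol = 1e-10, ftol = 1e-10))
  p_hat <- fixed; p_hat[free] <- fit$par
  m <- model_trace(p_hat)
  amp <- sum(y_obs * m) / sum(m * m)
  rss <- sum((y_obs - amp * m)^2)
  dof <- max(1L, length(y_obs) - length(free) - 1L)
  se <- tryCatch({
    cov <- solve(fit$hessian) * rss / dof
    s <- sqrt(pmax(0, diag(cov)))
    names(s) <- free
    s
  }, error = function(e) stats::setNames(rep(NA_real_, length(free)), free))
  converged <- fit$info %in% 1:4
  fit_result(c(p_hat[free], amplitude = amp), se = se, objective = rss,
             converged = converged, seed = as.integer(seed),
             details = list(info = fit$info, message = fit$message,
                            start = p_start[free], fixed = fixed[setdiff(all_pars, free)]))
}

#' Construct a temperature series of exchange couplings
#'
#' @param T_K Temperatures in K (> 0).
#' @param J_MHz Exchange coupling constants in MHz.
#' @return Object of class `temperature_series`.
#' @export
temperature_series <- function(T_K, J_MHz) {
  if (length(T_K) != length(J_MHz))
    stop_validation("T_K and J_MHz must have equal length")
  if (any(T_K <= 0)) stop_validation("temperatures must be > 0 K")
  structure(list(T_K = as.numeric(T_K), J_MHz = as.numeric(J_MHz)),
            class = "temperature_series")
}

#' Fit the linear temperature dependence of the exchange coupling
#'
#' Ordinary least squares of J on T; exchange couplings of conformationally
#' flexible biradicals often vary approximately linearly with temperature.
#'
#' @param series A [temperature_series()] with >= 2 distinct temperatures.
#' @return The series augmented with `slope_MHz_per_K`, `intercept_MHz`,
#'   `residuals` and the underlying `lm` fit.
#' @export
#' @examples
#' s <- temperature_series(c(213, 253, 293), c(49.3, 61.7, 74.1))
#' fit_J_temperature(s)$slope_MHz_per_K
fit_J_temperature <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  if (length(unique(series$T_K)) < 2L)
    stop("fitting J(T) requires at least 2 distinct temperatures")
  fit <- stats::lm(J ~ T, data = data.frame(T = series$T_K, J = series$J_MHz))
  series$slope_MHz_per_K <- unname(stats::coef(fit)[2])
  series$intercept_MHz <- unname(stats::coef(fit)[1])
  series$residuals <- unname(stats::residuals(fit))
  series$fit <- fit
  class(series) <- c("temperature_series_fit", class(series))
  series
}

#' Extrapolate the fitted J(T) line to a target temperature
#'
#' @param series_fit Result of [fit_J_temperature()].
#' @param T_target Temperature in K (e.g. the glass transition).
#' @return List with `J_MHz`, `T_K` and `extrapolated` (TRUE when outside
#'   the measured range).
#' @export
extrapolate_J <- function(series_fit, T_target) {
  stopifnot(inherits(series_fit, "temperature_series_fit"))
  if (T_target <= 0) stop_validation("T_target must be > 0 K")
  J <- series_fit$intercept_MHz + series_fit$slope_MHz_per_K * T_target
  list(J_MHz = J, T_K = T_target,
       extrapolated = T_target < min(series_fit$T_K) ||
         T_target > max(series_fit$T_K))
}

#' Estimate the glass transition temperature from the melting point
#'
#' Empirical two-thirds rule for glass-forming solvents: `Tg ~ (2/3) Tm`.
#'
#' @param T_m Melting point in K (> 0).
#' @return Estimated glass transition temperature in K.
#' @export
#' @examples
#' estimate_Tg(175)  # ~116.7 K
estimate_Tg <- function(T_m) {
  if (!is.numeric(T_m) || !is.finite(T_m) || T_m <= 0)
    stop_validation("T_m must be a positive temperature in K")
  2 / 3 * T_m
}
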