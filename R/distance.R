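# Regime-correct conversion between the dipolar coupling constant and the
# inter-spin distance (point-dipole approximation, g ~ 2).

#' Point-dipole conversion constant
#'
#' Default is the conventional 52.01 MHz nm^3 for two g ~ 2 electrons; an
#' explicit g pair rescales it as `g1 g2 / g_e^2` (opt-in; the printed
#' constant is used verbatim otherwise for reproducibility).
#'
#' @param g1,g2 Optional g values of the two spins.
#' @return Constant in MHz nm^3.
#' @export
dipolar_constant <- function(g1 = NULL, g2 = NULL) {
  if (is.null(g1) && is.null(g2)) return(DIP_CONST_MHZ_NM3)
  if (is.null(g2)) g2 <- g1
  DIP_CONST_MHZ_NM3 * (g1 * g2) / G_FREE_ELECTRON^2
}

.check_distance_regime <- function(regime) {
  regime <- as.character(regime[1])
  if (regime == "intermediate")
    stop("no closed-form distance conversion exists in the intermediate regime; ",
         "simulate the full spectrum by diagonalization instead")
  match.arg(regime, c("weak", "strong"))
}

#' Convert a dipolar coupling constant to an inter-spin distance
#'
#' Weak coupling: `r_nm = (52.01 / D)^(1/3)` nm. Strong coupling: the powder
#' singularities sit 50% higher than for an uncoupled pair at the same
#' distance, so `r_nm = (1.5 * 52.01 / D)^(1/3)` with `D` the apparent coupling
#' read from the stretched pattern.
#'
#' @param D Dipolar coupling constant in MHz (> 0).
#' @param regime `"weak"` or `"strong"`.
#' @param constant Conversion constant in MHz nm^3 (see [dipolar_constant()]).
#' @return Object of class `distance_result` with fields `r_nm`, `D_MHz`,
#'   `regime`, `constant`.
#' @export
#' @examples
#' distance_from_D(1.2, "weak")    # 3.51 nm
#' distance_from_D(7.0, "strong")  # 2.23 nm
distance_from_D <- function(D, regime = c("weak", "strong"),
                            constant = dipolar_constant()) {
  regime <- .check_distance_regime(regime)
  if (!is.numeric(D) || !is.finite(D) || D <= 0)
    stop_validation("D must be a positive finite coupling constant in MHz")
  eff <- if (regime == "strong") STRONG_COUPLING_STRETCH * constant else constant
  structure(list(r_nm = (eff / D)^(1 / 3), D_MHz = D, regime = regime,
                 constant = constant),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> D = %.4g MHz (%s coupling) -> r = %.4g nm\n",
              x$D_MHz, x$regime, x$r_nm))
  invisible(x)
}

#' Convert an inter-spin distance to a dipolar coupling constant
#'
#' Exact inverse of [distance_from_D()].
#'
#' @param r_nm Distance in nm (> 0).
#' @inheritParams distance_from_D
#' @return D in MHz.
#' @export
#' @examples
#' D_from_distance(3.51, "weak")  # ~1.2 MHz
D_from_distance <- function(r_nm, regime = c("weak", "strong"),
                            constant = dipolar_constant()) {
  regime <- .check_distance_regime(regime)
  if (!is.numeric(r_nm) || any(!is.finite(r_nm)) || any(r_nm <= 0))
    stop_validation("r_nm must be a positive finite distance in nm")
  eff <- if (regime == "strong") STRONG_COUPLING_STRETCH * constant else constant
  eff / r_nm^3
}

#' Apparent-distance bias of a misread strong-coupling pattern
#'
#' Applying the weak-coupling conversion to a strong-coupling (1.5x
#' stretched) powder pattern biases distances to `1.5^(-1/3) ~ 87%` of the
#' actual inter-spin distance.
#'
#' @return The dimensionless ratio apparent/actual, `(1/1.5)^(1/3)`.
#' @export
#' @examples
#' apparent_distance_bias()  # 0.8736
apparent_distance_bias <- function() {
  STRONG_COUPLING_STRETCH^(-1 / 3)
}
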