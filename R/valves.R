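#' Smoothed-diode valve resistance
#'
#' The valve resistance interpolates between its open value `R_min` and its
#' closed value `R_max` on a log scale, smoothly switched by the pressure
#' difference across the valve:
#' \deqn{R = 10^c, \quad c = \log_{10} R_{min} +
#'   (\log_{10} R_{max} - \log_{10} R_{min})
#'   \left[\tfrac12 + \tfrac1\pi \arctan\!\big(\tfrac{200\pi}{2}(P_2 - P_1)\big)\right],}
#' with `P1` the upstream and `P2` the downstream pressure (mmHg). At equal
#' pressures the resistance is the geometric mean of `R_min` and `R_max`;
#' for strongly negative `P2 - P1` (forward driving) it tends to `R_min`,
#' for strongly positive `P2 - P1` (reverse loading) to `R_max`, and it is
#' monotone non-decreasing in `P2 - P1`.
#'
#' @param P1 Upstream pressure (mmHg), vectorized.
#' @param P2 Downstream pressure (mmHg), vectorized.
#' @param valve A [valve_model()].
#' @return Resistance (mmHg s/ml).
#' @export
valve_resistance <- function(P1, P2, valve) {
  stopifnot(inherits(valve, "valve_model"))
  lmin <- log10(valve$R_min)
  lmax <- log10(valve$R_max)
  cc <- lmin + (lmax - lmin) * (0.5 + atan(valve$steepness * (P2 - P1)) / pi)
  10^cc
}

#' Flow through a smoothed-diode valve
#'
#' `Q = (P1 - P2) / R(P1, P2)`. A forward pressure difference drives a large
#' positive flow through the near-open resistance; a reverse difference
#' drives only a small leakage flow through the near-closed resistance, so
#' the characteristic is strongly asymmetric (diode-like).
#'
#' @inheritParams valve_resistance
#' @return Flow rate (ml/s).
#' @export
valve_flow <- function(P1, P2, valve) {
  (P1 - P2) / valve_resistance(P1, P2, valve)
}
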