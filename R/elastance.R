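#' Chamber activation ramp
#'
#' Piecewise-cosine activation `r(t)` of an elastance chamber within one
#' heartbeat: a raised-cosine ramp up over the contraction phase, a
#' raised-cosine ramp down over the relaxation phase, and zero afterwards,
#'
#' \deqn{r(t) = \frac12 (1 - \cos(\pi t / T_{contr})), \quad t \le T_{contr}}
#' \deqn{r(t) = \frac12 (1 + \cos(\pi (t - T_{contr}) / T_{relax})), \quad
#'       T_{contr} < t \le T_{contr} + T_{relax}}
#' \deqn{r(t) = 0, \quad t > T_{contr} + T_{relax}.}
#'
#' The ramp is continuous everywhere and maps into `[0, 1]`. The caller is
#' responsible for reducing `t` modulo the heartbeat period and for
#' subtracting the activation onset; [elastance_value()] does both.
#'
#' @param t Time since activation onset (s), vectorized; `0 <= t`.
#' @param chamber An [elastance_chamber()].
#' @return Activation values in `[0, 1]`, same length as `t`.
#' @export
activation <- function(t, chamber) {
  stopifnot(inherits(chamber, "elastance_chamber"))
  Tc <- chamber$T_contr
  Tr <- chamber$T_relax
  r <- numeric(length(t))
  up <- t <= Tc
  dn <- t > Tc & t <= Tc + Tr
  r[up] <- 0.5 * (1 - cos(pi * t[up] / Tc))
  r[dn] <- 0.5 * (1 + cos(pi * (t[dn] - Tc) / Tr))
  r
}

#' Time-varying chamber elastance
#'
#' `E(t) = E_a r(t') + E_b` with `t' = (t - t_onset) mod T_cycle`, so the
#' elastance is `T_cycle`-periodic and bounded by `[E_b, E_a + E_b]`.
#'
#' @param t Absolute time (s), vectorized.
#' @param chamber An [elastance_chamber()].
#' @param T_cycle Heartbeat period (s).
#' @return Elastance (mmHg/ml), same length as `t`.
#' @export
elastance_value <- function(t, chamber, T_cycle = 0.8) {
  tl <- (t - chamber$t_onset) %% T_cycle
  chamber$E_a * activation(tl, chamber) + chamber$E_b
}

#' Chamber pressure from the elastance law
#'
#' `P = E(t) (V - V_0)`: pressure is the time-varying elastance times the
#' volume above the unstressed volume.
#'
#' @param V Chamber volume (ml), vectorized.
#' @param t Absolute time (s).
#' @param chamber An [elastance_chamber()].
#' @param T_cycle Heartbeat period (s).
#' @return Pressure (mmHg).
#' @export
chamber_pressure <- function(V, t, chamber, T_cycle = 0.8) {
  elastance_value(t, chamber, T_cycle) * (V - chamber$V_0)
}
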