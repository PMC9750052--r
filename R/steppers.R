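#' One explicit-Euler step of the circulation ODEs
#'
#' `y_{n+1} = y_n + dt f1(t_n, y_n)`, with the algebraic vector evaluated at
#' the step point. Interface forcings (open variants) are held constant over
#' the step: they are per-step data exchanged by the coupling algorithms.
#'
#' @param t Time at the start of the step (s).
#' @param y Named state vector.
#' @param dt Step size (s), > 0.
#' @param topology A [circuit_topology()].
#' @param forcings Interface forcings for open variants (see
#'   [assemble_rhs()]).
#' @return State vector at `t + dt`.
#' @export
step_euler <- function(t, y, dt, topology, forcings = NULL) {
  stopifnot(dt > 0)
  y1 <- y + dt * assemble_rhs(t, y, topology, forcings)
  if (any(!is.finite(y1))) {
    stop("non-finite state after Euler step (instability)", call. = FALSE)
  }
  y1
}

#' One classical Runge-Kutta (RK4) step of the circulation ODEs
#'
#' Classical 4th-order Runge-Kutta applied to the semi-explicit DAE: the
#' algebraic vector `z` is an explicit function of `(t, y)` and is
#' re-evaluated inside every stage, so no index reduction is needed.
#' Interface forcings are held constant over the step.
#'
#' @inheritParams step_euler
#' @return State vector at `t + dt`.
#' @export
step_rk4 <- function(t, y, dt, topology, forcings = NULL) {
  stopifnot(dt > 0)
  k1 <- assemble_rhs(t, y, topology, forcings)
  k2 <- assemble_rhs(t + dt / 2, y + dt / 2 * k1, topology, forcings)
  k3 <- assemble_rhs(t + dt / 2, y + dt / 2 * k2, topology, forcings)
  k4 <- assemble_rhs(t + dt, y + dt * k3, topology, forcings)
  y1 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(y1))) {
    stop("non-finite state after RK4 step (instability)", call. = FALSE)
  }
  y1
}

#' @keywords internal
.stepper <- function(method = c("rk4", "euler")) {
  method <- match.arg(method)
  switch(method, rk4 = step_rk4, euler = step_euler)
}
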