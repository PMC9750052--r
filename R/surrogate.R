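#' Advance the pulmonary-artery RLC surrogate one step
#'
#' The surrogate replaces the distributed pulmonary-artery model by the RLC
#' block of the closed loop: a capacitor `C_PA` at the inlet node (pressure
#' `P_PA`) and a series resistance-inductance `R_PA`, `L_PA` carrying the
#' flow `Q_PA` towards the downstream pressure `P_OUT`,
#' \deqn{C_{PA} \dot P_{PA} = Q_{IN} - Q_{PA}, \qquad
#'       L_{PA} \dot Q_{PA} = -R_{PA} Q_{PA} - (P_{OUT} - P_{PA}).}
#' It satisfies the bridging rule by construction: the flow-receiving side
#' sees a capacitor, the pressure-receiving side an inductor. Forcings are
#' held constant over the step; the integrator matches the 0D core's scheme
#' so that a partitioned run differs from the monolithic closed loop by the
#' splitting error only.
#'
#' @param t Time at the start of the step (s).
#' @param dt Step size (s).
#' @param Q_IN Inlet flow forcing (ml/s).
#' @param P_OUT Downstream pressure forcing (mmHg).
#' @param state Named vector `c(P_PA=, Q_PA=)`.
#' @param pa An [rlc_compartment()] with the block parameters.
#' @param method `"rk4"` (default) or `"euler"`.
#' @return List with `P_IN` (the inlet-node pressure `P_PA`, mmHg), `Q_OUT`
#'   (the outgoing flow `Q_PA`, ml/s) and the advanced `state`.
#' @export
surrogate_advance <- function(t, dt, Q_IN, P_OUT, state, pa,
                              method = c("rk4", "euler")) {
  method <- match.arg(method)
  rhs <- function(s) {
    c(P_PA = (Q_IN - s[["Q_PA"]]) / pa$C,
      Q_PA = (-pa$R * s[["Q_PA"]] - (P_OUT - s[["P_PA"]])) / pa$L)
  }
  s <- state
  if (method == "euler") {
    s <- s + dt * rhs(s)
  } else {
    k1 <- rhs(s); k2 <- rhs(s + dt / 2 * k1)
    k3 <- rhs(s + dt / 2 * k2); k4 <- rhs(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (any(!is.finite(s))) stop("non-finite surrogate state", call. = FALSE)
  list(P_IN = s[["P_PA"]], Q_OUT = s[["Q_PA"]], state = s)
}

#' Pulmonary-artery RLC surrogate as a distributed model
#'
#' Wraps [surrogate_advance()] into the distributed-model contract used by
#' the coupling drivers: `advance(t, dt, Q_IN, P_OUT)` returning
#' `(P_IN, Q_OUT)`, plus `checkpoint()`/`restore(token)` so that the
#' splitting-implicit algorithm can re-run a step during subiterations.
#' Restoring a checkpoint and advancing with identical inputs reproduces
#' identical outputs bitwise.
#'
#' @param pa An [rlc_compartment()] with `R_PA`, `L_PA`, `C_PA`; defaults to
#'   the shipped closed-loop pulmonary-artery block.
#' @param state0 Initial internal state `c(P_PA=, Q_PA=)`.
#' @param method Internal integrator, `"rk4"` (default) or `"euler"`.
#' @return An object of class `distributed_model` (a list of closures:
#'   `advance`, `checkpoint`, `restore`, `state`, `label`).
#' @export
#' @examples
#' dm <- pa_surrogate()
#' tok <- dm$checkpoint()
#' out <- dm$advance(0, 1e-3, Q_IN = 100, P_OUT = 10)
#' dm$restore(tok)
pa_surrogate <- function(pa = circulation_params()$compartments$pa,
                         state0 = c(P_PA = 0, Q_PA = 0),
                         method = c("rk4", "euler")) {
  method <- match.arg(method)
  env <- new.env(parent = emptyenv())
  env$state <- state0[c("P_PA", "Q_PA")]
  structure(list(
    advance = function(t, dt, Q_IN, P_OUT) {
      out <- surrogate_advance(t, dt, Q_IN, P_OUT, env$state, pa, method)
      env$state <- out$state
      list(P_IN = out$P_IN, Q_OUT = out$Q_OUT)
    },
    checkpoint = function() env$state,
    restore = function(token) {
      env$state <- token
      invisible(NULL)
    },
    state = function() env$state,
    label = "pa_surrogate"
  ), class = "distributed_model")
}

#' @export
print.distributed_model <- function(x, ...) {
  cat("<distributed_model>", x$label, "\n")
  invisible(x)
}
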