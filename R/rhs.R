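#' Algebraic variables of the circulation circuit
#'
#' Evaluates the algebraic closure `z = f2(t, y)`: the four chamber
#' pressures from the elastance law, the four valve flows from the
#' smoothed-diode law, and the instantaneous valve resistances.
#'
#' The pulmonary valve's downstream pressure depends on the circuit
#' variant: the proximal-compartment pressure `P_PC` in the closed loop and
#' in open setting 2, and the externally supplied interface pressure `P_IN`
#' in open setting 1 (which therefore requires `forcings$P_IN`).
#'
#' @param t Time (s).
#' @param y Named state vector in the topology's layout.
#' @param topology A [circuit_topology()].
#' @param forcings For open variants, a list with elements `P_IN` (mmHg) and
#'   `Q_OUT` (ml/s); must be `NULL` for the closed variant. Only
#'   `open_setting1` uses `P_IN` inside the algebraic closure.
#' @return Named numeric vector `z` with chamber pressures `P_RA, P_RV,
#'   P_LA, P_LV` (mmHg), valve flows `Q_TV, Q_PV, Q_MVV, Q_AV` (ml/s) and
#'   valve resistances `R_TV, R_PV, R_MVV, R_AV` (mmHg s/ml).
#' @export
algebraic_eval <- function(t, y, topology, forcings = NULL) {
  p <- topology$params
  Tc <- p$T_cycle
  P_RA <- chamber_pressure(y[["V_RA"]], t, p$chambers$RA, Tc)
  P_RV <- chamber_pressure(y[["V_RV"]], t, p$chambers$RV, Tc)
  P_LA <- chamber_pressure(y[["V_LA"]], t, p$chambers$LA, Tc)
  P_LV <- chamber_pressure(y[["V_LV"]], t, p$chambers$LV, Tc)

  # pulmonary valve downstream node
  P_pv_down <- if (topology$variant == "open_setting1") {
    if (is.null(forcings) || is.null(forcings$P_IN)) {
      stop("open_setting1 needs forcings$P_IN to evaluate the pulmonary valve",
           call. = FALSE)
    }
    forcings$P_IN
  } else {
    y[["P_PC"]]
  }
  # aortic valve feeds the systemic arterial capacitor node
  R_TV <- valve_resistance(P_RA, P_RV, p$valves$TV)
  R_PV <- valve_resistance(P_RV, P_pv_down, p$valves$PV)
  R_MVV <- valve_resistance(P_LA, P_LV, p$valves$MV)
  R_AV <- valve_resistance(P_LV, y[["P_ART_SYS"]], p$valves$AV)

  c(P_RA = P_RA, P_RV = P_RV, P_LA = P_LA, P_LV = P_LV,
    Q_TV = (P_RA - P_RV) / R_TV,
    Q_PV = (P_RV - P_pv_down) / R_PV,
    Q_MVV = (P_LA - P_LV) / R_MVV,
    Q_AV = (P_LV - y[["P_ART_SYS"]]) / R_AV,
    R_TV = R_TV, R_PV = R_PV, R_MVV = R_MVV, R_AV = R_AV)
}

#' Right-hand side of the circulation ODE system
#'
#' Assembles `dy/dt = f1(t, y, z, P_IN, Q_OUT)` for the selected circuit
#' variant: chamber volume balances, capacitor equations
#' `C dP/dt = Q_in - Q_out` and inductor equations
#' `L dQ/dt = -R Q - (P_downstream - P_upstream)`.
#'
#' For the open variants the interface data enter as
#' `L_IN dQ_IN/dt = -R_IN Q_IN - (P_IN - P_PC)` at the inlet (setting 2)
#' and `C_OUT dP_MV/dt = Q_OUT - Q_MV` at the outlet (both settings). In
#' setting 1 the pulmonary valve drains the right ventricle directly against
#' `P_IN`, so the provided inlet flow is the algebraic valve flow `Q_PV`.
#'
#' @inheritParams algebraic_eval
#' @param z Optional pre-computed algebraic vector from [algebraic_eval()];
#'   computed if missing.
#' @return Named vector `dy/dt` in the topology's layout.
#' @export
assemble_rhs <- function(t, y, topology, forcings = NULL, z = NULL) {
  variant <- topology$variant
  open <- variant != "closed"
  if (open) {
    if (is.null(forcings) || is.null(forcings$P_IN) || is.null(forcings$Q_OUT)) {
      stop("open variants require forcings P_IN and Q_OUT", call. = FALSE)
    }
  } else if (!is.null(forcings)) {
    stop("the closed variant takes no interface forcings", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("non-finite state vector", call. = FALSE)
  if (is.null(z)) z <- algebraic_eval(t, y, topology, forcings)
  cmp <- topology$params$compartments

  dy <- numeric(length(y))
  names(dy) <- names(y)

  dy[["V_RA"]] <- y[["Q_VEN_SYS"]] - z[["Q_TV"]]
  dy[["V_RV"]] <- z[["Q_TV"]] - z[["Q_PV"]]
  dy[["V_LA"]] <- y[["Q_VEN_PUL"]] - z[["Q_MVV"]]
  dy[["V_LV"]] <- z[["Q_MVV"]] - z[["Q_AV"]]

  if (variant != "open_setting1") {
    # proximal compartment: capacitor fed by the pulmonary valve, drained by Q_IN
    dy[["P_PC"]] <- (z[["Q_PV"]] - y[["Q_IN"]]) / cmp$proximal$C
    # inductor between P_PC and the next node (P_PA closed, P_IN open)
    P_down_in <- if (variant == "closed") y[["P_PA"]] else forcings$P_IN
    dy[["Q_IN"]] <- (-cmp$proximal$R * y[["Q_IN"]] -
                       (P_down_in - y[["P_PC"]])) / cmp$proximal$L
  }
  if (variant == "closed") {
    dy[["P_PA"]] <- (y[["Q_IN"]] - y[["Q_PA"]]) / cmp$pa$C
    dy[["Q_PA"]] <- (-cmp$pa$R * y[["Q_PA"]] -
                       (y[["P_MV"]] - y[["P_PA"]])) / cmp$pa$L
  }
  # microvasculature capacitor: fed by Q_PA (closed) or interface Q_OUT (open)
  Q_into_mv <- switch(variant,
    closed = y[["Q_PA"]],
    open_setting2 = forcings$Q_OUT,
    open_setting1 = forcings$Q_OUT)
  dy[["P_MV"]] <- (Q_into_mv - y[["Q_MV"]]) / cmp$micro$C
  dy[["Q_MV"]] <- (-cmp$micro$R * y[["Q_MV"]] -
                     (y[["P_VEN_PUL"]] - y[["P_MV"]])) / cmp$micro$L

  dy[["P_VEN_PUL"]] <- (y[["Q_MV"]] - y[["Q_VEN_PUL"]]) / cmp$ven_pul$C
  dy[["Q_VEN_PUL"]] <- (-cmp$ven_pul$R * y[["Q_VEN_PUL"]] -
                          (z[["P_LA"]] - y[["P_VEN_PUL"]])) / cmp$ven_pul$L

  dy[["P_ART_SYS"]] <- (z[["Q_AV"]] - y[["Q_ART_SYS"]]) / cmp$art_sys$C
  dy[["Q_ART_SYS"]] <- (-cmp$art_sys$R * y[["Q_ART_SYS"]] -
                          (y[["P_VEN_SYS"]] - y[["P_ART_SYS"]])) / cmp$art_sys$L

  dy[["P_VEN_SYS"]] <- (y[["Q_ART_SYS"]] - y[["Q_VEN_SYS"]]) / cmp$ven_sys$C
  dy[["Q_VEN_SYS"]] <- (-cmp$ven_sys$R * y[["Q_VEN_SYS"]] -
                          (z[["P_RA"]] - y[["P_VEN_SYS"]])) / cmp$ven_sys$L
  dy
}

#' Interface outputs of an open circuit
#'
#' The quantities an open 0D circuit provides to the distributed model:
#' the inlet flow `Q_IN` (the proximal inductor flow in setting 2, the
#' pulmonary-valve flow in setting 1) and the outlet pressure
#' `P_OUT = P_MV` (the microvasculature capacitor pressure).
#'
#' @inheritParams algebraic_eval
#' @return List with `Q_IN` (ml/s) and `P_OUT` (mmHg).
#' @export
interface_outputs <- function(t, y, topology, forcings = NULL) {
  Q_IN <- if (topology$variant == "open_setting1") {
    z <- algebraic_eval(t, y, topology, forcings)
    z[["Q_PV"]]
  } else {
    y[["Q_IN"]]
  }
  list(Q_IN = unname(Q_IN), P_OUT = unname(y[["P_MV"]]))
}
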