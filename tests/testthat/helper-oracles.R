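# Independent oracles used across the suite. These are deliberately written
# as literal transcriptions of the governing equations, separate from the
# package's assembly code paths.

# natural-log transcription of the smoothed-diode resistance
oracle_valve_resistance <- function(P1, P2, R_min, R_max, k = 100 * pi) {
  exp(log(R_min) + (log(R_max) - log(R_min)) *
        (0.5 + atan(k * (P2 - P1)) / pi))
}

# literal per-equation transcription of the closed-loop circulation ODEs
oracle_closed_rhs <- function(t, y, p) {
  Tc <- p$T_cycle
  act <- function(tt, ch) {
    tl <- (tt - ch$t_onset) %% Tc
    if (tl <= ch$T_contr) {
      0.5 * (1 - cos(pi * tl / ch$T_contr))
    } else if (tl <= ch$T_contr + ch$T_relax) {
      0.5 * (1 + cos(pi * (tl - ch$T_contr) / ch$T_relax))
    } else 0
  }
  press <- function(V, ch) (ch$E_a * act(t, ch) + ch$E_b) * (V - ch$V_0)
  P_RA <- press(y[["V_RA"]], p$chambers$RA)
  P_RV <- press(y[["V_RV"]], p$chambers$RV)
  P_LA <- press(y[["V_LA"]], p$chambers$LA)
  P_LV <- press(y[["V_LV"]], p$chambers$LV)
  vr <- function(P1, P2, v) oracle_valve_resistance(P1, P2, v$R_min, v$R_max,
                                                    v$steepness)
  Q_TV <- (P_RA - P_RV) / vr(P_RA, P_RV, p$valves$TV)
  Q_PV <- (P_RV - y[["P_PC"]]) / vr(P_RV, y[["P_PC"]], p$valves$PV)
  Q_MVV <- (P_LA - P_LV) / vr(P_LA, P_LV, p$valves$MV)
  Q_AV <- (P_LV - y[["P_ART_SYS"]]) / vr(P_LV, y[["P_ART_SYS"]], p$valves$AV)
  cmp <- p$compartments
  c(V_RA = y[["Q_VEN_SYS"]] - Q_TV,
    V_RV = Q_TV - Q_PV,
    V_LA = y[["Q_VEN_PUL"]] - Q_MVV,
    V_LV = Q_MVV - Q_AV,
    P_PC = (Q_PV - y[["Q_IN"]]) / cmp$proximal$C,
    P_PA = (y[["Q_IN"]] - y[["Q_PA"]]) / cmp$pa$C,
    P_MV = (y[["Q_PA"]] - y[["Q_MV"]]) / cmp$micro$C,
    P_VEN_PUL = (y[["Q_MV"]] - y[["Q_VEN_PUL"]]) / cmp$ven_pul$C,
    P_ART_SYS = (Q_AV - y[["Q_ART_SYS"]]) / cmp$art_sys$C,
    P_VEN_SYS = (y[["Q_ART_SYS"]] - y[["Q_VEN_SYS"]]) / cmp$ven_sys$C,
    Q_IN = (-cmp$proximal$R * y[["Q_IN"]] - (y[["P_PA"]] - y[["P_PC"]])) / cmp$proximal$L,
    Q_PA = (-cmp$pa$R * y[["Q_PA"]] - (y[["P_MV"]] - y[["P_PA"]])) / cmp$pa$L,
    Q_MV = (-cmp$micro$R * y[["Q_MV"]] - (y[["P_VEN_PUL"]] - y[["P_MV"]])) / cmp$micro$L,
    Q_VEN_PUL = (-cmp$ven_pul$R * y[["Q_VEN_PUL"]] - (P_LA - y[["P_VEN_PUL"]])) / cmp$ven_pul$L,
    Q_ART_SYS = (-cmp$art_sys$R * y[["Q_ART_SYS"]] - (y[["P_VEN_SYS"]] - y[["P_ART_SYS"]])) / cmp$art_sys$L,
    Q_VEN_SYS = (-cmp$ven_sys$R * y[["Q_VEN_SYS"]] - (P_RA - y[["P_VEN_SYS"]])) / cmp$ven_sys$L)
}

# random physiological-ish closed state
random_closed_state <- function() {
  stats::setNames(c(
    stats::runif(4, 20, 180),            # chamber volumes
    stats::runif(6, 2, 100),             # capacitor pressures
    stats::runif(6, -50, 250)            # inductor flows
  ), state_names("closed"))
}

# closed-form step of the 2-state LTI surrogate under constant forcings,
# via the matrix exponential (Matrix::expm)
oracle_surrogate_step <- function(state, dt, Q_IN, P_OUT, pa) {
  A <- matrix(c(0, -1 / pa$C,
                1 / pa$L, -pa$R / pa$L), 2, 2, byrow = TRUE)
  b <- c(Q_IN / pa$C, -P_OUT / pa$L)
  x0 <- c(state[["P_PA"]], state[["Q_PA"]])
  xs <- solve(A, -b)                     # equilibrium
  x1 <- as.vector(Matrix::expm(A * dt) %*% (x0 - xs)) + xs
  stats::setNames(x1, c("P_PA", "Q_PA"))
}

# equilibrium closed state with all pressures equal and no flow at time t;
# every component of the right-hand side vanishes there
equilibrium_state <- function(p, P_star = 10, t = 0.1) {
  ch <- p$chambers
  E <- function(chm) chm$E_a * activation((t - chm$t_onset) %% p$T_cycle, chm) + chm$E_b
  stats::setNames(c(
    ch$RA$V_0 + P_star / E(ch$RA), ch$RV$V_0 + P_star / E(ch$RV),
    ch$LA$V_0 + P_star / E(ch$LA), ch$LV$V_0 + P_star / E(ch$LV),
    rep(P_star, 6), rep(0, 6)
  ), state_names("closed"))
}

surrogate_matched <- function(p = circulation_params(), method = "rk4") {
  y0 <- default_initial_state(p, "closed")
  pa_surrogate(p$compartments$pa,
               state0 = c(P_PA = y0[["P_PA"]], Q_PA = y0[["Q_PA"]]),
               method = method)
}

rel_l2 <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
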