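p_ref <- circulation_params()

test_that("state layouts expose the interface states of each variant", {
  expect_length(state_names("closed"), 16)
  expect_length(state_names("open_setting2"), 14)
  expect_length(state_names("open_setting1"), 12)
  expect_false("P_PA" %in% state_names("open_setting2"))
  expect_false("P_PC" %in% state_names("open_setting1"))
  expect_error(state_names("ring"), "unknown")
})

test_that("bridging check predicts which coupling topologies are admissible", {
  expect_true(attr(check_bridging(circuit_topology("open_setting2", p_ref)), "pass"))
  rep1 <- check_bridging(circuit_topology("open_setting1", p_ref))
  expect_false(attr(rep1, "pass"))
  expect_false(rep1$ok[rep1$interface == "inlet"])   # diode sits at the inlet
  expect_true(rep1$ok[rep1$interface == "outlet"])
  repc <- check_bridging(circuit_topology("closed", p_ref))
  expect_true(attr(repc, "pass"))
  expect_equal(nrow(repc), 0)
})

test_that("total stored volume sums chambers and capacitor charges", {
  topo <- circuit_topology("closed", p_ref)
  y <- stats::setNames(rep(0, 16), state_names("closed"))
  y[c("V_RA", "V_RV", "V_LA", "V_LV")] <- c(50, 100, 40, 110)
  expect_equal(total_blood_volume(y, topo), 300)
  y2 <- y
  y2[["P_VEN_SYS"]] <- 2.5
  expect_equal(total_blood_volume(y2, topo) - total_blood_volume(y, topo),
               p_ref$compartments$ven_sys$C * 2.5)
})

test_that("the right-hand side vanishes at a uniform-pressure no-flow equilibrium", {
  topo <- circuit_topology("closed", p_ref)
  y_eq <- equilibrium_state(p_ref, P_star = 10, t = 0.1)
  z <- algebraic_eval(0.1, y_eq, topo)
  expect_equal(unname(z[c("Q_TV", "Q_PV", "Q_MVV", "Q_AV")]), rep(0, 4))
  expect_equal(max(abs(assemble_rhs(0.1, y_eq, topo))), 0, tolerance = 1e-12)
})

test_that("assembled RHS matches the independent per-equation transcription", {
  topo <- circuit_topology("closed", p_ref)
  withr::with_seed(42, {
    for (i in 1:100) {
      y <- random_closed_state()
      t <- runif(1, 0, 0.8)
      expect_equal(assemble_rhs(t, y, topo), oracle_closed_rhs(t, y, p_ref),
                   tolerance = 1e-13)
    }
  })
})

test_that("closed-loop RHS conserves total stored volume identically", {
  topo <- circuit_topology("closed", p_ref)
  caps <- with(p_ref$compartments,
               c(proximal$C, pa$C, micro$C, ven_pul$C, art_sys$C, ven_sys$C))
  withr::with_seed(7, {
    for (i in 1:20) {
      dy <- assemble_rhs(runif(1, 0, 0.8), random_closed_state(), topo)
      dvol <- sum(dy[1:4]) + sum(caps * dy[5:10])
      expect_equal(dvol, 0, tolerance = 1e-10)
    }
  })
})

test_that("algebraic closure respects valve bounds and external forcing contracts", {
  topo <- circuit_topology("closed", p_ref)
  withr::with_seed(3, {
    y <- random_closed_state()
    z <- algebraic_eval(0.3, y, topo)
    for (vn in c("R_TV", "R_PV", "R_MVV", "R_AV")) {
      expect_gte(z[[vn]], p_ref$valves$TV$R_min)
      expect_lte(z[[vn]], p_ref$valves$TV$R_max)
    }
  })
  topo1 <- circuit_topology("open_setting1", p_ref)
  y1 <- stats::setNames(rep(10, 12), state_names("open_setting1"))
  expect_error(algebraic_eval(0, y1, topo1), "P_IN")
  expect_error(assemble_rhs(0, y1, topo1), "forcings")
  yc <- default_initial_state(p_ref, "closed")
  expect_error(assemble_rhs(0, yc, topo, forcings = list(P_IN = 1, Q_OUT = 1)),
               "no interface forcings")
})

test_that("open setting 2 uses the interface data exactly where specified", {
  topo <- circuit_topology("open_setting2", p_ref)
  y <- default_initial_state(p_ref, "open_setting2")
  f <- list(P_IN = 17.3, Q_OUT = 55)
  dy <- assemble_rhs(0.2, y, topo, f)
  cmp <- p_ref$compartments
  z <- algebraic_eval(0.2, y, topo, f)
  expect_equal(dy[["Q_IN"]],
               (-cmp$proximal$R * y[["Q_IN"]] - (f$P_IN - y[["P_PC"]])) / cmp$proximal$L)
  expect_equal(dy[["P_MV"]], (f$Q_OUT - y[["Q_MV"]]) / cmp$micro$C)
  expect_equal(dy[["P_PC"]], (z[["Q_PV"]] - y[["Q_IN"]]) / cmp$proximal$C)
})

test_that("steppers leave a stationary state unchanged and match their definitions", {
  topo <- circuit_topology("closed", p_ref)
  y_eq <- equilibrium_state(p_ref, P_star = 8, t = 0.55)
  # the equilibrium is exact at frozen elastance; use a tiny step so the
  # elastance drift over the step stays below tolerance
  expect_equal(step_euler(0.55, y_eq, 1e-9, topo), y_eq, tolerance = 1e-9)
  expect_equal(step_rk4(0.55, y_eq, 1e-9, topo), y_eq, tolerance = 1e-9)
  withr::with_seed(5, {
    y <- default_initial_state(p_ref, "closed")
    expect_equal(step_euler(0.1, y, 1e-3, topo),
                 y + 1e-3 * assemble_rhs(0.1, y, topo))
  })
})

test_that("RK4 agrees with a refined Euler reference and shows fourth order", {
  topo <- circuit_topology("closed", p_ref)
  y0 <- default_initial_state(p_ref, "closed")
  advance <- function(stepper, dt, T_end, y) {
    t <- 0
    while (t < T_end - dt / 2) {
      y <- stepper(t, y, dt, topo)
      t <- t + dt
    }
    y
  }
  # refined-Euler oracle on a 0.01 s horizon
  y_rk <- advance(step_rk4, 1e-4, 0.01, y0)
  y_eu <- advance(step_euler, 1e-7, 0.01, y0)
  expect_lt(max(abs(y_rk - y_eu) / pmax(abs(y_eu), 1)), 1e-6)
  # observed order on a smooth sub-interval (mid-diastole, no valve
  # switching), with steps well below the PA block's 1000 rad/s resonance
  y_s <- advance(step_rk4, 1e-5, 0.55, y0)
  adv2 <- function(dt) {
    y <- y_s
    t <- 0.55
    while (t < 0.6 - dt / 2) {
      y <- step_rk4(t, y, dt, topo)
      t <- t + dt
    }
    y
  }
  ref <- adv2(6.25e-6)
  e1 <- max(abs(adv2(2e-4) - ref))
  e2 <- max(abs(adv2(1e-4) - ref))
  e3 <- max(abs(adv2(5e-5) - ref))
  order12 <- log2(e1 / e2)
  order23 <- log2(e2 / e3)
  expect_gt(order12, 3.2)
  expect_lt(order12, 4.8)
  expect_gt(order23, 3.0)
})

test_that("euler global error on a short horizon shrinks linearly in dt", {
  # the open circuit (no stiff PA capacitor) is where the explicit Euler
  # stepper is used; constant interface forcings over the horizon
  topo <- circuit_topology("open_setting2", p_ref)
  y0 <- default_initial_state(p_ref, "open_setting2")
  f <- list(P_IN = 15, Q_OUT = 100)
  advance <- function(dt, T_end = 0.1) {
    y <- y0
    t <- 0
    while (t < T_end - dt / 2) {
      y <- step_euler(t, y, dt, topo, f)
      t <- t + dt
    }
    y
  }
  ref <- advance(1.25e-5)
  e1 <- max(abs(advance(2e-4) - ref))
  e2 <- max(abs(advance(1e-4) - ref))
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
})

test_that("non-finite states are reported as instabilities", {
  topo <- circuit_topology("closed", p_ref)
  y <- default_initial_state(p_ref, "closed")
  y[["P_PA"]] <- Inf
  expect_error(assemble_rhs(0, y, topo), "non-finite")
})
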