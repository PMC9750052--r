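p_ref <- circulation_params()
y0_open <- default_initial_state(p_ref, "open_setting2")

test_that("one splitting-explicit step follows the prescribed data flow", {
  dm <- surrogate_matched(p_ref)
  prev <- interface_outputs(0, y0_open, circuit_topology("open_setting2", p_ref),
                            list(P_IN = 0, Q_OUT = 0))
  st0 <- dm$checkpoint()
  res <- se_step(0, y0_open, circuit_topology("open_setting2", p_ref), dm,
                 list(Q_IN = prev$Q_IN, P_OUT = prev$P_OUT), 1e-3)
  # distributed model advanced exactly once with the previous exchange
  manual <- surrogate_advance(0, 1e-3, prev$Q_IN, prev$P_OUT, st0,
                              p_ref$compartments$pa)
  expect_equal(res$exchange$P_IN, manual$P_IN)
  expect_equal(res$exchange$Q_OUT, manual$Q_OUT)
  # then the 0D advanced with those as forcings
  y_manual <- step_rk4(0, y0_open, 1e-3,
                       circuit_topology("open_setting2", p_ref),
                       list(P_IN = manual$P_IN, Q_OUT = manual$Q_OUT))
  expect_equal(res$y, y_manual)
  expect_equal(res$exchange$Q_IN, unname(y_manual[["Q_IN"]]))
})

test_that("splitting-explicit coupling converges linearly to the monolithic loop", {
  errs <- vapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    ref <- monolithic_reference(p_ref, dt = dt, beats = 1)
    run <- run_coupled(surrogate_matched(p_ref), p_ref, setting = 2,
                       algorithm = "se", dt = dt, beats = 1, y0 = y0_open)
    expect_false(run$stability$unstable)
    n <- nrow(run$interface)
    rel_l2(run$interface$P_IN[2:n], ref$P_IN[2:n])
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  # first-order interface splitting: halving dt about halves the discrepancy
  expect_gt(errs[1] / errs[2], 1.4)
  expect_lt(errs[1] / errs[2], 2.9)
})

test_that("splitting-implicit subiterations contract and stop at the tolerance", {
  dm <- surrogate_matched(p_ref)
  guess <- interface_outputs(0, y0_open,
                             circuit_topology("open_setting2", p_ref),
                             list(P_IN = 0, Q_OUT = 0))
  topo <- circuit_topology("open_setting2", p_ref)
  tok <- dm$checkpoint()
  tight <- si_step(0, y0_open, topo, dm, guess, 1e-3, epsilon = 1e-10,
                   k_max = 400)
  # re-seeding from the converged exchange finishes in a single subiteration
  # (the distributed model is rolled back to the step start first)
  dm$restore(tok)
  again <- si_step(0, y0_open, topo, dm,
                   list(Q_IN = tight$exchange$Q_IN, P_OUT = tight$exchange$P_OUT),
                   1e-3, epsilon = 1e-3)
  expect_equal(again$k, 1)
  expect_equal(again$exchange$P_IN, tight$exchange$P_IN, tolerance = 1e-6)
  # k_max exhaustion is an explicit error carrying the residual
  dm$restore(tok)
  expect_error(si_step(0, y0_open, topo, dm, guess, 1e-3, epsilon = 1e-10,
                       k_max = 2), "did not converge")
})

test_that("SE and SI agree at dt = 1e-3 and agree more closely at dt = 5e-4", {
  diffs <- vapply(c(1e-3, 5e-4), function(dt) {
    se <- run_coupled(surrogate_matched(p_ref), p_ref, setting = 2,
                      algorithm = "se", dt = dt, beats = 0.5, y0 = y0_open)
    si <- run_coupled(surrogate_matched(p_ref), p_ref, setting = 2,
                      algorithm = "si", dt = dt, beats = 0.5, y0 = y0_open)
    expect_gt(si$mean_k, 1)
    n <- nrow(se$interface)
    rel_l2(se$interface$P_IN[2:n], si$interface$P_IN[2:n])
  }, numeric(1))
  expect_lt(diffs[1], 0.05)
  expect_lt(diffs[2], diffs[1])
})

test_that("one-way coupling reproduces the closed loop's own PA block", {
  ref <- monolithic_reference(p_ref, dt = 1e-3, beats = 1)
  ow <- one_way_run(ref, surrogate_matched(p_ref), dt = 1e-3, T_end = 0.8)
  expect_false(ow$stability$unstable)
  n <- nrow(ow$interface)
  expect_lt(rel_l2(ow$interface$P_IN[2:n], ref$P_IN[2:n]), 0.02)
  expect_lt(rel_l2(ow$interface$Q_OUT[2:n], ref$Q_OUT[2:n]), 0.02)
  # zero-forcing record drives a resting surrogate nowhere
  zero_rec <- tibble::tibble(t = seq(0, 0.1, by = 1e-3), Q_IN = 0, P_OUT = 0)
  dm0 <- pa_surrogate(p_ref$compartments$pa)
  ow0 <- one_way_run(zero_rec, dm0, dt = 1e-3, T_end = 0.1)
  expect_equal(max(abs(ow0$interface$P_IN[-1])), 0)
  # a record shorter than the horizon is an input error
  expect_error(one_way_run(zero_rec, dm0, dt = 1e-3, T_end = 1), "rows")
})

test_that("instability monitor flags bounded, unbounded and non-finite series", {
  t <- seq(0, 1, by = 1e-2)
  ok <- tibble::tibble(t = t, P_IN = 20 * sin(2 * pi * t), Q_IN = 100 * cos(2 * pi * t))
  expect_false(instability_monitor(ok)$unstable)
  bad <- ok
  bad$P_IN[51] <- NaN
  m <- instability_monitor(bad)
  expect_true(m$unstable)
  expect_equal(m$first_failure_time, t[51])
  big <- ok
  big$Q_IN[11] <- 6000
  expect_equal(instability_monitor(big)$first_failure_time, t[11])
})

test_that("coupled runs report counts, settings and a usable record", {
  run <- run_coupled(surrogate_matched(p_ref), p_ref, setting = 2,
                     algorithm = "se", dt = 1e-3, beats = 3, y0 = y0_open)
  expect_equal(nrow(run$record), 2401)
  expect_equal(run$mean_k, 1)
  expect_true(attr(run$bridging, "pass"))
  m <- cycle_metrics(run, beat = 3)
  expect_gt(m$P_IN_mean, 10)
  g <- glance(run)
  expect_false(g$unstable)
})
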