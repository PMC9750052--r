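test_that("richardson recovers a constructed second-order model exactly", {
  h <- 0.4 * 1.6^(0:2)
  f <- 10 + 3 * h^2
  rs <- richardson(h, f)
  expect_equal(rs$p, 2, tolerance = 1e-10)
  expect_equal(rs$f_ref, 10, tolerance = 1e-10)
  expect_equal(rs$E, abs(f - 10) / 10, tolerance = 1e-9)
  # scale invariance: scaling f scales f_ref, leaves p and E unchanged
  rs2 <- richardson(h, 7 * f)
  expect_equal(rs2$p, rs$p)
  expect_equal(rs2$f_ref, 7 * rs$f_ref)
  expect_equal(rs2$E, rs$E, tolerance = 1e-9)
  expect_named(glance(rs), c("p", "f_ref", "r"))
  expect_equal(nrow(tidy(rs)), 3)
})

test_that("degenerate convergence studies raise explicit errors", {
  h <- 0.4 * 1.6^(0:2)
  expect_error(richardson(h, c(5, 5, 5)), "degenerate")
  expect_error(richardson(h, c(5, 6, 5.5)), "non-positive")
  expect_error(richardson(c(0.4, 0.7, 1.1), c(6.785, 6.774, 6.754)),
               "ratio is not constant")
  expect_error(richardson(c(0.4, 0.3, 1.1), c(1, 2, 3)), "increasing")
  expect_error(richardson(h, c(1, 2)), "three")
})

test_that("richardson on the printed mesh study matches direct formula evaluation", {
  # mesh sizes are quoted rounded; the nominal ratio 1.6 enters the order
  # formula (frozen oracle values computed by independent transcription)
  rs <- richardson(c(0.4, 0.7, 1.1), c(6.785, 6.774, 6.754), r = 1.6)
  expect_equal(rs$p, 1.2719837966, tolerance = 1e-9)
  expect_equal(rs$f_ref, 6.7997405435, tolerance = 1e-9)
  expect_equal(rs$E, c(0.00216781, 0.00378552, 0.00672681), tolerance = 1e-6)
})

test_that("cycle metrics average and bracket synthetic signals correctly", {
  t <- seq(0, 2.4, by = 1e-3)
  const <- tibble::tibble(t = t, P_IN = 15, Q_IN = 100, P_RV = 12, V_RV = 120)
  m <- cycle_metrics(const, beat = 2, T_cycle = 0.8)
  expect_equal(m$P_IN_mean, 15)
  expect_equal(m$Q_IN_mean, 100)
  expect_equal(m$SV, 0)
  sine <- tibble::tibble(t = t, P_IN = 15, Q_IN = 0, P_RV = 12,
                         V_RV = 100 + 40 * sin(2 * pi * t / 0.8))
  m2 <- cycle_metrics(sine, beat = 3, T_cycle = 0.8)
  expect_equal(m2$SV, 80, tolerance = 1e-4)
  expect_equal(m2$EDV, 140, tolerance = 1e-4)
  expect_error(cycle_metrics(const, beat = 9, T_cycle = 0.8), "span")
})

test_that("cycle metrics are invariant to whole-beat shifts on a periodic record", {
  t <- seq(0, 4, by = 1e-3)
  rec <- tibble::tibble(t = t,
                        P_IN = 16 + 3 * sin(2 * pi * t / 0.8),
                        Q_IN = 110 + 80 * sin(2 * pi * t / 0.8 + 1),
                        P_RV = 13 + 10 * pmax(0, sin(2 * pi * t / 0.8)),
                        V_RV = 115 + 40 * cos(2 * pi * t / 0.8))
  m3 <- cycle_metrics(rec, beat = 3, T_cycle = 0.8)
  m4 <- cycle_metrics(rec, beat = 4, T_cycle = 0.8)
  for (col in names(m3)[-1]) {
    expect_equal(m3[[col]], m4[[col]], tolerance = 1e-10, label = col)
  }
})

test_that("pressure-volume loops close and measure stroke work", {
  # degenerate single-point loop
  t <- seq(0, 0.8, by = 1e-2)
  flat <- tibble::tibble(t = t, V_RV = 100, P_RV = 10)
  l0 <- pv_loop(flat, beat = 1, T_cycle = 0.8)
  expect_equal(attr(l0, "area"), 0)
  # synthetic rectangle V in [66, 154], P in [5, 25]: area 88 * 20
  corners <- tibble::tibble(
    t = seq(0, 0.8, length.out = 401),
    V_RV = c(seq(66, 154, length.out = 100), rep(154, 100),
             seq(154, 66, length.out = 100), rep(66, 101)),
    P_RV = c(rep(5, 100), seq(5, 25, length.out = 100),
             rep(25, 100), seq(25, 5, length.out = 101))
  )
  l1 <- pv_loop(corners, beat = 1, T_cycle = 0.8)
  expect_equal(attr(l1, "area"), 88 * 20, tolerance = 0.02)
  expect_s3_class(autoplot(l1), "ggplot")
})

test_that("scenario definitions differ only in the distal resistance", {
  h <- scenario("healthy")
  pah <- scenario("pah")
  expect_equal(h$compartments$micro$R, 2.29e-2)
  expect_equal(pah$compartments$micro$R, 5 * 2.29e-2)
  expect_equal(signif(pah$compartments$micro$R, 3), 0.114)
  pah$compartments$micro$R <- h$compartments$micro$R
  pah$scenario <- h$scenario
  expect_equal(pah, h)
  expect_error(scenario("storm"), "unknown")
})

test_that("raising the distal resistance raises inlet pressure and lowers flow", {
  mH <- cycle_metrics(run_closed0d(scenario("healthy"), beats = 3), beat = 3)
  mP <- cycle_metrics(run_closed0d(scenario("pah"), beats = 3), beat = 3)
  expect_gt(mP$P_IN_mean, mH$P_IN_mean)
  expect_lt(mP$Q_IN_mean, mH$Q_IN_mean)
  # the PAH loop shifts to higher pressures and volumes
  expect_gt(mP$P_RV_max, mH$P_RV_max)
  expect_gt(mP$EDV, mH$EDV)
  expect_lt(mP$SV, mH$SV)
})
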