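chow_maintenance <- function(FM = 4, FFM = 23, lam = 0.22) {
  m <- maintenance_EI(FM, FFM, lam, default_p)
  list(init = body_state(FM, FFM),
       intake = intake_schedule(0, m, diet_chow(), baseline_EI = m),
       activity = activity_schedule(), EI = m)
}

test_that("a maintenance-fed mouse stays at its initial composition", {
  mt <- chow_maintenance()
  tr <- simulate_mouse(mt$init, mt$intake, mt$activity, default_p,
                       horizon = 50)
  expect_lt(max(abs(tr$FM - 4)), 1e-6)
  expect_lt(max(abs(tr$FFM - 23)), 1e-6)
  expect_equal(tr$EE, tr$EI, tolerance = 1e-8)
})

test_that("a small surplus grows fat at the closed-form initial slope", {
  mt <- chow_maintenance()
  p0 <- model_parameters(beta = 1e-12)  # disable DIT for the closed form
  sch <- intake_schedule(0, mt$EI + 1, diet_chow(), baseline_EI = mt$EI + 1)
  tr <- simulate_mouse(mt$init, sch, mt$activity, p0, horizon = 30,
                       dt_out = 0.25)
  expect_true(all(diff(tr$FM) > 0))
  a <- alpha_fm(4, p0)
  slope0 <- 1 / (p0$rho_FM + a * p0$rho_FFM + p0$eta_FM + a * p0$eta_FFM)
  expect_equal(tr$dFM_dt[1], slope0, tolerance = 1e-6)
  # the finite difference over the first quarter-day is slightly below the
  # instantaneous slope as the surplus starts eroding
  expect_equal((tr$FM[2] - tr$FM[1]) / 0.25, slope0, tolerance = 1e-2)
})

test_that("trajectories satisfy the partition coupling pointwise", {
  proto <- study_protocols()$hf7_chow
  act <- activity_schedule(proto$switch_times, proto$switch_to)
  tr <- simulate_mouse(proto$init, proto$intake, act, default_p,
                       horizon = 100, dt_out = 0.1)
  # finite-difference dFFM/dFM against alpha(FM) away from discontinuities
  mid <- which(tr$t > 1 & tr$t < 48)
  fd <- diff(tr$FFM[mid]) / diff(tr$FM[mid])
  expect_equal(fd, alpha_fm(tr$FM[mid[-length(mid)]], default_p),
               tolerance = 1e-2)
  # annotated rates match the coupling exactly
  expect_equal(tr$dFFM_dt, alpha_fm(tr$FM, default_p) * tr$dFM_dt,
               tolerance = 1e-12)
})

test_that("cumulative energy is conserved along a 140 d trajectory", {
  proto <- study_protocols()$hf7_chow
  act <- activity_schedule(proto$switch_times, proto$switch_to)
  tr <- simulate_mouse(proto$init, proto$intake, act, default_p,
                       horizon = 140)
  resid <- default_p$rho_FM * (tr$FM - tr$FM[1]) +
    default_p$rho_FFM * (tr$FFM - tr$FFM[1]) - tr$Ebal
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("adaptive solution agrees with a fine fixed-step Euler oracle", {
  proto <- study_protocols()$hf7_chow
  act <- activity_schedule(proto$switch_times, proto$switch_to)
  tr <- simulate_mouse(proto$init, proto$intake, act, default_p, horizon = 70)
  eu <- euler_simulate(proto$init, proto$intake, act, default_p,
                       horizon = 70, dt = 0.001)
  expect_equal(tail(tr$FM, 1), eu$FM, tolerance = 1e-3)
  expect_equal(tail(tr$FFM, 1), eu$FFM, tolerance = 1e-3)
})

test_that("solution is converged with respect to solver tolerances", {
  proto <- study_protocols()$hf7_chow
  act <- activity_schedule(proto$switch_times, proto$switch_to)
  t1 <- simulate_mouse(proto$init, proto$intake, act, default_p, horizon = 70)
  t2 <- simulate_mouse(proto$init, proto$intake, act, default_p, horizon = 70,
                       rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(tail(t1$FM, 1) - tail(t2$FM, 1)), 1e-4)
})

test_that("uniformly larger intake gives pointwise larger fat mass", {
  sch_lo <- intake_schedule(0, 12, diet_chow())
  sch_hi <- intake_schedule(0, 13, diet_chow())
  lo <- simulate_mouse(body_state(4, 23), sch_lo, activity_schedule(),
                       default_p, horizon = 60)
  hi <- simulate_mouse(body_state(4, 23), sch_hi, activity_schedule(),
                       default_p, horizon = 60)
  expect_true(all(hi$FM >= lo$FM))
})

test_that("the fixed-step compiled path matches the adaptive solver", {
  proto <- study_protocols()$hf_c_hf_c
  act <- activity_schedule(proto$switch_times, proto$switch_to)
  tr <- simulate_mouse(proto$init, proto$intake, act, default_p,
                       horizon = 168)
  fast <- simulate_fast(proto$init, proto$intake, act, default_p,
                        times = tr$t, dt = 0.5)
  expect_lt(max(abs(tr$FM - fast$FM)), 1e-4)
  expect_lt(max(abs(tr$FFM - fast$FFM)), 1e-4)
})

test_that("leaving the partition-function domain fails with the time named", {
  sch <- intake_schedule(0, 0, diet_chow(), baseline_EI = 12)
  expect_error(
    simulate_mouse(body_state(0.5, 23), sch, activity_schedule(),
                   default_p, horizon = 100),
    "t = ")
})

test_that("trajectory CSV export keeps all annotated columns", {
  mt <- chow_maintenance()
  tr <- simulate_mouse(mt$init, mt$intake, mt$activity, default_p,
                       horizon = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_true(all(c("t", "FM", "FFM", "BW", "EE", "lambda", "comp_K",
                    "comp_DIT", "comp_deposition") %in% names(back)))
  expect_equal(back$FM, tr$FM, tolerance = 1e-9)
})
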