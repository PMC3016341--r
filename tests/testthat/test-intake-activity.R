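test_that("intake schedule evaluates piecewise-constant EI and macro splits", {
  sch <- intake_schedule(c(0, 49, 56), c(12, 6, 10),
                         list(diet_chow(), diet_chow(), diet_chow()))
  expect_equal(ei_at(c(0, 48.9, 49, 55, 56, 200), sch),
               c(12, 12, 6, 6, 10, 10))
  # baseline defaults to the mean over the leading chow intervals
  expect_equal(sch$baseline_EI, mean(c(12, 6, 10)))
  expect_equal(delta_ei_at(49, sch), 6 - sch$baseline_EI)
  expect_equal(macro_intake_at(0, sch), c(I_P = 2.88, I_F = 1.44, I_C = 7.68))
  expect_error(intake_schedule(c(0, 10), c(5, -1), diet_chow()), "EI")
  expect_error(intake_schedule(c(0, 10, 10), c(5, 5, 5), diet_chow()),
               "increasing")
})

test_that("schedules starting on a non-chow diet require an explicit baseline", {
  expect_error(intake_schedule(0, 13.5, diet_high_fat()), "baseline_EI")
  sch <- intake_schedule(0, 13.5, diet_high_fat(), baseline_EI = 12)
  expect_equal(delta_ei_at(3, sch), 1.5)
})

test_that("monotone spline interpolation passes through the data", {
  tt <- c(0, 7, 14, 21)
  ei <- c(10, 12, 12.5, 13)
  sch <- intake_schedule(tt, ei, diet_chow(), interp = "spline")
  expect_equal(ei_at(tt, sch), ei, tolerance = 1e-12)
  # monotone data stay monotone between knots
  grid <- ei_at(seq(0, 21, 0.25), sch)
  expect_true(all(diff(grid) >= -1e-12))
  # constant extrapolation beyond the last knot
  expect_equal(ei_at(100, sch), 13)
})

test_that("intake CSV round-trips through read_intake_csv", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_d = c(0, 49), EI_kcal_d = c(12, 13.5),
                       diet_name = c("chow", "high_fat")),
            f, row.names = FALSE)
  sch <- read_intake_csv(f, baseline_EI = 12)
  expect_equal(ei_at(c(10, 60), sch), c(12, 13.5))
  expect_equal(diet_at(60, sch)$name, "high_fat")
  expect_error(read_intake_csv(f, diets = list(chow = diet_chow())),
               "unknown diet")
})

test_that("activity coefficient follows the diet-switch dynamics", {
  act <- activity_schedule(c(49, 98), c("hf", "chow"))
  # baseline, high-fat plateau, and the post-switch exponential relaxation
  expect_equal(lambda_at(10, act), 0.22)
  expect_equal(lambda_at(c(49, 97.9), act), c(0.13, 0.13))
  expect_equal(lambda_at(98, act), 0.27)           # right-continuous jump
  expect_equal(lambda_at(98 + 14, act), 0.19 + 0.08 * exp(-1),
               tolerance = 1e-9)
  expect_equal(lambda_at(98 + 1000, act), 0.19, tolerance = 1e-9)
  expect_error(activity_schedule(c(98, 49), c("hf", "chow")), "increasing")
  expect_error(activity_schedule(10, "snack"), "hf")
})

test_that("multi-switch schedules alternate plateau and relaxation segments", {
  act <- activity_schedule(c(0, 49, 70, 140), c("hf", "chow", "hf", "chow"))
  expect_equal(lambda_at(10, act), 0.13)
  expect_equal(lambda_at(49, act), 0.27)
  expect_equal(lambda_at(69.9, act), 0.19 + 0.08 * exp(-20.9 / 14),
               tolerance = 1e-9)
  expect_equal(lambda_at(100, act), 0.13)
  expect_equal(lambda_at(154, act), 0.19 + 0.08 * exp(-1), tolerance = 1e-9)
})
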