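test_that("right atrial pressure lookup covers the three regimes and is total", {
  expect_equal(right_atrial_pressure(1.8, 0.60)$rap, 3)
  expect_equal(right_atrial_pressure(2.5, 0.30)$rap, 15)
  expect_equal(right_atrial_pressure(2.5, 0.60)$rap, 8)
  expect_equal(right_atrial_pressure(1.8, 0.30)$rap, 8)
  # boundary assignment: 2.1 cm with the small branch, 50% with collapsing
  expect_equal(right_atrial_pressure(2.1, 0.5)$rap, 3)
  expect_equal(right_atrial_pressure(2.1, 0.49)$rap, 8)
  expect_equal(right_atrial_pressure(2.11, 0.5)$rap, 8)

  grid <- expand.grid(d = seq(0.5, 4, by = 0.1), c = seq(0, 1, by = 0.05))
  rap <- right_atrial_pressure(grid$d, grid$c)$rap
  expect_true(all(rap %in% c(3, 8, 15)))
  expect_equal(length(rap), nrow(grid))
})

test_that("Bernoulli gradient and the pressure estimates built on it", {
  expect_equal(bernoulli_gradient(0), 0)
  expect_equal(bernoulli_gradient(1), 4)
  expect_equal(bernoulli_gradient(2.8), 31.36)
  v <- seq(0, 6, by = 0.25)
  expect_true(all(diff(bernoulli_gradient(v)) > 0))

  expect_equal(rv_systolic_pressure(0, 3), 3)
  expect_equal(rv_systolic_pressure(3.0, 3), 39)
  expect_equal(rv_systolic_pressure(2.5, 8), 33)

  expect_equal(pa_diastolic_pressure(0, 8), 8)
  expect_equal(pa_diastolic_pressure(1.0, 3), 7)
  expect_equal(pa_diastolic_pressure(1.5, 8), 17)
})

test_that("mean pulmonary pressure estimators agree with hand arithmetic", {
  expect_equal(mean_pa_pressure(25, 10), 15)
  expect_equal(mean_pa_pressure(18, 18), 18) # degenerate equality
  expect_error(mean_pa_pressure(10, 25), ">=")
  expect_equal(mean_pa_pressure_doppler(1.8, 3), 15.96)
  expect_equal(mean_pa_pressure_doppler(1.8, 3, add_rap = FALSE), 12.96)
})

test_that("pulmonary pulse pressure equals SPAP - PADP for any common RAP", {
  expect_equal(pa_pulse_pressure(2, 2), 0)
  expect_equal(pa_pulse_pressure(3.0, 1.0), 32)
  expect_error(pa_pulse_pressure(1.0, 3.0), "inconsistent")

  set.seed(41)
  trv <- runif(500, 1, 5)
  predv <- trv * runif(500, 0, 1)
  rap <- sample(c(3, 8, 15), 500, replace = TRUE)
  expect_equal(
    pa_pulse_pressure(trv, predv),
    rv_systolic_pressure(trv, rap) - pa_diastolic_pressure(predv, rap),
    tolerance = 1e-12
  )
})

test_that("the two pulmonary resistance estimators and capacitance", {
  expect_equal(pvr_invasive(15, 15, 5), 0)
  expect_equal(pvr_invasive(15, 5, 5.0), 160)
  expect_equal(pvr_invasive(40, 12, 4.0), 560)
  expect_error(pvr_invasive(10, 15, 5), ">=")

  d <- pvr_doppler(2.0, 20)
  expect_equal(d$pvr_wood, 1.0)
  expect_identical(d$severity, "normal")
  expect_true(d$reliable)
  expect_equal(pvr_doppler(3.0, 10)$pvr_wood, 3.0)
  d9 <- pvr_doppler(4.5, 5)
  expect_equal(d9$pvr_wood, 9.0)
  expect_false(d9$reliable)
  expect_identical(pvr_doppler(4.0, 10)$severity, "significant_ph")

  expect_equal(pulmonary_vascular_capacitance(32, 32), 1.0)
  expect_equal(pulmonary_vascular_capacitance(70, 20), 3.5)
  expect_equal(pulmonary_vascular_capacitance(45, 30), 1.5)
})

test_that("resistance unit conversions are exact with exact round trips", {
  expect_equal(convert_resistance(3, "wood", "dyn"), 240)
  expect_equal(convert_resistance(80, "dyn", "wood"), 1.0)
  expect_equal(convert_resistance(100, "dyn", "wood"), 1.25)
  expect_equal(convert_resistance(3, "wood", "mpa"), 24)
  # dyn <-> MPa.s/m^3 via Wood units: factor 10
  expect_equal(convert_resistance(900, "dyn", "mpa"), 90)
  expect_equal(convert_resistance(100, "dyn", "mpa"), 10)

  x <- c(0, 1, 3.7, 120, 1261.9)
  expect_identical(
    convert_resistance(convert_resistance(x, "wood", "dyn"), "dyn", "wood"), x
  )
  expect_identical(
    convert_resistance(convert_resistance(x, "mpa", "wood"), "wood", "mpa"), x
  )
})
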