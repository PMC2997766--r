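test_that("cycle length reproduces the printed heart-rate table", {
  expect_equal(cycle_length(75), 800)
  # printed values at standard heart rates
  hrs <- c(50, 60, 70, 80, 100, 110, 120, 140, 150, 160, 170, 180)
  printed <- c(1200, 1000, 857, 750, 600, 545, 500, 429, 400, 375, 353, 333)
  expect_equal(cycle_length(hrs), printed)
  # half-away-from-zero rounding at the two anomalous entries
  expect_equal(cycle_length(90), 667)
  expect_equal(cycle_length(130), 462)
  expect_error(cycle_length(0), "> 0")
})

test_that("percent change", {
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(50, 100), 100)
  expect_equal(percent_change(80, 60), -25)
  expect_true(is.na(percent_change(0, 10))) # marker, not an exception
})

test_that("force-frequency classification and critical heart rate", {
  up <- force_frequency(data.frame(hr = c(60, 100, 140), sp_esvi = c(5, 7, 9)))
  expect_identical(up$shape, "up_sloping")
  expect_equal(up$critical_heart_rate, 140)

  flat <- force_frequency(data.frame(hr = c(60, 100, 140), sp_esvi = c(5, 7, 5)))
  expect_identical(flat$shape, "flat_or_negative")
  expect_equal(flat$critical_heart_rate, 100)

  bi <- force_frequency(data.frame(hr = c(60, 100, 140), sp_esvi = c(5, 9, 7)))
  expect_identical(bi$shape, "biphasic")
  expect_equal(bi$critical_heart_rate, 100)

  # exhaustive three-way rule on all orderings of three distinct values
  vals <- c(3, 6, 9)
  for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    v <- vals[p]
    r <- force_frequency(data.frame(hr = c(60, 100, 140), sp_esvi = v))
    expected <- if (v[3] > max(v[1:2])) "up_sloping"
                else if (v[3] <= v[1]) "flat_or_negative" else "biphasic"
    expect_identical(r$shape, expected)
    expect_equal(r$critical_heart_rate, c(60, 100, 140)[which.max(v)])
  }

  # invariance under uniform scaling; earliest stage wins ties
  set.seed(51)
  for (i in 1:20) {
    v <- runif(4, 1, 20)
    a <- force_frequency(data.frame(hr = c(60, 90, 120, 150), sp_esvi = v))
    b <- force_frequency(data.frame(hr = c(60, 90, 120, 150), sp_esvi = 3.7 * v))
    expect_identical(a$shape, b$shape)
    expect_equal(a$critical_heart_rate, b$critical_heart_rate)
  }
  tie <- force_frequency(data.frame(hr = c(60, 100, 140), sp_esvi = c(5, 9, 9)))
  expect_equal(tie$critical_heart_rate, 100)
  expect_error(force_frequency(data.frame(hr = 60, sp_esvi = 5)), "2 stages")
})

test_that("stroke-volume decomposition sums to 100% and matches worked cases", {
  expect_equal(sv_decomposition(120, 50, 130, 40),
               tibble::tibble(edv_contribution = 50, esv_contribution = 50))
  expect_equal(sv_decomposition(120, 50, 120, 30)$esv_contribution, 100)
  expect_equal(sv_decomposition(120, 50, 135, 45)$edv_contribution, 75)
  expect_true(all(is.na(sv_decomposition(120, 50, 130, 60)))) # dSV = 0

  set.seed(61)
  for (i in 1:200) {
    er <- runif(1, 80, 200); sr <- runif(1, 20, er - 10)
    ep <- runif(1, 80, 220); sp <- runif(1, 10, ep - 10)
    d <- sv_decomposition(er, sr, ep, sp)
    if (!is.na(d$edv_contribution)) {
      expect_equal(d$edv_contribution + d$esv_contribution, 100, tolerance = 1e-9)
    }
  }
})

test_that("exercise pulmonary pressure flag and mPAP consistency note", {
  expect_identical(exercise_spap_flag(40, FALSE), "normal")
  expect_identical(exercise_spap_flag(50, FALSE), "abnormal")
  expect_identical(exercise_spap_flag(55, TRUE), "may_be_physiologic")
  expect_identical(exercise_spap_flag(61, TRUE), "abnormal")

  expect_true(mpap_consistency(15, 15)$consistent)
  c7 <- mpap_consistency(15, 22)
  expect_false(c7$consistent)
  expect_equal(c7$delta, 7)
  expect_true(mpap_consistency(20, 17)$consistent)
})

test_that("derive_panel populates every sheet row with a value or a reason", {
  case <- manual_case()
  panel <- derive_panel(case$stages[1, ], case$subject)
  expect_true(all(!is.na(panel$value) | !is.na(panel$not_computable)))
  expect_true(all(!is.na(panel$value))) # fully-specified record: all computed

  # frozen hand-computed rest values
  expect_equal(panel_value(panel, "bsa"), sqrt(3.6), tolerance = 1e-12)
  expect_equal(panel_value(panel, "sv"), 80)
  expect_equal(panel_value(panel, "co"), 4.8)
  expect_equal(panel_value(panel, "map"), 280 / 3, tolerance = 1e-12)
  expect_equal(panel_value(panel, "esp"), 108)
  expect_equal(panel_value(panel, "ees_index"), 108 * sqrt(3.6) / 60, tolerance = 1e-12)
  expect_equal(panel_value(panel, "ea_index"), 108 * sqrt(3.6) / 80, tolerance = 1e-12)
  expect_equal(panel_value(panel, "vac"), 80 / 60, tolerance = 1e-12)
  expect_equal(panel_value(panel, "svr"), 80 * (280 / 3 - 5) / 4.8, tolerance = 1e-12)
  expect_equal(panel_value(panel, "compliance"), 2.0)
  expect_equal(panel_value(panel, "e_eprime_septal"), 8.0)
  expect_equal(panel_value(panel, "pcwp_est"), 11.82)
  expect_equal(panel_value(panel, "filling_rate"), 80 / sqrt(3.6) / 500 * 1000,
               tolerance = 1e-12)
  expect_equal(panel_value(panel, "cycle_length"), 1000)
  expect_equal(panel_value(panel, "rap"), 3)
  expect_equal(panel_value(panel, "tr_gradient"), 25)
  expect_equal(panel_value(panel, "spap"), 28)
  expect_equal(panel_value(panel, "padp"), 7)
  expect_equal(panel_value(panel, "mpap_standard"), 14)
  expect_equal(panel_value(panel, "mpap_doppler"), 4 * 1.7^2 + 3)
  expect_equal(panel_value(panel, "papp"), 21)
  expect_equal(panel_value(panel, "pvr_invasive"), 80 * (14 - 11.82) / 4.8,
               tolerance = 1e-12)
  expect_equal(panel_value(panel, "pvr_doppler"), 1.25)
  expect_equal(panel_value(panel, "pvc"), 80 / 21, tolerance = 1e-12)
})

test_that("missing optional inputs disable only the dependent parameters", {
  case <- manual_case()
  stage <- case$stages[1, ]
  stage$tr_velocity <- NA_real_
  panel <- derive_panel(stage, case$subject)
  for (p in c("tr_gradient", "spap", "mpap_standard", "papp", "pvc", "pvr_doppler")) {
    expect_true(!is.na(panel_nc(panel, p)), info = p)
  }
  expect_match(panel_nc(panel, "pvr_doppler"), "tr_velocity")
  # systemic block untouched
  for (p in c("sv", "co", "map", "ees_index", "vac", "svr")) {
    expect_false(is.na(panel_value(panel, p)), info = p)
  }

  stage2 <- case$stages[1, ]
  stage2$heart_rate <- NA_real_
  expect_error(derive_panel(stage2, case$subject), "mandatory")
})

test_that("resting reference bands flag rest values but not stress physiology", {
  comp <- stress_comparison(manual_case())
  cmp <- tidy(comp)
  svr_row <- cmp[cmp$parameter == "svr", ]
  expect_match(svr_row$flag_rest, "above normal") # rest SVR 1472 > 1300
  expect_true(is.na(svr_row$flag_peak)) # exercise vasodilation not flagged
  co_row <- cmp[cmp$parameter == "co", ]
  expect_true(is.na(co_row$flag_rest)) # rest CO 4.8 within 4-6
  expect_true(is.na(co_row$flag_peak)) # peak CO 13.2 is exercise physiology
})
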