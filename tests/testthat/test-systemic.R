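test_that("body surface area matches hand-computed values and is monotone", {
  expect_equal(body_surface_area(36, 100), 1)
  expect_equal(body_surface_area(70, 180), sqrt(3.5), tolerance = 1e-12)
  expect_equal(body_surface_area(70, 180), 1.8708, tolerance = 1e-4)
  expect_equal(body_surface_area(81, 160), 1.8974, tolerance = 1e-4)
  # the two formulas agree to a few percent over the adult range
  expect_equal(body_surface_area(70, 180, "power"),
               body_surface_area(70, 180, "mosteller"), tolerance = 0.03)
  expect_error(body_surface_area(-1, 170), "> 0")

  set.seed(11)
  w <- runif(50, 40, 120)
  h <- runif(50, 140, 200)
  for (m in c("mosteller", "power")) {
    expect_true(all(body_surface_area(w + 1, h, m) > body_surface_area(w, h, m)))
    expect_true(all(body_surface_area(w, h + 1, m) > body_surface_area(w, h, m)))
  }
})

test_that("stroke volume, cardiac output and their indices", {
  expect_equal(stroke_volume(120, 50, 1.75), tibble::tibble(sv = 70, svi = 40))
  expect_equal(stroke_volume(110, 40, 2.0)$svi, 35)
  expect_error(stroke_volume(100, 100, 1.8), "exceed")
  expect_error(stroke_volume(100, 110, 1.8), "exceed")

  expect_equal(cardiac_output(60, 1000, 2.0)$co, 60) # unit scaling: mL -> L
  co <- cardiac_output(70, 80, 1.9)
  expect_equal(co$co, 5.6)
  expect_equal(co$ci, 2.947, tolerance = 1e-3)
  expect_equal(cardiac_output(120, 50, 1.9)$co, 6.0)
})

test_that("arterial pressures: MAP is a convex combination, ESP is 0.9 SBP", {
  expect_equal(mean_arterial_pressure(120, 80), 93 + 1 / 3)
  expect_equal(mean_arterial_pressure(130, 70), 90)
  expect_error(mean_arterial_pressure(80, 80), "exceed")

  expect_equal(end_systolic_pressure(100), 90)
  expect_equal(end_systolic_pressure(120), 108)
  expect_equal(end_systolic_pressure(180), 162)

  set.seed(21)
  sbp <- runif(1000, 90, 220)
  dbp <- sbp - runif(1000, 1, 80)
  map <- mean_arterial_pressure(sbp, dbp)
  expect_true(all(map > dbp & map < sbp))
  expect_equal(end_systolic_pressure(sbp) / sbp, rep(0.9, 1000))
})

test_that("elastance indices reproduce worked values under both conventions", {
  expect_equal(lv_elastance_index(108, 54, 1.0), 2.0)
  expect_equal(lv_elastance_index(162, 20, 1.8), 14.58)
  expect_equal(arterial_elastance_index(100, 100, 1.0), 1.0)
  expect_equal(arterial_elastance_index(108, 80, 1.8), 2.43)
  # divide-by-BSA convention divides the raw ratio instead
  expect_equal(lv_elastance_index(162, 20, 1.8, "divide_bsa"), 162 / 20 / 1.8)
})

test_that("coupling equals SV/ESV and the elastance-ratio identity holds", {
  expect_equal(ventricular_arterial_coupling(70, 35), 2.0)
  expect_equal(ventricular_arterial_coupling(45, 90), 0.5)

  set.seed(31)
  n <- 1e4
  esp <- runif(n, 50, 250)
  esv <- runif(n, 10, 200)
  sv <- runif(n, 10, 150)
  bsa <- runif(n, 1.2, 2.5)
  vac <- ventricular_arterial_coupling(sv, esv)
  ratio <- lv_elastance_index(esp, esv, bsa) / arterial_elastance_index(esp, sv, bsa)
  expect_equal(vac, ratio, tolerance = 1e-12)
  expect_equal(vac, sv / esv, tolerance = 1e-12)
})

test_that("vascular resistance and compliance match hand arithmetic and scale", {
  expect_equal(systemic_vascular_resistance(5, 4.2), 0)
  expect_equal(systemic_vascular_resistance(93.33, 5.6), 1261.9, tolerance = 1e-3)
  expect_equal(systemic_vascular_resistance(90, 8.0), 850)
  expect_error(systemic_vascular_resistance(90, 0), "> 0")

  expect_equal(systemic_arterial_compliance(40, 40), 1.0)
  expect_equal(systemic_arterial_compliance(70, 40), 1.75)
  expect_equal(systemic_arterial_compliance(90, 75), 1.2)
  expect_error(systemic_arterial_compliance(70, 0), "> 0")

  # doubling SV doubles CO and compliance, halves the arterial elastance index
  sv <- 80; hr <- 70; bsa <- 1.9; pp <- 40; esp <- 110
  expect_equal(cardiac_output(hr, 2 * sv, bsa)$co, 2 * cardiac_output(hr, sv, bsa)$co)
  expect_equal(systemic_arterial_compliance(2 * sv, pp),
               2 * systemic_arterial_compliance(sv, pp))
  expect_equal(arterial_elastance_index(esp, 2 * sv, bsa),
               arterial_elastance_index(esp, sv, bsa) / 2)
})
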