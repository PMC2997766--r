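check_positive <- function(x, name) {
  if (any(!is.na(x) & x <= 0)) abort(paste0(name, " must be > 0"))
  invisible(x)
}

#' Body surface area
#'
#' Two common anthropometric formulas. `mosteller` is
#' `sqrt(weight * height / 3600)`; `power` is the Haycock exponent form
#' `0.024265 * weight^0.5378 * height^0.3964` (weight kg, height cm).
#' Mosteller is the default used throughout the panel; the two agree to a few
#' percent over the adult range.
#'
#' @param weight Body weight, kg.
#' @param height Body height, cm.
#' @param method `"mosteller"` (default) or `"power"`.
#' @return BSA in m^2.
#' @examples
#' body_surface_area(70, 180) # sqrt(3.5) = 1.8708
#' @export
body_surface_area <- function(weight, height, method = c("mosteller", "power")) {
  method <- match.arg(method)
  check_positive(weight, "weight")
  check_positive(height, "height")
  switch(method,
    mosteller = sqrt(weight * height / 3600),
    power = 0.024265 * weight^0.5378 * height^0.3964
  )
}

#' Stroke volume and stroke volume index
#'
#' `sv = edv - esv` (mL); `svi = sv / bsa` (mL/m^2). Normal stroke volume is
#' 60-100 mL/beat.
#'
#' @param edv,esv End-diastolic and end-systolic LV volume, mL; must satisfy
#'   `edv > esv > 0`.
#' @param bsa Body surface area, m^2.
#' @return A tibble with columns `sv` and `svi`.
#' @export
stroke_volume <- function(edv, esv, bsa) {
  check_positive(esv, "esv")
  check_positive(bsa, "bsa")
  if (any(!is.na(edv) & !is.na(esv) & edv <= esv)) {
    abort("edv must exceed esv")
  }
  sv <- edv - esv
  tibble(sv = sv, svi = sv / bsa)
}

#' Cardiac output and cardiac index
#'
#' `co = heart_rate * sv / 1000` (L/min); `ci = co / bsa` (L/min/m^2).
#' Normal ranges: CO approx. 4-6 L/min, CI approx. 2.5-3.6 L/min/m^2.
#'
#' @param heart_rate Heart rate, bpm.
#' @param sv Stroke volume, mL.
#' @param bsa Body surface area, m^2.
#' @return A tibble with columns `co` and `ci`.
#' @export
cardiac_output <- function(heart_rate, sv, bsa) {
  check_positive(heart_rate, "heart_rate")
  check_positive(sv, "sv")
  check_positive(bsa, "bsa")
  co <- heart_rate * sv / 1000
  tibble(co = co, ci = co / bsa)
}

#' Mean arterial pressure
#'
#' `(sbp - dbp) / 3 + dbp`, mmHg; a convex combination of the two cuff
#' pressures, so always strictly between DBP and SBP. Normal 70-100 mmHg.
#'
#' @param sbp,dbp Systolic and diastolic cuff pressure, mmHg; `sbp > dbp`.
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(!is.na(sbp) & !is.na(dbp) & sbp <= dbp)) abort("sbp must exceed dbp")
  (sbp - dbp) / 3 + dbp
}

#' End-systolic pressure surrogate
#'
#' `0.9 * sbp`: the cuff-based estimate of LV end-systolic pressure used in
#' the elastance calculations.
#'
#' @param sbp Systolic cuff pressure, mmHg.
#' @return ESP in mmHg.
#' @export
end_systolic_pressure <- function(sbp) {
  check_positive(sbp, "sbp")
  0.9 * sbp
}

#' LV end-systolic elastance index
#'
#' Contractility surrogate: pressure over end-systolic volume, indexed to body
#' size. The default (`indexing = "volume_index"`) divides pressure by the
#' end-systolic volume *index* (`esv / bsa`), i.e. `pressure * bsa / esv`,
#' which reproduces the published normal rest/peak averages (about 4.5 rising
#' to 14.5 mmHg/mL/m^2 with exercise). `indexing = "divide_bsa"` instead
#' divides the raw pressure/volume ratio by BSA. The pressure is normally the
#' end-systolic surrogate `0.9 * SBP` ([end_systolic_pressure()]); raw SBP can
#' be passed for the cuff-pressure convention.
#'
#' @param pressure Systolic or end-systolic pressure, mmHg.
#' @param esv End-systolic volume, mL.
#' @param bsa Body surface area, m^2.
#' @param indexing `"volume_index"` (default) or `"divide_bsa"`.
#' @return Elastance index, mmHg/mL/m^2.
#' @examples
#' lv_elastance_index(162, 20, 1.8) # 14.58
#' @export
lv_elastance_index <- function(pressure, esv, bsa,
                               indexing = c("volume_index", "divide_bsa")) {
  indexing <- match.arg(indexing)
  check_positive(esv, "esv")
  check_positive(bsa, "bsa")
  switch(indexing,
    volume_index = pressure / (esv / bsa),
    divide_bsa = (pressure / esv) / bsa
  )
}

#' Effective arterial elastance index
#'
#' Lumped arterial load: end-systolic pressure over stroke volume, indexed to
#' body size with the same convention as [lv_elastance_index()]. Published
#' normal averages rise from about 2.3 at rest to 3.2 mmHg/mL/m^2 at peak
#' exercise.
#'
#' @param esp End-systolic pressure (0.9 * SBP), mmHg.
#' @param sv Stroke volume, mL.
#' @param bsa Body surface area, m^2.
#' @param indexing `"volume_index"` (default) or `"divide_bsa"`.
#' @return Elastance index, mmHg/mL/m^2.
#' @export
arterial_elastance_index <- function(esp, sv, bsa,
                                     indexing = c("volume_index", "divide_bsa")) {
  indexing <- match.arg(indexing)
  check_positive(sv, "sv")
  check_positive(bsa, "bsa")
  switch(indexing,
    volume_index = esp / (sv / bsa),
    divide_bsa = (esp / sv) / bsa
  )
}

#' Ventricular-arterial coupling
#'
#' The elastance ratio Ees/Ea; the pressure terms cancel, so coupling equals
#' `sv / esv` exactly and is independent of the blood-pressure measurement.
#' Normal averages: about 1.9 at rest rising to 4.5 at peak exercise; in
#' dilated cardiomyopathy the ratio stays blunted around 0.4-0.5.
#'
#' @param sv Stroke volume, mL.
#' @param esv End-systolic volume, mL.
#' @return Dimensionless coupling ratio.
#' @export
ventricular_arterial_coupling <- function(sv, esv) {
  check_positive(esv, "esv")
  sv / esv
}

#' Systemic vascular resistance
#'
#' `80 * (map - 5) / co`, where 5 mmHg approximates right atrial pressure.
#' Normal 900-1300 dyne.s.cm^-5.
#'
#' @param map Mean arterial pressure, mmHg.
#' @param co Cardiac output, L/min.
#' @return SVR in dyne.s.cm^-5.
#' @export
systemic_vascular_resistance <- function(map, co) {
  check_positive(co, "co")
  80 * (map - 5) / co
}

#' Systemic arterial compliance
#'
#' Stroke volume over systemic pulse pressure (`sbp - dbp`), mL/mmHg; the
#' pulsatile component of the arterial load.
#'
#' @param sv Stroke volume, mL.
#' @param pp Pulse pressure, mmHg; must be > 0.
#' @return Compliance in mL/mmHg.
#' @export
systemic_arterial_compliance <- function(sv, pp) {
  check_positive(pp, "pp")
  sv / pp
}
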