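#' Right atrial pressure from inferior vena cava imaging
#'
#' Categorical estimate from IVC diameter and respiratory (sniff) collapse:
#' a small IVC (<= 2.1 cm) that collapses (>= 50%) maps to 3 mmHg
#' (range 0-5); a dilated IVC (> 2.1 cm) with poor collapse (< 50%) maps to
#' 15 mmHg (range 10-20); every other combination is indeterminate and maps
#' to the intermediate 8 mmHg (range 5-10). The 2.1 cm and 50% boundaries
#' are assigned to the small-diameter and collapsing branches respectively,
#' so the lookup is total: every pair yields exactly one of {3, 8, 15}.
#'
#' @param ivc_diameter IVC diameter, cm (> 0).
#' @param ivc_collapse Respiratory collapse as a fraction in \[0, 1\].
#' @return A tibble with columns `rap` (mmHg), `rap_low`, `rap_high` (the
#'   associated range) and `regime` (`"normal"`, `"intermediate"`, `"high"`).
#' @examples
#' right_atrial_pressure(1.8, 0.60) # 3 mmHg
#' right_atrial_pressure(2.5, 0.30) # 15 mmHg
#' right_atrial_pressure(2.5, 0.60) # 8 mmHg
#' @export
right_atrial_pressure <- function(ivc_diameter, ivc_collapse) {
  check_positive(ivc_diameter, "ivc_diameter")
  if (any(!is.na(ivc_collapse) & (ivc_collapse < 0 | ivc_collapse > 1))) {
    abort("ivc_collapse must be a fraction in [0, 1]")
  }
  small <- ivc_diameter <= 2.1
  collapsing <- ivc_collapse >= 0.5
  regime <- dplyr::case_when(
    small & collapsing ~ "normal",
    !small & !collapsing ~ "high",
    TRUE ~ "intermediate"
  )
  tibble(
    rap = unname(c(normal = 3, intermediate = 8, high = 15)[regime]),
    rap_low = unname(c(normal = 0, intermediate = 5, high = 10)[regime]),
    rap_high = unname(c(normal = 5, intermediate = 10, high = 20)[regime]),
    regime = regime
  )
}

#' Simplified Bernoulli pressure gradient
#'
#' `4 * velocity^2`: the pressure drop (mmHg) across a regurgitant jet of
#' peak velocity `velocity` (m/s).
#'
#' @param velocity Jet velocity, m/s (>= 0).
#' @return Gradient in mmHg.
#' @export
bernoulli_gradient <- function(velocity) {
  if (any(!is.na(velocity) & velocity < 0)) abort("velocity must be >= 0")
  4 * velocity^2
}

#' Right ventricular systolic pressure / systolic pulmonary artery pressure
#'
#' `4 * tr_velocity^2 + rap`. In the absence of a gradient across the
#' pulmonary valve this equals systolic pulmonary artery pressure. Values
#' above 40 mmHg warrant further evaluation.
#'
#' @param tr_velocity Peak tricuspid regurgitant jet velocity, m/s.
#' @param rap Right atrial pressure, mmHg.
#' @return RVSP (= SPAP) in mmHg.
#' @export
rv_systolic_pressure <- function(tr_velocity, rap) {
  bernoulli_gradient(tr_velocity) + rap
}

#' Pulmonary artery diastolic pressure
#'
#' `4 * pr_end_diastolic_velocity^2 + rap` from the end-diastolic pulmonary
#' regurgitant jet. A regurgitant end-diastolic gradient above 5 mmHg is
#' itself abnormal.
#'
#' @param pr_edv End-diastolic pulmonary regurgitant velocity, m/s.
#' @param rap Right atrial pressure, mmHg.
#' @return PADP in mmHg.
#' @export
pa_diastolic_pressure <- function(pr_edv, rap) {
  bernoulli_gradient(pr_edv) + rap
}

#' Mean pulmonary artery pressure (standard formula)
#'
#' `spap / 3 + 2 * padp / 3`.
#'
#' @param spap Systolic pulmonary artery pressure, mmHg; `spap >= padp`.
#' @param padp Diastolic pulmonary artery pressure, mmHg.
#' @return mPAP in mmHg.
#' @export
mean_pa_pressure <- function(spap, padp) {
  if (any(!is.na(spap) & !is.na(padp) & spap < padp)) {
    abort("spap must be >= padp")
  }
  spap / 3 + 2 * padp / 3
}

#' Mean pulmonary artery pressure (Doppler estimate)
#'
#' `4 * pr_peak^2 (+ rap)` from the peak early-diastolic pulmonary
#' regurgitant velocity. Reporting both this and the standard estimate lets
#' the internal consistency of the data be challenged (see
#' [mpap_consistency()]). Whether the right atrial pressure term is added is
#' configurable (`add_rap`, default `TRUE`, the more explicit of the two
#' printed conventions).
#'
#' @param pr_peak Peak early pulmonary regurgitant velocity, m/s.
#' @param rap Right atrial pressure, mmHg.
#' @param add_rap Add `rap` to the Bernoulli gradient? Default `TRUE`.
#' @return Doppler mPAP in mmHg.
#' @export
mean_pa_pressure_doppler <- function(pr_peak, rap, add_rap = TRUE) {
  bernoulli_gradient(pr_peak) + if (isTRUE(add_rap)) rap else 0
}

#' Pulmonary artery pulse pressure
#'
#' `4 * tr_velocity^2 - 4 * pr_edv^2`; algebraically identical to
#' SPAP - PADP for any common right atrial pressure (the RAP terms cancel).
#' A negative result means the two jets are mutually inconsistent and is an
#' error.
#'
#' @param tr_velocity Peak tricuspid regurgitant velocity, m/s.
#' @param pr_edv End-diastolic pulmonary regurgitant velocity, m/s.
#' @return PAPP in mmHg.
#' @export
pa_pulse_pressure <- function(tr_velocity, pr_edv) {
  out <- bernoulli_gradient(tr_velocity) - bernoulli_gradient(pr_edv)
  if (any(!is.na(out) & out < 0)) {
    abort("inconsistent velocities: TR gradient below PR end-diastolic gradient")
  }
  out
}

#' Pulmonary vascular resistance (catheterization formula)
#'
#' `80 * (mpap - pcwp) / co`, dyne.s.cm^-5. Normal 100-200 dyne.s.cm^-5.
#' When no measured wedge pressure is available the panel substitutes the
#' E/e'-based estimate from [estimate_pcwp()] and marks it as estimated.
#'
#' @param mpap Mean pulmonary artery pressure, mmHg; `mpap >= pcwp`.
#' @param pcwp Pulmonary capillary wedge pressure, mmHg.
#' @param co Cardiac output, L/min.
#' @return PVR in dyne.s.cm^-5.
#' @export
pvr_invasive <- function(mpap, pcwp, co) {
  check_positive(co, "co")
  if (any(!is.na(mpap) & !is.na(pcwp) & mpap < pcwp)) {
    abort("mpap must be >= pcwp")
  }
  80 * (mpap - pcwp) / co
}

#' Pulmonary vascular resistance (Doppler estimate, Wood units)
#'
#' `10 * tr_velocity / rvot_tvi`. Severity labels: `"normal"` below 1.5 Wood
#' units, `"significant_ph"` above 3 (i.e. > 240 dyne.s.cm^-5),
#' `"borderline"` in between. The relationship is not reliable at very high
#' resistance: `reliable` is `FALSE` when the estimate exceeds 8 Wood units.
#'
#' @param tr_velocity Peak tricuspid regurgitant velocity, m/s.
#' @param rvot_tvi Right ventricular outflow tract time-velocity integral, cm.
#' @return A tibble with columns `pvr_wood`, `reliable`, `severity`.
#' @export
pvr_doppler <- function(tr_velocity, rvot_tvi) {
  check_positive(rvot_tvi, "rvot_tvi")
  wood <- 10 * tr_velocity / rvot_tvi
  tibble(
    pvr_wood = wood,
    reliable = !(wood > 8),
    severity = dplyr::case_when(
      wood < 1.5 ~ "normal",
      wood > 3 ~ "significant_ph",
      TRUE ~ "borderline"
    )
  )
}

#' Pulmonary vascular capacitance
#'
#' Stroke volume over pulmonary artery pulse pressure, mL/mmHg; a workload
#' measure on the right ventricle and a strong prognostic marker in
#' pulmonary hypertension.
#'
#' @param sv Stroke volume, mL.
#' @param papp Pulmonary artery pulse pressure, mmHg (> 0).
#' @return PVC in mL/mmHg.
#' @export
pulmonary_vascular_capacitance <- function(sv, papp) {
  check_positive(papp, "papp")
  sv / papp
}

#' Convert vascular resistance units
#'
#' Wood units (mmHg.min/L), dyne.s.cm^-5 (`1 Wood = 80 dyn`) and MPa.s/m^3
#' (`1 Wood = 8 MPa.s/m^3`, hence `dyn/10`; the dimensionally consistent
#' factor, which also matches the usual printed normal ranges, e.g.
#' 900-1300 dyn = 90-130 MPa.s/m^3). Conversions route through Wood units
#' with exact rational factors, so round trips are exact.
#'
#' @param value Resistance value(s), >= 0.
#' @param from,to One of `"wood"`, `"dyn"`, `"mpa"`.
#' @return Converted value(s).
#' @examples
#' convert_resistance(3, "wood", "dyn") # 240
#' convert_resistance(100, "dyn", "wood") # 1.25
#' @export
convert_resistance <- function(value, from = c("wood", "dyn", "mpa"),
                               to = c("wood", "dyn", "mpa")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (any(!is.na(value) & value < 0)) abort("resistance must be >= 0")
  to_wood <- c(wood = 1, dyn = 1 / 80, mpa = 1 / 8)
  from_wood <- c(wood = 1, dyn = 80, mpa = 8)
  value * to_wood[[from]] * from_wood[[to]]
}
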