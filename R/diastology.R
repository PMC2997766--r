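#' Mitral E/e' ratio
#'
#' Early mitral inflow velocity over early diastolic annular tissue velocity,
#' the standard noninvasive surrogate for LV filling pressure. When both
#' septal and lateral e' are supplied, the ratio against their average is
#' returned alongside; classification uses the septal ratio.
#'
#' @param mitral_e Early mitral inflow velocity, cm/s.
#' @param eprime_septal Septal annular e', cm/s (> 0).
#' @param eprime_lateral Optional lateral annular e', cm/s.
#' @return A tibble with columns `e_eprime_septal` and `e_eprime_avg`
#'   (`NA` when the lateral velocity is absent).
#' @export
e_over_eprime <- function(mitral_e, eprime_septal, eprime_lateral = NULL) {
  check_positive(eprime_septal, "eprime_septal")
  avg <- if (is.null(eprime_lateral)) {
    NA_real_
  } else {
    check_positive(eprime_lateral, "eprime_lateral")
    mitral_e / ((eprime_septal + eprime_lateral) / 2)
  }
  tibble(e_eprime_septal = mitral_e / eprime_septal, e_eprime_avg = avg)
}

#' Classify LV filling pressure from the septal E/e' ratio
#'
#' `"normal"` below 8, `"elevated"` above 15; the band between (8 to 15
#' inclusive) carries no published class and is `"indeterminate"`.
#'
#' @param e_eprime Septal E/e' ratio.
#' @return Character class.
#' @export
filling_pressure_class <- function(e_eprime) {
  dplyr::case_when(
    is.na(e_eprime) ~ NA_character_,
    e_eprime < 8 ~ "normal",
    e_eprime > 15 ~ "elevated",
    TRUE ~ "indeterminate"
  )
}

#' Estimate pulmonary capillary wedge pressure from E/e'
#'
#' `1.24 * e_eprime + 1.9` (mmHg). Filling pressures are considered elevated
#' when the estimate exceeds 12 mmHg; note the E/e' = 8 class boundary maps
#' to 11.82 mmHg, so a "normal" E/e' never produces an elevated wedge
#' estimate.
#'
#' @param e_eprime Septal E/e' ratio (> 0).
#' @return Estimated PCWP in mmHg.
#' @export
estimate_pcwp <- function(e_eprime) {
  1.24 * e_eprime + 1.9
}

#' Diastolic mean filling rate
#'
#' Stroke volume index over the cardiological diastolic time (first- to
#' second-heart-sound complement, sensor-estimated), scaled to seconds:
#' `(svi / diastolic_time_ms) * 1000`, mL/m^2/s. Rises about threefold from
#' rest to peak exercise in normals and far less in patients.
#'
#' @param svi Stroke volume index, mL/m^2.
#' @param diastolic_time Cardiological diastolic time, ms (> 0).
#' @return Filling rate in mL/m^2/s.
#' @export
diastolic_mean_filling_rate <- function(svi, diastolic_time) {
  check_positive(diastolic_time, "diastolic_time")
  svi / diastolic_time * 1000
}

#' Flag a reversed diastolic/systolic time ratio
#'
#' The ratio is normally above 1; reversal (<= 1) may compromise cardiac
#' filling and coronary perfusion time, especially under stress.
#'
#' @param ds_ratio Diastolic/systolic time ratio (> 0).
#' @return Logical: `TRUE` when flagged (ratio <= 1).
#' @export
ds_ratio_flag <- function(ds_ratio) {
  check_positive(ds_ratio, "ds_ratio")
  ds_ratio <= 1
}

#' Grade right ventricular diastolic function
#'
#' Decision rule on transtricuspid Doppler: E/A < 0.8 suggests impaired
#' relaxation; E/A in \[0.8, 2.1\] with tricuspid E/E' > 6 or diastolic flow
#' predominance in the hepatic veins suggests pseudonormal filling; E/A > 2.1
#' with a deceleration time < 120 ms suggests restrictive filling, as does
#' late diastolic antegrade flow in the pulmonary artery on its own. When the
#' auxiliary datum needed for the matched E/A band is absent the grade is
#' `"indeterminate"`; the function is total over its domain.
#'
#' @param e_a Tricuspid E/A ratio (> 0).
#' @param e_eprime Optional tricuspid E/E' ratio.
#' @param decel_time Optional E-wave deceleration time, ms.
#' @param hepatic_diastolic_predominance Optional logical: diastolic flow
#'   predominance in the hepatic veins.
#' @param pa_late_antegrade_flow Optional logical: late diastolic antegrade
#'   flow in the pulmonary artery.
#' @return One of `"impaired_relaxation"`, `"pseudonormal"`, `"restrictive"`,
#'   `"normal"`, `"indeterminate"`.
#' @export
rv_diastolic_grade <- function(e_a, e_eprime = NA, decel_time = NA,
                               hepatic_diastolic_predominance = NA,
                               pa_late_antegrade_flow = NA) {
  check_positive(e_a, "e_a")
  if (isTRUE(pa_late_antegrade_flow)) return("restrictive")
  if (e_a < 0.8) return("impaired_relaxation")
  if (e_a <= 2.1) {
    if (isTRUE(hepatic_diastolic_predominance)) return("pseudonormal")
    if (!is.na(e_eprime)) {
      if (e_eprime > 6) return("pseudonormal")
      # E/E' <= 6 without hepatic data: rule gives no positive grade
      if (!is.na(hepatic_diastolic_predominance)) return("normal")
    }
    return("indeterminate")
  }
  if (!is.na(decel_time)) {
    return(if (decel_time < 120) "restrictive" else "indeterminate")
  }
  "indeterminate"
}
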