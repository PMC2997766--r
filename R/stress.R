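#' Engine configuration
#'
#' Collects the calculation conventions that are genuinely open choices.
#'
#' @param bsa_method `"mosteller"` (default) or `"power"`; see
#'   [body_surface_area()].
#' @param ees_pressure Pressure fed to the LV elastance index: `"esp"`
#'   (default, the 0.9 * SBP end-systolic surrogate) or `"sbp"` (raw cuff
#'   systolic pressure).
#' @param elastance_indexing `"volume_index"` (default) or `"divide_bsa"`;
#'   see [lv_elastance_index()].
#' @param mpap_doppler_add_rap Add right atrial pressure to the Doppler mean
#'   pulmonary pressure estimate (default `TRUE`).
#' @param mpap_tolerance Tolerance (mmHg) for the standard-vs-Doppler mean
#'   pulmonary pressure consistency check; default 5.
#' @param athlete_or_over55 Subject is a well-trained athlete or older than
#'   55 years (relaxes the exercise SPAP cutoff from 43 to 60 mmHg).
#' @return A named list of class `hemo_config`.
#' @export
hemo_config <- function(bsa_method = c("mosteller", "power"),
                        ees_pressure = c("esp", "sbp"),
                        elastance_indexing = c("volume_index", "divide_bsa"),
                        mpap_doppler_add_rap = TRUE,
                        mpap_tolerance = 5,
                        athlete_or_over55 = FALSE) {
  structure(list(
    bsa_method = match.arg(bsa_method),
    ees_pressure = match.arg(ees_pressure),
    elastance_indexing = match.arg(elastance_indexing),
    mpap_doppler_add_rap = isTRUE(mpap_doppler_add_rap),
    mpap_tolerance = mpap_tolerance,
    athlete_or_over55 = isTRUE(athlete_or_over55)
  ), class = "hemo_config")
}

#' Cardiac cycle length from heart rate
#'
#' `60000 / heart_rate` rounded half-away-from-zero to integer milliseconds
#' (e.g. 800 ms at 75 bpm, 1200 ms at 50 bpm, 500 ms at 120 bpm).
#'
#' @param heart_rate Heart rate, bpm (> 0).
#' @return Cycle length in whole ms.
#' @export
cycle_length <- function(heart_rate) {
  check_positive(heart_rate, "heart_rate")
  x <- 60000 / heart_rate
  sign(x) * floor(abs(x) + 0.5)
}

#' Percent change from rest to peak
#'
#' `100 * (peak - rest) / rest`; `NA` (a not-computable marker, not an
#' error) when the rest value is 0 or either value is missing.
#'
#' @param rest_value,peak_value Numeric vectors.
#' @return Percent change vector.
#' @export
percent_change <- function(rest_value, peak_value) {
  ifelse(is.na(rest_value) | is.na(peak_value) | rest_value == 0,
         NA_real_, 100 * (peak_value - rest_value) / rest_value)
}

#' Classify the force-frequency relation and find the critical heart rate
#'
#' The contractility series is systolic cuff pressure over end-systolic
#' volume index (SP/ESVi) at each stress stage. Shape: `"up_sloping"` when
#' the peak-stage value strictly exceeds every earlier value;
#' `"flat_or_negative"` when the peak value is at or below baseline;
#' `"biphasic"` when the peak value exceeds baseline but not some
#' intermediate value (an interior optimum). The critical heart rate (optimum
#' stimulation frequency) is the heart rate at which SP/ESVi is maximal,
#' taking the earliest stage on ties. The classification is invariant to
#' uniform scaling of the contractility values.
#'
#' @param series A data frame with columns `hr` (bpm) and `sp_esvi`
#'   (mmHg/mL/m^2), ordered by stage; at least 2 rows.
#' @return An object of class `ffr_result`: list with `shape`,
#'   `critical_heart_rate` and the input `series` as a tibble.
#' @examples
#' force_frequency(data.frame(hr = c(60, 100, 140), sp_esvi = c(5, 9, 7)))
#' @export
force_frequency <- function(series) {
  series <- as_tibble(series)
  if (!all(c("hr", "sp_esvi") %in% names(series))) {
    abort("series needs columns 'hr' and 'sp_esvi'")
  }
  if (nrow(series) < 2) abort("force-frequency needs at least 2 stages")
  v <- series$sp_esvi
  n <- length(v)
  shape <- if (v[n] > max(v[-n])) {
    "up_sloping"
  } else if (v[n] <= v[1]) {
    "flat_or_negative"
  } else {
    "biphasic"
  }
  i_max <- which.max(v) # earliest on ties
  structure(list(
    shape = shape,
    critical_heart_rate = series$hr[i_max],
    series = series
  ), class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat("Force-frequency relation: ", x$shape,
      " (critical heart rate ", x$critical_heart_rate, " bpm)\n", sep = "")
  invisible(x)
}

#' Decompose the stroke-volume response into volume mechanisms
#'
#' Splits the rest-to-peak change in stroke volume into the share driven by
#' end-diastolic dilation (Frank-Starling recruitment) and the share driven
#' by end-systolic emptying (inotropic recruitment):
#' `edv_contribution = 100 * dEDV / dSV`,
#' `esv_contribution = 100 * (-dESV) / dSV`; the two always sum to 100%.
#'
#' @param edv_rest,esv_rest Rest volumes, mL.
#' @param edv_peak,esv_peak Peak volumes, mL.
#' @return A tibble with `edv_contribution` and `esv_contribution` (percent);
#'   both `NA` when the stroke volume did not change.
#' @export
sv_decomposition <- function(edv_rest, esv_rest, edv_peak, esv_peak) {
  d_sv <- (edv_peak - esv_peak) - (edv_rest - esv_rest)
  edv_c <- ifelse(d_sv == 0, NA_real_, 100 * (edv_peak - edv_rest) / d_sv)
  esv_c <- ifelse(d_sv == 0, NA_real_, 100 * -(esv_peak - esv_rest) / d_sv)
  tibble(edv_contribution = edv_c, esv_contribution = esv_c)
}

#' Flag the exercise systolic pulmonary artery pressure
#'
#' Normal exercise SPAP is below 43 mmHg. In well-trained athletes or
#' subjects older than 55 years values up to 55-60 mmHg are encountered and
#' may be physiologic, so for them the flag escalates to abnormal only above
#' 60 mmHg.
#'
#' @param peak_spap Peak-exercise SPAP, mmHg (>= 0).
#' @param athlete_or_over55 Logical.
#' @return `"normal"`, `"may_be_physiologic"` or `"abnormal"`.
#' @export
exercise_spap_flag <- function(peak_spap, athlete_or_over55 = FALSE) {
  dplyr::case_when(
    is.na(peak_spap) ~ NA_character_,
    peak_spap < 43 ~ "normal",
    athlete_or_over55 & peak_spap <= 60 ~ "may_be_physiologic",
    TRUE ~ "abnormal"
  )
}

#' Check internal consistency of the two mean pulmonary pressure estimates
#'
#' Compares the standard (systolic/diastolic weighted) and Doppler
#' (regurgitant-jet) mean pulmonary artery pressure estimates; using several
#' methods lets the internal consistency of the data be challenged and
#' confirmed.
#'
#' @param mpap_standard,mpap_doppler The two estimates, mmHg.
#' @param tolerance Agreement tolerance, mmHg (default 5).
#' @return A tibble with `delta` (absolute difference), `consistent`
#'   (logical) and `note`.
#' @export
mpap_consistency <- function(mpap_standard, mpap_doppler, tolerance = 5) {
  delta <- abs(mpap_doppler - mpap_standard)
  tibble(
    delta = delta,
    consistent = delta <= tolerance,
    note = ifelse(delta <= tolerance,
                  sprintf("mPAP estimates consistent (|difference| %.1f <= %g mmHg)",
                          delta, tolerance),
                  sprintf("mPAP estimates disagree (|difference| %.1f > %g mmHg)",
                          delta, tolerance))
  )
}

# ---------------------------------------------------------------------------
# Panel derivation

# Row order mirrors the printed rest-and-stress algorithm sheet: systemic
# block, diastolic block, then right-heart block.
panel_parameters <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~parameter, ~label, ~algorithm, ~unit, ~digits,
    "bsa", "Body surface area", "sqrt(weight * height / 3600)", "m^2", 2,
    "sv", "Stroke volume", "EDV - ESV", "mL", 1,
    "svi", "Stroke volume index", "SV / BSA", "mL/m^2", 1,
    "co", "Cardiac output", "HR * SV / 1000", "L/min", 2,
    "ci", "Cardiac index", "CO / BSA", "L/min/m^2", 2,
    "map", "Mean arterial pressure", "(SBP - DBP)/3 + DBP", "mmHg", 1,
    "pp", "Pulse pressure", "SBP - DBP", "mmHg", 1,
    "esp", "End-systolic pressure", "0.9 * SBP", "mmHg", 1,
    "ees_index", "LV elastance index", "ESP / (ESV / BSA)", "mmHg/mL/m^2", 2,
    "ea_index", "Arterial elastance index", "ESP / (SV / BSA)", "mmHg/mL/m^2", 2,
    "vac", "Ventricular-arterial coupling", "Ees/Ea = SV / ESV", "ratio", 2,
    "svr", "Systemic vascular resistance", "80 * (MAP - 5) / CO", "dyne.s.cm^-5", 0,
    "compliance", "Systemic arterial compliance", "SV / PP", "mL/mmHg", 2,
    "e_eprime_septal", "Mitral E/e' (septal)", "E / e'(septal)", "ratio", 2,
    "e_eprime_avg", "Mitral E/e' (averaged)", "E / mean(e' septal, lateral)", "ratio", 2,
    "pcwp_est", "Estimated wedge pressure", "1.24 * E/e' + 1.9", "mmHg", 1,
    "filling_rate", "Diastolic mean filling rate", "SVi / diastolic time * 1000", "mL/m^2/s", 1,
    "ds_ratio", "Diastolic/systolic time ratio", "measured (M-mode or sensor)", "ratio", 2,
    "cycle_length", "Cardiac cycle length", "60000 / HR", "ms", 0,
    "rap", "Right atrial pressure", "IVC diameter + collapse lookup", "mmHg", 0,
    "tr_gradient", "TR peak gradient", "4 * TRV^2", "mmHg", 1,
    "spap", "Systolic PA pressure (RVSP)", "4 * TRV^2 + RAP", "mmHg", 1,
    "padp", "Diastolic PA pressure", "4 * PR(end-diastolic V)^2 + RAP", "mmHg", 1,
    "mpap_standard", "Mean PA pressure (standard)", "SPAP/3 + 2*PADP/3", "mmHg", 1,
    "mpap_doppler", "Mean PA pressure (Doppler)", "4 * PR(peak V)^2 + RAP", "mmHg", 1,
    "papp", "PA pulse pressure", "4*TRV^2 - 4*PR(end-diastolic V)^2", "mmHg", 1,
    "pvr_invasive", "Pulmonary vascular resistance", "80 * (mPAP - PCWP) / CO", "dyne.s.cm^-5", 0,
    "pvr_doppler", "Pulmonary vascular resistance (Doppler)", "10 * TRV / TVI(RVOT)", "Wood units", 2,
    "pvc", "Pulmonary vascular capacitance", "SV / PAPP", "mL/mmHg", 2
  )
}

range_flag <- function(value, lo, hi, what, active = TRUE) {
  # resting reference bands are suppressed for stress stages (active = FALSE):
  # a cardiac output of 13 L/min is expected, not abnormal, at peak exercise
  if (is.na(value) || !active) return(NA_character_)
  if (value < lo) sprintf("%s below normal %g-%g", what, lo, hi)
  else if (value > hi) sprintf("%s above normal %g-%g", what, lo, hi)
  else NA_character_
}

#' Derive the full hemodynamic panel for one stage
#'
#' Runs every applicable calculation on one stage record: the systemic block
#' (BSA, SV/SVi, CO/CI, MAP, PP, ESP, elastance indices, coupling, SVR,
#' compliance), the diastolic block (E/e', wedge estimate, filling rate, D/S
#' ratio), and the right-heart block (RAP lookup, Bernoulli pressures, both
#' mean-pressure and both resistance estimators, capacitance). Parameters
#' whose inputs are missing or invalid are retained in the sheet with an
#' explicit not-computable reason naming the missing field; normal-range
#' flags are warnings only and never block a value.
#'
#' @param stage A one-row data frame (or named list) of stage measurements;
#'   see [hemo_case()] for fields and units.
#' @param subject Subject biometrics (`height` cm, `weight` kg).
#' @param config A [hemo_config()].
#' @return A `hemo_panel` tibble with one row per panel parameter and columns
#'   `parameter`, `label`, `algorithm`, `value`, `unit`, `flag`,
#'   `not_computable` (reason, or `NA`), plus a `stage_label` attribute.
#' @export
derive_panel <- function(stage, subject, config = hemo_config()) {
  stage <- as.list(as_tibble(as.list(stage))[1, ])
  subject <- as.list(as_tibble(as.list(subject))[1, ])
  for (f in setdiff(stage_fields(), names(stage))) stage[[f]] <- NA_real_

  miss <- mandatory_stage_fields()[vapply(
    mandatory_stage_fields(), function(f) is.na(stage[[f]]), logical(1)
  )]
  if (length(miss) > 0) {
    abort(paste0("mandatory field(s) missing: ", paste(miss, collapse = ", ")))
  }
  if (is.null(subject$height) || is.null(subject$weight) ||
      is.na(subject$height) || is.na(subject$weight)) {
    abort("mandatory field(s) missing: height, weight")
  }

  values <- list()
  flags <- list()
  nc <- list()
  set <- function(param, value, flag = NA_character_) {
    values[[param]] <<- value
    flags[[param]] <<- flag
  }
  mark_nc <- function(param, reason) {
    nc[[param]] <<- reason
  }
  need <- function(...) {
    fields <- c(...)
    absent <- fields[vapply(fields, function(f) is.na(stage[[f]]), logical(1))]
    if (length(absent) == 0) NULL else paste0("missing ", paste(absent, collapse = ", "))
  }

  resting <- is.null(stage$stage_label) || is.na(stage$stage_label) ||
    identical(stage$stage_label, "rest")

  bsa <- body_surface_area(subject$weight, subject$height, config$bsa_method)
  set("bsa", bsa, range_flag(bsa, 1.5, 3.5, "BSA"))

  volumes_ok <- stage$edv > stage$esv && stage$esv > 0
  pressures_ok <- stage$sbp > stage$dbp && stage$dbp > 0

  sbp <- stage$sbp
  esp <- if (pressures_ok) end_systolic_pressure(sbp) else NA_real_
  if (pressures_ok) {
    map <- mean_arterial_pressure(stage$sbp, stage$dbp)
    pp <- stage$sbp - stage$dbp
    set("map", map, range_flag(map, 70, 100, "MAP", resting))
    set("pp", pp)
    set("esp", esp)
  } else {
    for (p in c("map", "pp", "esp")) mark_nc(p, "invalid pressures (SBP <= DBP)")
    map <- pp <- NA_real_
  }

  if (volumes_ok) {
    sv_tbl <- stroke_volume(stage$edv, stage$esv, bsa)
    sv <- sv_tbl$sv
    svi <- sv_tbl$svi
    set("sv", sv, range_flag(sv, 60, 100, "SV", resting))
    set("svi", svi)
    co_tbl <- cardiac_output(stage$heart_rate, sv, bsa)
    co <- co_tbl$co
    set("co", co, range_flag(co, 4, 6, "CO", resting))
    set("ci", co_tbl$ci, range_flag(co_tbl$ci, 2.5, 3.6, "CI", resting))
    vac <- ventricular_arterial_coupling(sv, stage$esv)
    set("vac", vac,
        if (vac <= 0.5) "blunted coupling (DCM-like, 0.4-0.5 band)" else NA_character_)
  } else {
    for (p in c("sv", "svi", "co", "ci", "vac")) {
      mark_nc(p, "invalid volumes (EDV <= ESV)")
    }
    sv <- svi <- co <- NA_real_
  }

  ees_pressure <- if (config$ees_pressure == "esp") esp else sbp
  if (volumes_ok && pressures_ok) {
    set("ees_index",
        lv_elastance_index(ees_pressure, stage$esv, bsa, config$elastance_indexing))
    set("ea_index",
        arterial_elastance_index(esp, sv, bsa, config$elastance_indexing))
    svr <- systemic_vascular_resistance(map, co)
    set("svr", svr, range_flag(svr, 900, 1300, "SVR", resting))
    set("compliance", systemic_arterial_compliance(sv, pp))
  } else {
    reason <- if (!volumes_ok) "invalid volumes (EDV <= ESV)" else "invalid pressures (SBP <= DBP)"
    for (p in c("ees_index", "ea_index", "svr", "compliance")) mark_nc(p, reason)
  }

  # diastolic block
  r <- need("mitral_e", "mitral_eprime_septal")
  e_sept <- NA_real_
  if (is.null(r)) {
    lat <- if (is.na(stage$mitral_eprime_lateral)) NULL else stage$mitral_eprime_lateral
    ee <- e_over_eprime(stage$mitral_e, stage$mitral_eprime_septal, lat)
    e_sept <- ee$e_eprime_septal
    set("e_eprime_septal", e_sept,
        paste0("filling pressures ", filling_pressure_class(e_sept)))
    if (!is.na(ee$e_eprime_avg)) set("e_eprime_avg", ee$e_eprime_avg)
    else mark_nc("e_eprime_avg", "missing mitral_eprime_lateral")
    pcwp <- estimate_pcwp(e_sept)
    set("pcwp_est", pcwp,
        if (pcwp > 12) "elevated filling pressure (PCWP > 12 mmHg)" else NA_character_)
  } else {
    for (p in c("e_eprime_septal", "e_eprime_avg", "pcwp_est")) mark_nc(p, r)
  }

  r <- need("diastolic_time")
  if (is.null(r) && volumes_ok) {
    set("filling_rate", diastolic_mean_filling_rate(svi, stage$diastolic_time))
  } else {
    mark_nc("filling_rate", r %||% "invalid volumes (EDV <= ESV)")
  }

  r <- need("ds_ratio")
  if (is.null(r)) {
    set("ds_ratio", stage$ds_ratio,
        if (ds_ratio_flag(stage$ds_ratio))
          "reversed diastolic/systolic ratio (<= 1) may compromise filling"
        else NA_character_)
  } else {
    mark_nc("ds_ratio", r)
  }

  set("cycle_length", cycle_length(stage$heart_rate))

  # right-heart block
  r <- need("ivc_diameter", "ivc_collapse")
  rap <- NA_real_
  if (is.null(r)) {
    rap_tbl <- right_atrial_pressure(stage$ivc_diameter, stage$ivc_collapse)
    rap <- rap_tbl$rap
    set("rap", rap, paste0(rap_tbl$regime, " (range ", rap_tbl$rap_low, "-",
                           rap_tbl$rap_high, " mmHg)"))
  } else {
    mark_nc("rap", r)
  }

  r <- need("tr_velocity")
  spap <- NA_real_
  if (is.null(r)) {
    set("tr_gradient", bernoulli_gradient(stage$tr_velocity),
        if (stage$tr_velocity > 2.9) "TR velocity above normal cutoff (2.8-2.9 m/s)"
        else NA_character_)
    if (!is.na(rap)) {
      spap <- rv_systolic_pressure(stage$tr_velocity, rap)
      set("spap", spap,
          if (spap > 40) "RVSP > 40 mmHg: further evaluation recommended"
          else NA_character_)
    } else {
      mark_nc("spap", "missing ivc_diameter, ivc_collapse (no RAP estimate)")
    }
  } else {
    mark_nc("tr_gradient", r)
    mark_nc("spap", r)
  }

  r <- need("pr_end_diastolic_velocity")
  padp <- NA_real_
  if (is.null(r) && !is.na(rap)) {
    grad <- bernoulli_gradient(stage$pr_end_diastolic_velocity)
    padp <- pa_diastolic_pressure(stage$pr_end_diastolic_velocity, rap)
    set("padp", padp,
        if (grad > 5) "PR end-diastolic gradient > 5 mmHg" else NA_character_)
  } else {
    mark_nc("padp", r %||% "missing ivc_diameter, ivc_collapse (no RAP estimate)")
  }

  if (!is.na(spap) && !is.na(padp)) {
    set("mpap_standard", mean_pa_pressure(spap, padp))
  } else {
    mark_nc("mpap_standard", "missing SPAP or PADP inputs")
  }

  r <- need("pr_peak_velocity")
  if (is.null(r) && (!config$mpap_doppler_add_rap || !is.na(rap))) {
    set("mpap_doppler",
        mean_pa_pressure_doppler(stage$pr_peak_velocity, rap,
                                 config$mpap_doppler_add_rap),
        if (config$mpap_doppler_add_rap) "includes RAP term" else "RAP term omitted")
  } else {
    mark_nc("mpap_doppler", r %||% "missing ivc_diameter, ivc_collapse (no RAP estimate)")
  }

  r <- need("tr_velocity", "pr_end_diastolic_velocity")
  papp <- NA_real_
  if (is.null(r)) {
    papp <- pa_pulse_pressure(stage$tr_velocity, stage$pr_end_diastolic_velocity)
    set("papp", papp)
    if (volumes_ok && papp > 0) {
      set("pvc", pulmonary_vascular_capacitance(sv, papp))
    } else {
      mark_nc("pvc", if (!volumes_ok) "invalid volumes (EDV <= ESV)" else "zero PA pulse pressure")
    }
  } else {
    mark_nc("papp", r)
    mark_nc("pvc", r)
  }

  if (!is.null(values$mpap_standard) && !is.null(values$pcwp_est) && volumes_ok &&
      values$mpap_standard >= values$pcwp_est) {
    pvr <- pvr_invasive(values$mpap_standard, values$pcwp_est, co)
    rf <- range_flag(pvr, 100, 200, "PVR", resting)
    set("pvr_invasive", pvr,
        paste(c("PCWP estimated from E/e'", if (!is.na(rf)) rf), collapse = "; "))
  } else {
    mark_nc("pvr_invasive", "missing mPAP or wedge-pressure estimate")
  }

  r <- need("tr_velocity", "rvot_tvi")
  if (is.null(r)) {
    pd <- pvr_doppler(stage$tr_velocity, stage$rvot_tvi)
    set("pvr_doppler", pd$pvr_wood,
        paste0(pd$severity,
               if (!pd$reliable) "; unreliable (> 8 Wood units)" else ""))
  } else {
    mark_nc("pvr_doppler", r)
  }

  spec <- panel_parameters()
  panel <- dplyr::mutate(
    spec,
    value = vapply(.data$parameter, function(p) values[[p]] %||% NA_real_,
                   numeric(1), USE.NAMES = FALSE),
    flag = vapply(.data$parameter, function(p) flags[[p]] %||% NA_character_,
                  character(1), USE.NAMES = FALSE),
    not_computable = vapply(.data$parameter, function(p) nc[[p]] %||% NA_character_,
                            character(1), USE.NAMES = FALSE)
  )
  structure(panel, class = c("hemo_panel", class(panel)),
            stage_label = stage$stage_label %||% NA_character_)
}

#' @export
print.hemo_panel <- function(x, ...) {
  cat("<hemo_panel> stage:", attr(x, "stage_label") %||% "?", "\n")
  NextMethod()
}
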