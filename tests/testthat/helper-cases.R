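# A fully-specified two-stage case with hand-checkable arithmetic
# (BSA = sqrt(3.6), rest SV = 80 mL, rest CO = 4.8 L/min, ...).
manual_case <- function() {
  hemo_case(
    subject = list(age = 50, height = 180, weight = 72),
    stages = data.frame(
      stage_label = c("rest", "peak"),
      heart_rate = c(60, 120),
      sbp = c(120, 150), dbp = c(80, 70),
      edv = c(140, 150), esv = c(60, 40),
      mitral_e = c(80, 110),
      mitral_eprime_septal = c(10, 14),
      mitral_eprime_lateral = c(12, 16),
      diastolic_time = c(500, 252),
      ds_ratio = c(1.2, 1.02),
      tr_velocity = c(2.5, 2.8),
      ivc_diameter = c(1.8, 1.8),
      ivc_collapse = c(0.6, 0.6),
      pr_end_diastolic_velocity = c(1.0, 1.2),
      pr_peak_velocity = c(1.7, 1.9),
      rvot_tvi = c(20, 24)
    )
  )
}

panel_value <- function(panel, param) panel$value[panel$parameter == param]
panel_nc <- function(panel, param) panel$not_computable[panel$parameter == param]
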