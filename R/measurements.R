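#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Canonical stage-level fields, fixed units (velocities: mitral in cm/s,
# tricuspid/pulmonary regurgitant jets in m/s; times in ms; volumes in mL).
stage_fields <- function() {
  c(
    "stage_label", "heart_rate", "sbp", "dbp", "edv", "esv",
    "mitral_e", "mitral_eprime_septal", "mitral_eprime_lateral",
    "diastolic_time", "ds_ratio",
    "tr_velocity", "ivc_diameter", "ivc_collapse",
    "pr_end_diastolic_velocity", "pr_peak_velocity", "rvot_tvi"
  )
}

mandatory_stage_fields <- function() {
  c("heart_rate", "sbp", "dbp", "edv", "esv")
}

subject_fields <- function() c("age", "height", "weight")

#' Assemble a rest/stress echocardiography case
#'
#' Bundles subject biometrics with an ordered table of per-stage measurements
#' (first row = rest, last row = peak) into a `hemo_case` object, the input to
#' [derive_panel()] and [stress_comparison()].
#'
#' @param subject A named list or one-row data frame with `height` (cm),
#'   `weight` (kg) and optionally `age` (years).
#' @param stages A data frame with one row per stage. Recognised columns are
#'   `stage_label`, the mandatory `heart_rate` (bpm), `sbp`/`dbp` (mmHg),
#'   `edv`/`esv` (mL), and the optional Doppler/timing fields `mitral_e`,
#'   `mitral_eprime_septal`, `mitral_eprime_lateral` (cm/s), `diastolic_time`
#'   (ms), `ds_ratio`, `tr_velocity`, `pr_end_diastolic_velocity`,
#'   `pr_peak_velocity` (m/s), `ivc_diameter` (cm), `ivc_collapse`
#'   (fraction 0-1; values > 1 are taken as percent and divided by 100),
#'   `rvot_tvi` (cm). Unknown columns are an error; absent optional fields
#'   are stored as `NA`, never imputed.
#'
#' @return A `hemo_case` object: a list with elements `subject` (one-row
#'   tibble) and `stages` (tibble, one row per stage in rest-to-peak order).
#' @seealso [read_case()], [validate_case()], [make_fixture()]
#' @examples
#' case <- hemo_case(
#'   subject = list(age = 44, height = 175, weight = 72),
#'   stages = data.frame(
#'     stage_label = c("rest", "peak"),
#'     heart_rate = c(68, 160), sbp = c(120, 160), dbp = c(78, 72),
#'     edv = c(132, 130), esv = c(45, 18)
#'   )
#' )
#' validate_case(case)
#' @export
hemo_case <- function(subject, stages) {
  subject <- as_tibble(as.list(subject))
  unknown <- setdiff(names(subject), subject_fields())
  if (length(unknown) > 0) {
    abort(paste0("unknown subject field(s): ", paste(unknown, collapse = ", ")))
  }
  for (f in c("height", "weight")) {
    if (is.null(subject[[f]]) || is.na(subject[[f]])) {
      abort(paste0("mandatory subject field missing: ", f))
    }
    if (subject[[f]] <= 0) abort(paste0("subject ", f, " must be > 0"))
  }
  if ("age" %in% names(subject) && !is.na(subject$age) && subject$age < 0) {
    abort("subject age must be >= 0")
  }
  subject <- subject[intersect(subject_fields(), names(subject))]

  stages <- as_tibble(stages)
  unknown <- setdiff(names(stages), stage_fields())
  if (length(unknown) > 0) {
    abort(paste0("unknown stage field(s): ", paste(unknown, collapse = ", ")))
  }
  miss <- setdiff(mandatory_stage_fields(), names(stages))
  if (length(miss) > 0) {
    abort(paste0("mandatory stage field(s) missing: ", paste(miss, collapse = ", ")))
  }
  if (nrow(stages) < 2) abort("a case needs at least two stages (rest and peak)")
  for (f in setdiff(stage_fields(), names(stages))) stages[[f]] <- NA_real_
  if (all(is.na(stages$stage_label))) {
    stages$stage_label <- default_stage_labels(nrow(stages))
  }
  stages$stage_label <- as.character(stages$stage_label)
  # percent dialect for IVC collapse: "60" means 60%
  stages$ivc_collapse <- ifelse(
    !is.na(stages$ivc_collapse) & stages$ivc_collapse > 1,
    stages$ivc_collapse / 100, stages$ivc_collapse
  )
  stages <- stages[, stage_fields()]
  structure(list(subject = subject, stages = stages), class = "hemo_case")
}

default_stage_labels <- function(n) {
  if (n == 2) return(c("rest", "peak"))
  c("rest", paste0("intermediate", seq_len(n - 2)), "peak")
}

#' @export
print.hemo_case <- function(x, ...) {
  cat("<hemo_case> ", nrow(x$stages), " stages\n", sep = "")
  cat("subject: height ", x$subject$height, " cm, weight ",
      x$subject$weight, " kg\n", sep = "")
  print(x$stages[, c("stage_label", mandatory_stage_fields())])
  invisible(x)
}

#' Read a case file (JSON or CSV)
#'
#' JSON schema: `{"subject": {...}, "stages": [{"stage_label": "rest", ...}]}`
#' with the field names of [hemo_case()]. CSV dialect: one row per stage,
#' header = field names, with the subject columns `age`, `height`, `weight`
#' repeated on each row; UTF-8, comma separated, `.` decimal.
#'
#' @param path Path to the case file.
#' @param format `"json"`, `"csv"`, or `"auto"` (from the file extension).
#' @return A `hemo_case`.
#' @export
read_case <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("case file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", csv = "csv",
                     abort(paste0("cannot infer format from extension '.", ext, "'")))
  }
  if (format == "json") {
    parsed <- tryCatch(
      jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) abort(paste0("malformed JSON in ", path, ": ", conditionMessage(e)))
    )
    if (is.null(parsed$subject) || is.null(parsed$stages)) {
      abort("JSON case must have 'subject' and 'stages' entries")
    }
    hemo_case(parsed$subject, as.data.frame(parsed$stages))
  } else {
    df <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) abort(paste0("malformed CSV in ", path, ": ", conditionMessage(e)))
    )
    subj_cols <- intersect(subject_fields(), names(df))
    if (!all(c("height", "weight") %in% subj_cols)) {
      abort("CSV case must carry 'height' and 'weight' columns")
    }
    subject <- lapply(df[subj_cols], function(col) col[which(!is.na(col))[1]])
    hemo_case(subject, df[setdiff(names(df), subj_cols)])
  }
}

#' Write a case file (JSON or CSV)
#'
#' Inverse of [read_case()]: `read_case(write_case(case, path))` restores
#' every stored field in both formats. Values are written at full precision.
#'
#' @param case A `hemo_case`.
#' @param path Output path.
#' @param format `"json"`, `"csv"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(case, "hemo_case"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), json = "json", csv = "csv",
                     abort("cannot infer format from extension"))
  }
  if (format == "json") {
    drop_na_cols <- function(df) df[, colSums(!is.na(df)) > 0 | names(df) == "stage_label", drop = FALSE]
    jsonlite::write_json(
      list(subject = as.list(case$subject), stages = drop_na_cols(case$stages)),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    df <- case$stages
    for (f in subject_fields()) {
      df[[f]] <- if (is.null(case$subject[[f]])) NA_real_ else case$subject[[f]]
    }
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

issue_row <- function(stage, field, severity, message) {
  tibble(stage = stage, field = field, severity = severity, message = message)
}

#' Validate a case against physiologic plausibility rules
#'
#' Pure report-only check: each violated invariant yields one issue row.
#' `error` rows (e.g. ESV >= EDV, DBP >= SBP) block only the dependent
#' parameters during panel derivation; `warning` rows flag unusual but
#' admissible physiology (tricuspid regurgitant velocity above the 2.9 m/s
#' normal cutoff, diastolic/systolic time ratio at or below 1, peak heart
#' rate not above rest).
#'
#' @param case A `hemo_case`.
#' @return A tibble with columns `stage`, `field`, `severity`
#'   (`"error"`/`"warning"`), `message`; zero rows for a fully normal case.
#' @export
validate_case <- function(case) {
  stopifnot(inherits(case, "hemo_case"))
  st <- case$stages
  issues <- purrr::map_dfr(seq_len(nrow(st)), function(i) {
    s <- st[i, ]
    lab <- s$stage_label
    out <- list()
    add <- function(field, severity, message) {
      out[[length(out) + 1]] <<- issue_row(lab, field, severity, message)
    }
    if (!is.na(s$heart_rate) && s$heart_rate <= 0) {
      add("heart_rate", "error", "heart rate must be positive")
    }
    if (!is.na(s$sbp) && !is.na(s$dbp) && (s$dbp >= s$sbp || s$dbp <= 0)) {
      add("sbp/dbp", "error", "pressures must satisfy SBP > DBP > 0")
    }
    if (!is.na(s$edv) && !is.na(s$esv) && (s$esv >= s$edv || s$esv <= 0)) {
      add("sv", "error", "volumes must satisfy EDV > ESV > 0; stroke volume not computable")
    }
    for (f in c("mitral_e", "mitral_eprime_septal", "mitral_eprime_lateral",
                "tr_velocity", "pr_end_diastolic_velocity", "pr_peak_velocity")) {
      if (!is.na(s[[f]]) && s[[f]] < 0) add(f, "error", paste0(f, " must be >= 0"))
    }
    if (!is.na(s$ivc_collapse) && (s$ivc_collapse < 0 || s$ivc_collapse > 1)) {
      add("ivc_collapse", "error", "IVC collapse must be a fraction in [0, 1]")
    }
    if (!is.na(s$tr_velocity) && s$tr_velocity > 2.9) {
      add("tr_velocity", "warning", "TR velocity above normal cutoff (2.8-2.9 m/s)")
    }
    if (!is.na(s$ds_ratio) && s$ds_ratio <= 1) {
      add("ds_ratio", "warning",
          "diastolic/systolic time ratio at or below 1 may compromise filling")
    }
    dplyr::bind_rows(out)
  })
  hr <- st$heart_rate
  if (!is.na(hr[1]) && !is.na(hr[length(hr)]) && hr[length(hr)] <= hr[1]) {
    issues <- dplyr::bind_rows(
      issues,
      issue_row("peak", "heart_rate", "warning", "peak heart rate not above rest")
    )
  }
  if (nrow(issues) == 0) {
    issues <- tibble(stage = character(), field = character(),
                     severity = character(), message = character())
  }
  issues
}
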