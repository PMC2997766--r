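#' Compare rest and peak-stress hemodynamic panels
#'
#' The main pipeline entry point: validates the case, derives a full panel
#' for every stage, pairs the rest and peak panels into a calculated-results
#' table with absolute and percent changes, classifies the force-frequency
#' relation (systolic cuff pressure over end-systolic volume index across all
#' stages) with its critical heart rate, decomposes the stroke-volume
#' response into end-diastolic vs end-systolic contributions, flags the
#' exercise pulmonary pressure, and cross-checks the two mean pulmonary
#' pressure estimates.
#'
#' @param case A `hemo_case` (see [hemo_case()], [read_case()],
#'   [make_fixture()]).
#' @param config A [hemo_config()].
#' @return An object of class `stress_comparison`: a list with
#'   \describe{
#'     \item{comparison}{tibble: `parameter`, `label`, `algorithm`, `unit`,
#'       `rest`, `peak`, `delta`, `pct_change`, `flag_rest`, `flag_peak`,
#'       `not_computable`}
#'     \item{panels}{named list of per-stage `hemo_panel` tibbles}
#'     \item{ffr}{[force_frequency()] result (or `NULL` with < 2 usable
#'       stages)}
#'     \item{sv_decomposition}{[sv_decomposition()] tibble}
#'     \item{spap_exercise}{exercise SPAP flag for the peak stage}
#'     \item{consistency}{per-stage mean-pulmonary-pressure consistency
#'       notes}
#'     \item{validation}{the [validate_case()] report}
#'   }
#'   Use [generics::tidy()] for the comparison table, [generics::glance()]
#'   for a one-row summary, and [ggplot2::autoplot()] or [plot_trends()] for
#'   figures.
#' @examples
#' comp <- stress_comparison(make_fixture("normal", seed = 1))
#' glance(comp)
#' @export
stress_comparison <- function(case, config = hemo_config()) {
  stopifnot(inherits(case, "hemo_case"))
  validation <- validate_case(case)
  st <- case$stages
  labels <- st$stage_label
  panels <- purrr::map(seq_len(nrow(st)), function(i) {
    derive_panel(st[i, ], case$subject, config)
  })
  names(panels) <- labels

  rest_p <- panels[[1]]
  peak_p <- panels[[length(panels)]]
  comparison <- tibble(
    parameter = rest_p$parameter,
    label = rest_p$label,
    algorithm = rest_p$algorithm,
    unit = rest_p$unit,
    rest = rest_p$value,
    peak = peak_p$value,
    delta = peak_p$value - rest_p$value,
    pct_change = percent_change(rest_p$value, peak_p$value),
    flag_rest = rest_p$flag,
    flag_peak = peak_p$flag,
    not_computable = dplyr::coalesce(rest_p$not_computable, peak_p$not_computable)
  )

  # force-frequency series: raw systolic cuff pressure over ESV index
  bsa <- body_surface_area(case$subject$weight, case$subject$height,
                           config$bsa_method)
  ffr_series <- tibble(
    stage = labels,
    hr = st$heart_rate,
    sp_esvi = st$sbp / (st$esv / bsa)
  )
  usable <- stats::complete.cases(ffr_series[, c("hr", "sp_esvi")])
  ffr <- if (sum(usable) >= 2) force_frequency(ffr_series[usable, ]) else NULL

  n <- nrow(st)
  svdec <- sv_decomposition(st$edv[1], st$esv[1], st$edv[n], st$esv[n])

  peak_spap <- peak_p$value[peak_p$parameter == "spap"]
  spap_exercise <- exercise_spap_flag(peak_spap, config$athlete_or_over55)

  consistency <- purrr::map_dfr(seq_along(panels), function(i) {
    p <- panels[[i]]
    std <- p$value[p$parameter == "mpap_standard"]
    dop <- p$value[p$parameter == "mpap_doppler"]
    if (is.na(std) || is.na(dop)) return(NULL)
    dplyr::mutate(mpap_consistency(std, dop, config$mpap_tolerance),
                  stage = labels[i], .before = 1)
  })

  structure(list(
    comparison = comparison,
    panels = panels,
    ffr = ffr,
    sv_decomposition = svdec,
    spap_exercise = spap_exercise,
    consistency = consistency,
    validation = validation,
    case = case,
    config = config
  ), class = "stress_comparison")
}

#' @export
print.stress_comparison <- function(x, ...) {
  cat("<stress_comparison> ", length(x$panels), " stages (",
      paste(names(x$panels), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$ffr)) print(x$ffr)
  print(x$comparison[, c("parameter", "rest", "peak", "pct_change")], n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the calculated-results table of a stress comparison
#'
#' @param x A `stress_comparison`.
#' @param ... Unused.
#' @return The comparison tibble: one row per panel parameter with rest and
#'   peak values, absolute and percent change, flags and not-computable
#'   reasons.
#' @export
tidy.stress_comparison <- function(x, ...) {
  x$comparison
}

#' One-row summary of a stress comparison
#'
#' @param x A `stress_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: coupling and elastance indices at rest and peak,
#'   percent SVR change, filling-rate rest-to-peak ratio, force-frequency
#'   shape and critical heart rate, stroke-volume decomposition, exercise
#'   SPAP flag, and issue counts from validation.
#' @export
glance.stress_comparison <- function(x, ...) {
  cmp <- x$comparison
  val <- function(p, col) cmp[[col]][cmp$parameter == p]
  tibble(
    vac_rest = val("vac", "rest"),
    vac_peak = val("vac", "peak"),
    ees_index_rest = val("ees_index", "rest"),
    ees_index_peak = val("ees_index", "peak"),
    ea_index_rest = val("ea_index", "rest"),
    ea_index_peak = val("ea_index", "peak"),
    svr_pct_change = val("svr", "pct_change"),
    filling_rate_ratio = val("filling_rate", "peak") / val("filling_rate", "rest"),
    ffr_shape = if (is.null(x$ffr)) NA_character_ else x$ffr$shape,
    critical_heart_rate = if (is.null(x$ffr)) NA_real_ else x$ffr$critical_heart_rate,
    edv_contribution = x$sv_decomposition$edv_contribution,
    esv_contribution = x$sv_decomposition$esv_contribution,
    spap_exercise = x$spap_exercise %||% NA_character_,
    n_errors = sum(x$validation$severity == "error"),
    n_warnings = sum(x$validation$severity == "warning")
  )
}
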