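format_value <- function(value, digits, reason) {
  dplyr::case_when(
    !is.na(value) ~ sprintf(paste0("%.", digits, "f"), value),
    !is.na(reason) ~ paste0("n/c (", reason, ")"),
    TRUE ~ ""
  )
}

report_rows <- function(comparison) {
  cmp <- comparison$comparison
  flags <- purrr::map2_chr(cmp$flag_rest, cmp$flag_peak, function(r, p) {
    paste(c(if (!is.na(r)) paste0("rest: ", r),
            if (!is.na(p)) paste0("peak: ", p)), collapse = "; ")
  })
  tibble(
    parameter = cmp$parameter,
    algorithm = cmp$algorithm,
    rest = format_value(cmp$rest, cmp$digits %||% NA, cmp$not_computable),
    peak = format_value(cmp$peak, cmp$digits %||% NA, cmp$not_computable),
    unit = cmp$unit,
    pct_change = ifelse(is.na(cmp$pct_change), "",
                        sprintf("%.1f", cmp$pct_change)),
    flags = flags
  )
}

#' Render the calculated-results sheet
#'
#' Produces the rest/peak report: one row per panel parameter with the
#' calculation algorithm, the rest and peak values (rendered at the
#' parameter's stated precision: pressures 0-1 decimals, elastances and
#' ratios 2, percent changes 1), the percent rest-to-peak change, and flags.
#' Parameters that could not be computed are rendered `n/c (<reason>)`.
#' Output is deterministic: identical inputs give byte-identical documents.
#'
#' @param comparison A [stress_comparison()] result.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param path Optional output file; when given the document is also written
#'   there.
#' @return The document as a single string, invisibly when `path` is given.
#' @export
render_report <- function(comparison, format = c("text", "csv", "json"),
                          path = NULL) {
  stopifnot(inherits(comparison, "stress_comparison"))
  format <- match.arg(format)
  cmp <- comparison$comparison
  cmp$digits <- panel_parameters()$digits[match(cmp$parameter, panel_parameters()$parameter)]
  rows <- report_rows(list(comparison = cmp))

  doc <- switch(format,
    csv = readr::format_csv(rows),
    json = as.character(jsonlite::toJSON(list(
      rows = rows,
      force_frequency = if (is.null(comparison$ffr)) NULL else
        list(shape = comparison$ffr$shape,
             critical_heart_rate = comparison$ffr$critical_heart_rate),
      sv_decomposition = comparison$sv_decomposition,
      spap_exercise = comparison$spap_exercise,
      mpap_consistency = comparison$consistency
    ), auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")),
    text = {
      hdr <- c("parameter", "algorithm", "rest", "peak", "unit", "% change", "flags")
      m <- rbind(hdr, as.matrix(rows))
      widths <- apply(nchar(m), 2, max)
      lines <- apply(m, 1, function(r) {
        paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
      })
      extra <- c(
        if (!is.null(comparison$ffr))
          sprintf("force-frequency: %s (critical heart rate %g bpm)",
                  comparison$ffr$shape, comparison$ffr$critical_heart_rate),
        if (!is.na(comparison$sv_decomposition$edv_contribution))
          sprintf("stroke-volume response: %.1f%% end-diastolic, %.1f%% end-systolic",
                  comparison$sv_decomposition$edv_contribution,
                  comparison$sv_decomposition$esv_contribution),
        if (!is.na(comparison$spap_exercise %||% NA))
          paste0("exercise SPAP: ", comparison$spap_exercise),
        if (nrow(comparison$consistency) > 0) comparison$consistency$note
      )
      paste(c(lines, "", extra, ""), collapse = "\n")
    }
  )
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(doc), con)
    return(invisible(doc))
  }
  doc
}

#' Plot rest-to-peak trends against heart rate
#'
#' One panel per computable parameter, heart rate on the x axis and the
#' parameter value on the y axis across all stages, plus a force-frequency
#' panel (SP/ESVi vs heart rate) with the critical heart rate marked.
#'
#' @param comparison A [stress_comparison()].
#' @param outdir Directory for the figure files (created if needed); one PNG
#'   per parameter plus `force_frequency.png`.
#' @param width,height Figure size in inches.
#' @return Invisibly, the written file paths. Parameters with fewer than two
#'   computed values are omitted (with a message).
#' @export
plot_trends <- function(comparison, outdir, width = 4, height = 3) {
  stopifnot(inherits(comparison, "stress_comparison"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  long <- trend_data(comparison)
  params <- unique(long$parameter)
  written <- character()
  for (p in setdiff(panel_parameters()$parameter, params)) {
    message("omitting plot for '", p, "': fewer than two computed values")
  }
  for (p in params) {
    d <- long[long$parameter == p, ]
    gp <- ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$value)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(title = d$label[1], x = "heart rate (bpm)", y = d$unit[1]) +
      ggplot2::theme_minimal(base_size = 10)
    f <- file.path(outdir, paste0(p, ".png"))
    ggplot2::ggsave(f, gp, width = width, height = height, dpi = 100)
    written <- c(written, f)
  }
  if (!is.null(comparison$ffr)) {
    s <- comparison$ffr$series
    gp <- ggplot2::ggplot(s, ggplot2::aes(x = .data$hr, y = .data$sp_esvi)) +
      ggplot2::geom_line(colour = "firebrick") +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_vline(xintercept = comparison$ffr$critical_heart_rate,
                          linetype = "dashed") +
      ggplot2::labs(
        title = paste0("Force-frequency relation (", comparison$ffr$shape, ")"),
        subtitle = paste0("critical heart rate ",
                          comparison$ffr$critical_heart_rate, " bpm"),
        x = "heart rate (bpm)", y = "SP/ESVi (mmHg/mL/m^2)"
      ) +
      ggplot2::theme_minimal(base_size = 10)
    f <- file.path(outdir, "force_frequency.png")
    ggplot2::ggsave(f, gp, width = width, height = height, dpi = 100)
    written <- c(written, f)
  }
  invisible(written)
}

trend_data <- function(comparison) {
  hr <- comparison$case$stages$heart_rate
  labels <- names(comparison$panels)
  long <- purrr::map_dfr(seq_along(comparison$panels), function(i) {
    p <- comparison$panels[[i]]
    tibble(stage = labels[i], hr = hr[i], parameter = p$parameter,
           label = p$label, unit = p$unit, value = p$value)
  })
  long <- long[!is.na(long$value), ]
  keep <- names(which(table(long$parameter) >= 2))
  long[long$parameter %in% keep, ]
}

#' Autoplot a stress comparison
#'
#' Faceted heart-rate trend plot over all computable panel parameters.
#'
#' @param object A [stress_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
autoplot.stress_comparison <- function(object, ...) {
  long <- trend_data(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hr, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "heart rate (bpm)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @export
plot.stress_comparison <- function(x, ...) print(autoplot.stress_comparison(x, ...))
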