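#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an adhesion-noise map as an electrical image
#'
#' @param object A `can_map`.
#' @param units `"uV2"` (default) or `"V2"` for the fill scale.
#' @param ... Unused.
#' @return A ggplot raster of the clamped adhesion noise.
#' @export
autoplot.can_map <- function(object, units = c("uV2", "V2"), ...) {
  units <- match.arg(units)
  d <- tidy(object, units = units)
  lab <- if (units == "uV2") expression(Delta * S[V] ~ "(" * mu * V^2 / Hz * ")")
         else expression(Delta * S[V] ~ (V^2 / Hz))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(ratio = object$spec$pitch_row / object$spec$pitch_col) +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "sensor column", y = "sensor row",
                  title = sprintf("Electrical image at %.0f kHz",
                                  object$analysis_freq / 1e3)) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation: mask with component contours
#'
#' @param object A `can_segmentation`.
#' @param ... Unused.
#' @return A ggplot of the cell mask with red component outlines.
#' @export
autoplot.can_segmentation <- function(object, ...) {
  d <- sensor_table(object$mask * 1, object$spec)
  ct <- purrr::imap(object$contours, function(m, i) {
    tibble::tibble(row = m[, "row"], col = m[, "col"], id = i)
  })
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey15", `1` = "grey85"),
                               name = "cell", labels = c("no", "yes")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(ratio = object$spec$pitch_row / object$spec$pitch_col) +
    ggplot2::labs(x = "sensor column", y = "sensor row",
                  title = sprintf("Segmented cells: %.1f%% covered",
                                  object$covered_area_pct)) +
    ggplot2::theme_minimal()
  if (length(ct))
    p <- p + ggplot2::geom_path(data = dplyr::bind_rows(ct),
                                ggplot2::aes(group = .data$id),
                                colour = "red", linewidth = 0.4)
  p
}

#' Covered-area (or adhesion-noise) time courses per chip
#'
#' Thin per-chip traces with a bold per-condition mean, the standard view
#' of a drug-response experiment.
#'
#' @param table Time-course tibble (from [analyze_experiment()] or
#'   assembled by hand) with `chip`, `condition`, `timepoint_h` and the
#'   response column.
#' @param response Column to plot (default `"covered_area_pct"`).
#' @return A ggplot.
#' @export
plot_timecourse <- function(table, response = "covered_area_pct") {
  stopifnot(all(c("chip", "condition", "timepoint_h", response)
                %in% names(table)))
  means <- table |>
    dplyr::group_by(.data$condition, .data$timepoint_h) |>
    dplyr::summarise(m = mean(.data[[response]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$timepoint_h,
                               y = .data[[response]],
                               colour = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$chip),
                       alpha = 0.35, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$m, group = .data$condition),
                       linewidth = 1.2) +
    ggplot2::labs(x = "time in culture (h)", y = response) +
    ggplot2::theme_minimal()
}
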