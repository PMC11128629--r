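#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an adhesion-noise map into a sensor table
#'
#' @param x A `can_map`.
#' @param units `"V2"` (SI, default) or `"uV2"` for the presentation unit.
#' @param ... Unused.
#' @return A tibble with 0-based `row`, `col`, clamped `value` and
#'   unclamped `raw_value` (V^2/Hz or uV^2/Hz).
#' @export
tidy.can_map <- function(x, units = c("V2", "uV2"), ...) {
  units <- match.arg(units)
  out <- sensor_table(x$values, x$spec)
  out$raw_value <- grid_to_sensor_vector(x$raw_values)
  if (units == "uV2") {
    out$value <- uV2_per_Hz(out$value)
    out$raw_value <- uV2_per_Hz(out$raw_value)
  }
  out
}

#' Tidy a segmentation into its component table
#'
#' @param x A `can_segmentation`.
#' @param ... Unused.
#' @return The per-component tibble (`label`, `n_sensors`, centroids).
#' @export
tidy.can_segmentation <- function(x, ...) x$components

#' One-row summary of a segmentation
#'
#' @param x A `can_segmentation`.
#' @param ... Unused.
#' @return A tibble with `n_components`, `covered_area_pct`,
#'   `threshold_gray`, `n_cell_sensors`.
#' @export
glance.can_segmentation <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$components),
                 covered_area_pct = x$covered_area_pct,
                 threshold_gray = x$threshold_gray,
                 n_cell_sensors = sum(x$mask))
}

#' Tidy a group-comparison test table
#'
#' @param x A `can_group_test`.
#' @param ... Unused.
#' @return The underlying tibble of comparisons.
#' @export
tidy.can_group_test <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a cell layout into its ground-truth cell table
#'
#' @param x A `cell_layout`.
#' @param ... Unused.
#' @return The per-cell tibble (centres, axes, cleft resistance).
#' @export
tidy.cell_layout <- function(x, ...) x$cells

#' One-row ground-truth summary of a layout
#'
#' @param x A `cell_layout`.
#' @param ... Unused.
#' @return A tibble with `n_cells`, `covered_area_pct`,
#'   `mean_r_j_ohm`.
#' @export
glance.cell_layout <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells),
                 covered_area_pct = covered_area_true(x),
                 mean_r_j_ohm = if (nrow(x$cells)) mean(x$cells$r_j_ohm)
                                else NA_real_)
}
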