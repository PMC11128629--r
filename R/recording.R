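#' Per-sensor noise recordings
#'
#' A `noise_recording` bundles the per-sensor payload of one acquisition on a
#' sensor array: either raw voltage time series or precomputed one-sided
#' power spectral densities (PSDs), together with the grid geometry and
#' acquisition metadata. Everything is stored in SI units: volts, V^2/Hz,
#' Hz, seconds, kelvin. The uV^2/Hz scale seen in figures is presentation
#' only (`1 uV^2/Hz == 1e-12 V^2/Hz`; see [uV2_per_Hz()]).
#'
#' @param spec A [sensor_array_spec()].
#' @param values Numeric matrix, one row per sensor in row-major sensor
#'   order: `n_sensors x n_samples` (timeseries, volts) or
#'   `n_sensors x n_freq` (psd, V^2/Hz).
#' @param kind `"timeseries"` or `"psd"`.
#' @param sampling_rate Sampling rate in Hz (timeseries only).
#' @param freq_grid Strictly increasing frequency grid in Hz (psd only).
#' @param meta Named list of metadata; recognised fields: `chip` (id),
#'   `timepoint_h` (hours), `condition` (e.g. `"untreated"`, `"treated"`,
#'   `"bare"`), `temperature_K`. A missing temperature defaults to 310.15 K
#'   (37 C incubation temperature).
#'
#' @details
#' Validation enforces: PSD values non-negative everywhere, `freq_grid`
#' strictly increasing and (for timeseries-derived PSDs) within
#' `[0, sampling_rate/2]`, and a sensor dimension equal to
#' `n_rows * n_cols`.
#'
#' @return An object of class `noise_recording`.
#' @seealso [calibration_recording()], [write_recording()], [welch_psd()].
#' @export
noise_recording <- function(spec, values, kind = c("psd", "timeseries"),
                            sampling_rate = NULL, freq_grid = NULL,
                            meta = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "sensor_array_spec"), is.matrix(values))
  if (nrow(values) != n_sensors(spec))
    stop(sprintf("`values` has %d rows but the array has %d sensors",
                 nrow(values), n_sensors(spec)), call. = FALSE)
  if (!is.list(meta)) stop("`meta` must be a list", call. = FALSE)
  if (is.null(meta$temperature_K)) meta$temperature_K <- 310.15
  if (meta$temperature_K <= 0) stop("temperature must be positive (K)", call. = FALSE)

  if (kind == "psd") {
    if (is.null(freq_grid)) stop("psd recordings need `freq_grid`", call. = FALSE)
    freq_grid <- as.numeric(freq_grid)
    if (length(freq_grid) != ncol(values))
      stop("`freq_grid` length must match ncol(values)", call. = FALSE)
    if (any(diff(freq_grid) <= 0))
      stop("`freq_grid` must be strictly increasing", call. = FALSE)
    if (any(freq_grid < 0)) stop("`freq_grid` must be non-negative", call. = FALSE)
    if (!is.null(sampling_rate) && any(freq_grid > sampling_rate / 2 + 1e-9))
      stop("`freq_grid` exceeds the Nyquist frequency", call. = FALSE)
    if (any(values < 0))
      stop("PSD values must be non-negative", call. = FALSE)
  } else {
    if (is.null(sampling_rate) || sampling_rate <= 0)
      stop("timeseries recordings need a positive `sampling_rate`", call. = FALSE)
  }

  structure(
    list(spec = spec, kind = kind, values = values,
         sampling_rate = sampling_rate,
         duration = if (kind == "timeseries") ncol(values) / sampling_rate else NULL,
         freq_grid = freq_grid, meta = meta),
    class = "noise_recording"
  )
}

#' Bare-sensor calibration recording
#'
#' A recording of the array exposed to electrolyte only (no cells), used to
#' characterise per-sensor background noise. Identical to [noise_recording()]
#' with `condition` forced to `"bare"`.
#'
#' @inheritParams noise_recording
#' @return A `noise_recording` whose `meta$condition` is `"bare"`.
#' @export
calibration_recording <- function(spec, values, kind = c("psd", "timeseries"),
                                  sampling_rate = NULL, freq_grid = NULL,
                                  meta = list()) {
  meta$condition <- "bare"
  noise_recording(spec, values, kind, sampling_rate, freq_grid, meta)
}

#' @export
print.noise_recording <- function(x, ...) {
  cat(sprintf("<noise_recording:%s> %d sensors", x$kind, nrow(x$values)))
  if (x$kind == "psd")
    cat(sprintf(", %d frequency bins (%.3g-%.3g Hz)\n",
                length(x$freq_grid), min(x$freq_grid), max(x$freq_grid)))
  else
    cat(sprintf(", %d samples at %.3g Hz (%.3g s)\n",
                ncol(x$values), x$sampling_rate, x$duration))
  cond <- x$meta$condition %||% "?"
  cat(sprintf("  chip=%s t=%s h condition=%s T=%.2f K\n",
              x$meta$chip %||% "?", x$meta$timepoint_h %||% "?",
              cond, x$meta$temperature_K))
  invisible(x)
}

#' Unit helpers for spectral power density
#'
#' Convert between the internal SI unit (V^2/Hz) and the presentation unit
#' uV^2/Hz used in figures and reports. `1 uV^2/Hz = 1e-12 V^2/Hz`.
#'
#' @param x Numeric values.
#' @return Converted numeric values.
#' @export
uV2_per_Hz <- function(x) x * 1e12

#' @rdname uV2_per_Hz
#' @export
V2_per_Hz <- function(x) x * 1e-12

#' Write / read the plain-text recording container
#'
#' The on-disk container for a recording is a directory of text files:
#' \describe{
#'   \item{`values.csv`}{the per-sensor payload matrix, one row per sensor in
#'     row-major sensor order, no header.}
#'   \item{`freq_grid.csv`}{(psd only) one frequency in Hz per line.}
#'   \item{`meta.json`}{kind, sampling rate/duration, the array spec and the
#'     metadata block.}
#' }
#'
#' @param rec A [noise_recording()].
#' @param path Directory to create/read.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the reconstructed `noise_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "noise_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as.data.frame(rec$values), file.path(path, "values.csv"),
                   col_names = FALSE, progress = FALSE)
  if (rec$kind == "psd")
    readr::write_csv(data.frame(f = rec$freq_grid),
                     file.path(path, "freq_grid.csv"),
                     col_names = FALSE, progress = FALSE)
  meta <- list(kind = rec$kind, sampling_rate = rec$sampling_rate,
               spec = unclass(rec$spec), meta = rec$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  spec <- sensor_array_spec(meta$spec$n_rows, meta$spec$n_cols,
                            meta$spec$pitch_row, meta$spec$pitch_col,
                            meta$spec$oxide)
  values <- as.matrix(readr::read_csv(file.path(path, "values.csv"),
                                      col_names = FALSE, progress = FALSE,
                                      show_col_types = FALSE))
  dimnames(values) <- NULL
  fg <- NULL
  if (identical(meta$kind, "psd"))
    fg <- readr::read_csv(file.path(path, "freq_grid.csv"), col_names = FALSE,
                          progress = FALSE, show_col_types = FALSE)[[1]]
  noise_recording(spec, values, meta$kind,
                  sampling_rate = meta$sampling_rate, freq_grid = fg,
                  meta = as.list(meta$meta))
}

#' Export a per-sensor scalar field as a (row, col, value) table
#'
#' @param values Per-sensor vector (row-major sensor order) or grid matrix.
#' @param spec A [sensor_array_spec()].
#' @return A tibble with 0-based `row`, `col` and `value` columns, one row
#'   per sensor.
#' @export
sensor_table <- function(values, spec) {
  stopifnot(inherits(spec, "sensor_array_spec"))
  if (is.matrix(values)) values <- grid_to_sensor_vector(values)
  stopifnot(length(values) == n_sensors(spec))
  idx <- seq_len(n_sensors(spec)) - 1L
  dplyr::bind_cols(sensor_index_to_grid(idx, spec),
                   tibble::tibble(value = as.numeric(values)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
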