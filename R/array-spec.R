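#' Sensor-array geometry
#'
#' Describes the rectangular grid of capacitive recording sites of a CMOS
#' microelectrode array: grid dimensions and the physical pitch between
#' neighbouring sites. All physical quantities are stored in the units given
#' below; micrometres are used for pitch because that is the natural scale of
#' the hardware.
#'
#' @param n_rows,n_cols Number of sensor rows / columns (positive integers).
#' @param pitch_row,pitch_col Centre-to-centre sensor spacing along the row
#'   (slow) and column (fast) axis, in micrometres.
#' @param oxide Free-text label of the top-oxide / coating, kept as metadata.
#'
#' @details
#' Sensors are addressed either by 0-based `(row, col)` grid coordinates or by
#' a 0-based row-major linear index `i = row * n_cols + col`; the two are a
#' bijection (see [sensor_index_to_grid()]). Row is the slow axis.
#'
#' @return An object of class `sensor_array_spec`: a list with fields
#'   `n_rows`, `n_cols`, `pitch_row`, `pitch_col`, `oxide`.
#' @seealso [canq_chip_spec()] for the high-density 256 x 384 array used
#'   throughout the examples, [array_extent()] for the physical active area.
#' @export
#' @examples
#' spec <- sensor_array_spec(4, 5, 6.5, 5.6)
#' n_sensors(spec)
sensor_array_spec <- function(n_rows, n_cols, pitch_row, pitch_col,
                              oxide = "TiO2") {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1,
            length(pitch_row) == 1, length(pitch_col) == 1)
  if (n_rows < 1 || n_cols < 1 || n_rows != floor(n_rows) || n_cols != floor(n_cols))
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  if (!is.finite(pitch_row) || !is.finite(pitch_col) ||
      pitch_row <= 0 || pitch_col <= 0)
    stop("sensor pitches must be positive", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pitch_row = as.numeric(pitch_row), pitch_col = as.numeric(pitch_col),
         oxide = as.character(oxide)),
    class = "sensor_array_spec"
  )
}

#' Default high-density array geometry
#'
#' The 256 x 384 capacitive sensor grid at 6.5 um x 5.6 um pitch (row x
#' column spacing) with an ALD-TiO2 top oxide -- the geometry of the
#' high-density CMOS MEA this package targets. 98,304 sensors in total.
#'
#' @return A [sensor_array_spec()].
#' @export
canq_chip_spec <- function() {
  sensor_array_spec(256L, 384L, 6.5, 5.6, oxide = "ALD-TiO2 30 nm")
}

#' @export
print.sensor_array_spec <- function(x, ...) {
  ext <- array_extent(x)
  cat(sprintf("<sensor_array_spec> %d x %d sensors (%s)\n",
              x$n_rows, x$n_cols, format(n_sensors(x), big.mark = ",")))
  cat(sprintf("  pitch %.2f um x %.2f um; extent %.4f mm x %.4f mm\n",
              x$pitch_row, x$pitch_col, ext[1] / 1e3, ext[2] / 1e3))
  cat(sprintf("  oxide: %s\n", x$oxide))
  invisible(x)
}

#' Number of sensors on an array
#' @param spec A [sensor_array_spec()].
#' @return Integer sensor count `n_rows * n_cols`.
#' @export
n_sensors <- function(spec) {
  stopifnot(inherits(spec, "sensor_array_spec"))
  spec$n_rows * spec$n_cols
}

#' Physical extent of the sensor array
#'
#' The exact extent `n * pitch` per axis, in micrometres. Data sheets round
#' this (the default chip is quoted as "1.6 mm x 2.5 mm"); the exact value is
#' stored and the rounded one is presentation only.
#'
#' @param spec A [sensor_array_spec()].
#' @return Named numeric vector `c(rows_um, cols_um)`.
#' @export
array_extent <- function(spec) {
  stopifnot(inherits(spec, "sensor_array_spec"))
  c(rows_um = spec$n_rows * spec$pitch_row,
    cols_um = spec$n_cols * spec$pitch_col)
}

#' Convert between linear sensor indices and grid coordinates
#'
#' Sensors are stored row-major with 0-based indices: sensor `i` sits at
#' `row = i %/% n_cols`, `col = i %% n_cols`. The two functions are exact
#' inverses.
#'
#' @param i 0-based linear sensor index (vectorized).
#' @param row,col 0-based grid coordinates (vectorized).
#' @param spec A [sensor_array_spec()].
#' @return `sensor_index_to_grid()`: a tibble with columns `row`, `col`;
#'   `grid_to_sensor_index()`: an integer vector of linear indices.
#' @export
#' @examples
#' spec <- sensor_array_spec(4, 5, 6, 6)
#' sensor_index_to_grid(5, spec)   # row 1, col 0
sensor_index_to_grid <- function(i, spec) {
  stopifnot(inherits(spec, "sensor_array_spec"))
  if (any(i < 0 | i >= n_sensors(spec) | i != floor(i)))
    stop("linear sensor index out of range", call. = FALSE)
  tibble::tibble(row = as.integer(i %/% spec$n_cols),
                 col = as.integer(i %% spec$n_cols))
}

#' @rdname sensor_index_to_grid
#' @export
grid_to_sensor_index <- function(row, col, spec) {
  stopifnot(inherits(spec, "sensor_array_spec"))
  if (any(row < 0 | row >= spec$n_rows | col < 0 | col >= spec$n_cols))
    stop("grid coordinates out of range", call. = FALSE)
  as.integer(row * spec$n_cols + col)
}

# Reshape a per-sensor vector (row-major order) into the grid matrix and back.
sensor_vector_to_grid <- function(v, spec) {
  matrix(v, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
}
grid_to_sensor_vector <- function(m) {
  as.vector(t(m))
}
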