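#' Background and adhesion-noise model parameters
#'
#' The per-sensor one-sided voltage-noise PSD is modelled as the sum of
#' three independent (hence additive) sources:
#'
#'   `S_V(f) = A_pink / f^alpha  +  S_white * (1 + eps_sensor)
#'           + 1{cell} * w * fraction * 4 k_B T R_J * B(f)`
#'
#' a 1/f^alpha setup-noise term that dominates below ~10 kHz, a white
#' background with fixed per-sensor relative offsets `eps_sensor`, and --
#' under a cell only -- the Johnson-Nyquist noise of the cleft resistance
#' `R_J`, flat over the plateau band and rolled off smoothly outside it
#' (`B(f)`, see [band_response()]). `w` is the sensor's coverage weight and
#' `fraction` the cell's adhesion-area fraction.
#'
#' @param A_pink Amplitude of the 1/f^alpha term in V^2 Hz^(alpha-1). The
#'   default puts the 1/f-to-white crossover at 10 kHz.
#' @param alpha 1/f exponent, in `[0.5, 2]` (default 1).
#' @param S_white White background level in V^2/Hz.
#' @param band_lo,band_hi Plateau band edges in Hz (defaults 100 and
#'   450 kHz).
#' @param temperature Kelvin (default 310.15, incubation temperature).
#' @param sensor_variability Relative SD of the background level across
#'   sensors: fixed device mismatch, a property of the chip that is
#'   reproduced between the bare calibration and the culture recording
#'   (which is what makes per-sensor background subtraction effective).
#' @param session_drift Relative SD of the per-sensor background drift
#'   between recording sessions -- the part of the background that
#'   calibration does not cancel.
#' @return An object of class `noise_model_params`.
#' @export
noise_model_params <- function(A_pink = 5e-11, alpha = 1,
                               S_white = 5e-15,
                               band_lo = 100e3, band_hi = 450e3,
                               temperature = 310.15,
                               sensor_variability = 0.5,
                               session_drift = 0.03) {
  stopifnot(A_pink >= 0, S_white >= 0, sensor_variability >= 0,
            session_drift >= 0,
            band_lo < band_hi, alpha >= 0.5, alpha <= 2, temperature > 0)
  structure(list(A_pink = A_pink, alpha = alpha, S_white = S_white,
                 band_lo = band_lo, band_hi = band_hi,
                 temperature = temperature,
                 sensor_variability = sensor_variability,
                 session_drift = session_drift),
            class = "noise_model_params")
}

#' Plateau band response
#'
#' The adhesion-noise plateau is flat (1) inside `[band_lo, band_hi]` and
#' rolls off as a raised cosine in log2-frequency, reaching 0 one octave
#' outside either edge. The measurement only constrains in-band flatness;
#' the roll-off shape is a modelling choice kept continuous so that
#' spectral estimates near the band edges are not distorted by
#' discontinuities.
#'
#' @param f Frequencies in Hz.
#' @param band_lo,band_hi Band edges in Hz.
#' @return Response in `[0, 1]`, vectorized over `f`.
#' @export
band_response <- function(f, band_lo = 100e3, band_hi = 450e3) {
  stopifnot(band_lo < band_hi, all(f > 0))
  b <- numeric(length(f))
  b[f >= band_lo & f <= band_hi] <- 1
  lo <- f < band_lo & f > band_lo / 2
  b[lo] <- 0.5 * (1 + cos(pi * log2(band_lo / f[lo])))
  hi <- f > band_hi & f < band_hi * 2
  b[hi] <- 0.5 * (1 + cos(pi * log2(f[hi] / band_hi)))
  b
}

#' Synthesize per-sensor PSDs for a cell layout
#'
#' Evaluates the noise model of [noise_model_params()] on a frequency grid
#' for every sensor of the layout. Because the sources are modelled as
#' uncorrelated, the cell term adds on top of the background: with
#' `n_averages = Inf` (noiseless), the in-band PSD at a cell sensor minus
#' the same sensor's bare PSD equals
#' `coverage * adhesion_fraction * 4 k_B T R_J` exactly.
#'
#' With finite `n_averages`, each bin is multiplied by an independent
#' `chi^2_{2K}/(2K)` factor, mimicking the sampling distribution of a
#' Welch estimate averaged over `K` segments.
#'
#' @param layout A [cell_layout()]; use an empty layout
#'   (`build_layout(spec, 0)`) for a bare calibration chip.
#' @param params A [noise_model_params()].
#' @param freq_grid Frequencies in Hz, strictly increasing, all > 0.
#' @param seed Integer seed for the session-specific noise (drift and
#'   estimation noise).
#' @param n_averages Effective number of Welch averages; `Inf` for a
#'   noiseless model evaluation. Default 487 (1 s at 1 MHz with 4096-sample
#'   segments and 50% overlap).
#' @param chip_seed Integer seed for the fixed per-sensor device mismatch;
#'   recordings of the same physical chip (culture and its bare
#'   calibration) must share it. Defaults to `seed`.
#' @return A [noise_recording()] of kind `"psd"`.
#' @export
synth_psd <- function(layout, params, freq_grid, seed = 1L,
                      n_averages = 487, chip_seed = seed) {
  stopifnot(inherits(layout, "cell_layout"),
            inherits(params, "noise_model_params"),
            all(freq_grid > 0), all(diff(freq_grid) > 0))
  spec <- layout$spec
  ns <- n_sensors(spec)
  nf <- length(freq_grid)

  base <- params$A_pink / freq_grid^params$alpha  # shared 1/f term
  B <- band_response(freq_grid, params$band_lo, params$band_hi)

  # per-sensor cell term: coverage * fraction * 4kT R_J (row-major order)
  lab_v <- grid_to_sensor_vector(layout$label_grid)
  cov_v <- grid_to_sensor_vector(layout$coverage)
  cell_amp <- numeric(ns)
  if (nrow(layout$cells) > 0) {
    m <- match(lab_v, layout$cells$label)
    hit <- !is.na(m)
    cell_amp[hit] <- cov_v[hit] * layout$cells$adhesion_fraction[m[hit]] *
      johnson_psd(layout$cells$r_j_ohm[m[hit]], params$temperature)
  }

  eps <- withr::with_seed(chip_seed,
    pmax(stats::rnorm(ns, 0, params$sensor_variability), -0.95))
  bg <- outer(1 + eps, base + params$S_white)  # device-mismatch background

  values <- withr::with_seed(seed, {
    drift <- stats::rnorm(ns, 0, params$session_drift)
    v <- bg * (1 + drift) + outer(cell_amp, B)
    if (is.finite(n_averages)) {
      k2 <- 2 * n_averages
      v <- v * matrix(stats::rchisq(ns * nf, df = k2) / k2, ns, nf)
    }
    pmax(v, 0)
  })

  noise_recording(spec, values, "psd", freq_grid = freq_grid,
                  meta = list(condition = if (nrow(layout$cells)) "culture" else "bare",
                              temperature_K = params$temperature))
}

#' Synthesize a voltage time series with a prescribed PSD
#'
#' Spectral shaping: a white complex-Gaussian spectrum is scaled by the
#' square root of the target one-sided PSD (interpolated onto the FFT bins,
#' clamped at the grid ends) and inverse-transformed. The expected Welch
#' PSD of the result converges to the target as the duration grows, and by
#' Parseval the sample variance approximates the integral of the target
#' PSD.
#'
#' @param psd_row Target one-sided PSD values (V^2/Hz) on `freq_grid`.
#' @param freq_grid Frequencies of `psd_row`, Hz, strictly increasing.
#' @param sampling_rate Hz; `sampling_rate / 2` must cover `freq_grid`.
#' @param duration Seconds; `duration * sampling_rate >= 2 * length(freq_grid)`.
#' @param seed Integer seed; the series is bit-reproducible.
#' @return Numeric voltage series of length `round(sampling_rate * duration)`.
#' @export
synth_timeseries <- function(psd_row, freq_grid, sampling_rate, duration,
                             seed = 1L) {
  stopifnot(length(psd_row) == length(freq_grid), all(psd_row >= 0),
            all(diff(freq_grid) > 0))
  if (sampling_rate / 2 < max(freq_grid))
    stop("Nyquist violation: sampling_rate/2 < max(freq_grid)", call. = FALSE)
  n <- round(sampling_rate * duration)
  if (n < 2 * length(freq_grid))
    stop("duration too short for the requested spectral resolution", call. = FALSE)

  f_bins <- (0:(n %/% 2)) * sampling_rate / n
  s <- stats::approx(freq_grid, psd_row, xout = f_bins, rule = 2)$y
  s[1] <- 0  # no DC power

  withr::with_seed(seed, {
    nh <- n %/% 2
    X <- complex(length.out = n)
    # bins 1 .. ceil(n/2)-1 paired with their conjugates
    kmax <- if (n %% 2 == 0) nh - 1 else nh
    amp <- sqrt(n * sampling_rate * s[2:(kmax + 1)] / 2)
    z <- complex(real = stats::rnorm(kmax), imaginary = stats::rnorm(kmax)) / sqrt(2)
    X[2:(kmax + 1)] <- amp * z
    X[n:(n - kmax + 1)] <- Conj(X[2:(kmax + 1)])
    if (n %% 2 == 0)  # real Nyquist bin
      X[nh + 1] <- sqrt(n * sampling_rate * s[nh + 1] / 2) * stats::rnorm(1)
    Re(stats::fft(X, inverse = TRUE)) / n
  })
}

#' Simulate one chip: matched culture and bare recordings
#'
#' Generates the culture PSD recording of a layout plus a bare calibration
#' recording of the same physical chip: both share the chip's fixed
#' per-sensor device mismatch (`chip_seed`) but have independent session
#' noise (background drift, estimation noise), as acquired in a separate
#' electrolyte-only session.
#'
#' @inheritParams synth_psd
#' @return A list with elements `culture` and `bare`, both
#'   [noise_recording()]s of kind `"psd"`.
#' @export
simulate_chip <- function(layout, params, freq_grid, seed = 1L,
                          n_averages = 487, chip_seed = seed) {
  bare_layout <- cell_layout(layout$spec,
                             matrix(0L, layout$spec$n_rows, layout$spec$n_cols),
                             empty_cells_table())
  list(culture = synth_psd(layout, params, freq_grid, seed = seed,
                           n_averages = n_averages, chip_seed = chip_seed),
       bare = synth_psd(bare_layout, params, freq_grid,
                        seed = seed + 10000L, n_averages = n_averages,
                        chip_seed = chip_seed))
}

#' Default analysis frequency grid
#'
#' 1-450 kHz in 2 kHz steps: the acquisition band, fine enough to resolve
#' the 100-450 kHz plateau and the 300 kHz analysis frequency.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_freq_grid <- function() seq(1e3, 450e3, by = 2e3)

#' Simulate a full multi-chip drug-response experiment
#'
#' For each chip of each condition, builds a random starting layout, evolves
#' it under the condition's dynamics preset (untreated: proliferation;
#' treated: detachment), and synthesizes matched culture + bare PSD
#' recordings at every timepoint. The result carries full ground truth for
#' benchmarking the analysis pipeline.
#'
#' @param spec A [sensor_array_spec()].
#' @param n_chips Chips per condition.
#' @param n_cells Starting cell clusters per chip. The default footprint
#'   scale (35 um) emulates the multi-cell clusters that adherent
#'   epithelial cultures form on the array; isolated single cells at
#'   ~15 um are near the resolution limit of the morphological cleanup.
#' @param params A [noise_model_params()].
#' @param timepoints Hours (default `c(0, 24, 48, 72)`).
#' @param freq_grid Frequencies in Hz.
#' @param diameter_dist,rj_dist Passed to [build_layout()].
#' @param seed Integer master seed.
#' @param n_averages Passed to [synth_psd()].
#' @return A tibble with one row per chip x condition x timepoint:
#'   `chip`, `condition`, `timepoint_h`, `true_area_pct`, `n_cells`, and
#'   list-columns `culture`, `bare` ([noise_recording()]s) and `layout`.
#' @export
simulate_experiment <- function(spec, n_chips = 4, n_cells = 30,
                                params = noise_model_params(),
                                timepoints = c(0, 24, 48, 72),
                                freq_grid = default_freq_grid(),
                                diameter_dist = c(35, 8),
                                rj_dist = c(1.58e6, 2e5),
                                seed = 1L, n_averages = 487) {
  rows <- list()
  for (cond in c("untreated", "treated")) {
    preset <- if (cond == "untreated") "proliferation" else "detachment"
    for (chip in seq_len(n_chips)) {
      s0 <- seed + 1000L * chip + 500000L * (cond == "treated")
      lay0 <- build_layout(spec, n_cells, diameter_dist, rj_dist, seed = s0)
      evo <- evolve_layout(lay0, scenario_preset(preset, timepoints,
                                                 seed = s0 + 1L))
      for (j in seq_along(timepoints)) {
        rec <- simulate_chip(evo$layouts[[j]], params, freq_grid,
                             seed = s0 + 10L * j, n_averages = n_averages)
        rows[[length(rows) + 1]] <- tibble::tibble(
          chip = sprintf("%s-%d", substr(cond, 1, 1), chip),
          condition = cond, timepoint_h = timepoints[j],
          true_area_pct = evo$truth$covered_area_pct[j],
          n_cells = evo$truth$n_cells[j],
          culture = list(rec$culture), bare = list(rec$bare),
          layout = list(evo$layouts[[j]]))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a simulation fixture to disk
#'
#' Emits the recording containers ([write_recording()]), the ground-truth
#' label grid as CSV, and a JSON manifest holding the parameters, seed, and
#' true covered area -- everything a downstream test needs to score the
#' pipeline against truth.
#'
#' @param layout A [cell_layout()].
#' @param params A [noise_model_params()].
#' @param path Output directory.
#' @param freq_grid,seed,n_averages Passed to [simulate_chip()].
#' @return `path`, invisibly.
#' @export
write_fixture <- function(layout, params, path,
                          freq_grid = default_freq_grid(), seed = 1L,
                          n_averages = 487) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rec <- simulate_chip(layout, params, freq_grid, seed, n_averages)
  write_recording(rec$culture, file.path(path, "culture"))
  write_recording(rec$bare, file.path(path, "bare"))
  readr::write_csv(as.data.frame(layout$label_grid),
                   file.path(path, "labels.csv"), col_names = FALSE,
                   progress = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_averages = n_averages,
         params = unclass(params),
         spec = unclass(layout$spec),
         true_covered_area_pct = covered_area_true(layout),
         n_cells = nrow(layout$cells)),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
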