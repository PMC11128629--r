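#' Synthetic cell layouts on a sensor array
#'
#' A `cell_layout` is the simulator's ground truth: an integer label per
#' sensor (0 = bare, k > 0 = cell/cluster id), the per-cell geometry and
#' cleft parameters, and a per-sensor coverage weight used for partial
#' sensors at cell boundaries.
#'
#' Physical coordinates: a sensor at grid position `(row, col)` (0-based) has
#' its centre at `x = (col + 0.5) * pitch_col`, `y = (row + 0.5) * pitch_row`
#' micrometres.
#'
#' @param spec A [sensor_array_spec()].
#' @param label_grid Integer matrix `n_rows x n_cols` of cell labels.
#' @param cells Tibble with one row per label: `label`, centre `cx_um`
#'   (column axis) / `cy_um` (row axis), semi-axes `ax_um`, `ay_um`,
#'   orientation `angle_rad`, cleft resistance `r_j_ohm`, and
#'   `adhesion_fraction` in (0, 1].
#' @param coverage Numeric matrix like `label_grid` with the fraction of each
#'   sensor's footprint under the cell (1 in the interior, < 1 at edges).
#' @return An object of class `cell_layout`.
#' @seealso [build_layout()], [evolve_layout()], [synth_psd()].
#' @export
cell_layout <- function(spec, label_grid, cells, coverage = NULL) {
  stopifnot(inherits(spec, "sensor_array_spec"),
            is.matrix(label_grid),
            all(dim(label_grid) == c(spec$n_rows, spec$n_cols)))
  if (any(label_grid < 0)) stop("labels must be non-negative", call. = FALSE)
  labs <- sort(unique(label_grid[label_grid > 0]))
  if (!all(labs %in% cells$label))
    stop("every nonzero label needs a row in `cells`", call. = FALSE)
  if (nrow(cells) > 0 &&
      any(cells$adhesion_fraction <= 0 | cells$adhesion_fraction > 1))
    stop("`adhesion_fraction` must lie in (0, 1]", call. = FALSE)
  if (is.null(coverage)) coverage <- (label_grid > 0) * 1.0
  stopifnot(all(dim(coverage) == dim(label_grid)))
  structure(list(spec = spec, label_grid = label_grid, cells = cells,
                 coverage = coverage),
            class = "cell_layout")
}

#' @export
print.cell_layout <- function(x, ...) {
  cat(sprintf("<cell_layout> %d cells on %d x %d grid; covered area %.1f%%\n",
              nrow(x$cells), x$spec$n_rows, x$spec$n_cols,
              covered_area_true(x)))
  invisible(x)
}

#' Ground-truth covered area of a layout
#'
#' `100 * (# sensors with nonzero label) / (# sensors)` -- the simulator
#' truth against which the imaging pipeline is benchmarked.
#'
#' @param layout A [cell_layout()].
#' @return Covered area in percent.
#' @export
covered_area_true <- function(layout) {
  stopifnot(inherits(layout, "cell_layout"))
  100 * sum(layout$label_grid > 0) / length(layout$label_grid)
}

empty_cells_table <- function() {
  tibble::tibble(label = integer(), cx_um = numeric(), cy_um = numeric(),
                 ax_um = numeric(), ay_um = numeric(), angle_rad = numeric(),
                 r_j_ohm = numeric(), adhesion_fraction = numeric())
}

# Rasterize one ellipse onto the grid. Returns list(idx = matrix-linear
# indices of sensors whose centre is inside, cover = coverage weight from a
# 3x3 subsample of each such sensor's footprint).
rasterize_ellipse <- function(spec, cx, cy, ax, ay, angle) {
  rmax <- max(ax, ay)
  rows <- seq(max(0, floor((cy - rmax) / spec$pitch_row - 1)),
              min(spec$n_rows - 1, ceiling((cy + rmax) / spec$pitch_row)))
  cols <- seq(max(0, floor((cx - rmax) / spec$pitch_col - 1)),
              min(spec$n_cols - 1, ceiling((cx + rmax) / spec$pitch_col)))
  if (!length(rows) || !length(cols))
    return(list(idx = integer(), cover = numeric()))
  g <- expand.grid(row = rows, col = cols)
  xc <- (g$col + 0.5) * spec$pitch_col
  yc <- (g$row + 0.5) * spec$pitch_row
  inside_fun <- function(x, y) {
    dx <- x - cx; dy <- y - cy
    u <- (dx * cos(angle) + dy * sin(angle)) / ax
    v <- (-dx * sin(angle) + dy * cos(angle)) / ay
    u * u + v * v <= 1
  }
  keep <- inside_fun(xc, yc)
  if (!any(keep)) return(list(idx = integer(), cover = numeric()))
  g <- g[keep, , drop = FALSE]
  # 3x3 subsample for boundary coverage weight
  offs <- (c(1, 3, 5) / 6) - 0.5
  cover <- rep(0, nrow(g))
  for (ox in offs) for (oy in offs) {
    cover <- cover + inside_fun((g$col + 0.5 + ox) * spec$pitch_col,
                                (g$row + 0.5 + oy) * spec$pitch_row)
  }
  list(idx = g$row + 1L + g$col * spec$n_rows,  # R matrix linear index
       cover = cover / 9)
}

#' Place random cells on a sensor array
#'
#' Draws `n_cells` non-overlapping elliptical cell footprints with axes from
#' `diameter_dist` and cleft resistances from `rj_dist`, rasterizes them onto
#' the sensor grid via the physical pitch, and returns the ground-truth
#' layout. A sensor is labelled when its centre falls inside the ellipse; a
#' 3x3 subsample of its footprint yields the boundary coverage weight.
#'
#' Overlap is tested on bounding circles (radius = major semi-axis); cells
#' are placed fully inside the array. Deterministic for a fixed `seed`.
#' By default footprints may not overlap; dense, cluster-forming cultures
#' can be emulated with `max_overlap > 0`, which admits centres down to
#' `(1 - max_overlap)` times the sum of bounding radii (a sensor then
#' keeps the label of the first cell that claimed it). Random sequential
#' placement of non-overlapping disks jams near 55% coverage, so layouts
#' denser than roughly half coverage require a positive `max_overlap`.
#'
#' @param spec A [sensor_array_spec()].
#' @param n_cells Number of cells to place (>= 0).
#' @param diameter_dist `c(mean, sd)` of cell diameters in micrometres;
#'   each ellipse axis is drawn independently. Presets: HT-29 cells are
#'   roughly 15 um, dermal fibroblasts roughly 40 um.
#' @param rj_dist `c(mean, sd)` of the per-cell cleft resistance in ohms.
#'   Default centres on 1.58 MOhm, the resistance of a typical adhesion
#'   cleft at incubation temperature.
#' @param seed Integer seed; the layout is a pure function of its arguments.
#' @param max_tries Placement attempts per cell before giving up.
#' @param max_overlap Allowed bounding-circle overlap fraction in `[0, 1)`;
#'   0 (default) enforces disjoint footprints.
#' @return A [cell_layout()].
#' @export
#' @examples
#' spec <- sensor_array_spec(20, 20, 6, 6)
#' lay <- build_layout(spec, 3, diameter_dist = c(24, 0), seed = 1)
#' covered_area_true(lay)
build_layout <- function(spec, n_cells,
                         diameter_dist = c(15, 2),
                         rj_dist = c(1.58e6, 2e5),
                         seed = 1L, max_tries = 200L,
                         max_overlap = 0) {
  stopifnot(inherits(spec, "sensor_array_spec"), n_cells >= 0,
            diameter_dist[1] > 0, rj_dist[1] > 0,
            max_overlap >= 0, max_overlap < 1)
  label_grid <- matrix(0L, spec$n_rows, spec$n_cols)
  coverage <- matrix(0, spec$n_rows, spec$n_cols)
  cells <- empty_cells_table()
  if (n_cells == 0)
    return(cell_layout(spec, label_grid, cells, coverage))

  ext_x <- spec$n_cols * spec$pitch_col
  ext_y <- spec$n_rows * spec$pitch_row

  withr::with_seed(seed, {
    placed <- 0L
    while (placed < n_cells) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ax <- max(1, stats::rnorm(1, diameter_dist[1], diameter_dist[2])) / 2
        ay <- max(1, stats::rnorm(1, diameter_dist[1], diameter_dist[2])) / 2
        ang <- stats::runif(1, 0, pi)
        rb <- max(ax, ay)
        if (2 * rb > min(ext_x, ext_y)) next
        cx <- stats::runif(1, rb, ext_x - rb)
        cy <- stats::runif(1, rb, ext_y - rb)
        if (nrow(cells) > 0) {
          d2 <- (cells$cx_um - cx)^2 + (cells$cy_um - cy)^2
          rsum <- (pmax(cells$ax_um, cells$ay_um) + rb) * (1 - max_overlap)
          if (any(d2 < rsum^2)) next
        }
        ras <- rasterize_ellipse(spec, cx, cy, ax, ay, ang)
        free <- ras$idx[label_grid[ras$idx] == 0L]  # first claim wins
        if (!length(free)) next
        placed <- placed + 1L
        label_grid[free] <- placed
        coverage[free] <- ras$cover[match(free, ras$idx)]
        cells <- dplyr::bind_rows(cells, tibble::tibble(
          label = placed, cx_um = cx, cy_um = cy, ax_um = ax, ay_um = ay,
          angle_rad = ang,
          r_j_ohm = max(1e3, stats::rnorm(1, rj_dist[1], rj_dist[2])),
          adhesion_fraction = 1.0))
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(paste0("could not place cell %d of %d after %d tries: ",
                            "grid occupancy too high (%.1f%% covered)"),
                     placed + 1L, n_cells, max_tries,
                     100 * sum(label_grid > 0) / length(label_grid)),
             call. = FALSE)
    }
  })
  cell_layout(spec, label_grid, cells, coverage)
}

#' Culture dynamics scenarios
#'
#' Describes how a layout evolves over the recording schedule:
#' `"proliferation"` adds daughter footprints adjacent to existing cells at
#' an exponential per-hour rate, `"detachment"` removes each cell with a
#' per-hour hazard, `"static"` leaves the layout unchanged.
#'
#' @param kind One of `"proliferation"`, `"detachment"`, `"static"`.
#' @param rate Per-hour rate parameter (>= 0). For proliferation the target
#'   covered area grows as `exp(rate * t)`; for detachment each cell
#'   survives an interval `dt` with probability `exp(-rate * dt)`.
#' @param timepoints Recording schedule in hours, ascending
#'   (default `c(0, 24, 48, 72)`).
#' @param seed Integer seed for the stochastic placement/removal decisions.
#' @return An object of class `dynamics_scenario`.
#' @seealso [scenario_preset()] for the calibrated presets.
#' @export
dynamics_scenario <- function(kind = c("static", "proliferation", "detachment"),
                              rate = 0, timepoints = c(0, 24, 48, 72),
                              seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(rate >= 0, length(timepoints) >= 1, all(diff(timepoints) > 0))
  structure(list(kind = kind, rate = rate, timepoints = timepoints,
                 seed = as.integer(seed)),
            class = "dynamics_scenario")
}

#' Calibrated dynamics presets
#'
#' `"proliferation"` doubles the covered area by 72 h
#' (`rate = log(2)/72` per hour), matching the growth of an untreated
#' adherent culture; `"detachment"` shrinks it 1.8-fold by 72 h
#' (`rate = log(1.8)/72`), matching cytotoxic-drug-induced detachment.
#' Both are exact on the expected trajectory; the per-cell realisation is
#' stochastic in the seed.
#'
#' @param kind `"proliferation"` or `"detachment"`.
#' @inheritParams dynamics_scenario
#' @return A [dynamics_scenario()].
#' @export
scenario_preset <- function(kind = c("proliferation", "detachment"),
                            timepoints = c(0, 24, 48, 72), seed = 1L) {
  kind <- match.arg(kind)
  rate <- if (kind == "proliferation") log(2) / 72 else log(1.8) / 72
  dynamics_scenario(kind, rate, timepoints, seed)
}

#' Evolve a layout over a recording schedule
#'
#' Applies a [dynamics_scenario()] to a starting layout and returns one
#' layout per timepoint plus the ground-truth area trajectory. Detachment
#' only removes cells (labels are conserved), proliferation only adds; the
#' true area trajectory is therefore monotone for either kind.
#'
#' @param layout A [cell_layout()] (state at the first timepoint).
#' @param scenario A [dynamics_scenario()].
#' @return A list with `layouts` (list of `cell_layout`, one per timepoint)
#'   and `truth`, a tibble with `timepoint_h`, `covered_area_pct`, `n_cells`.
#' @export
evolve_layout <- function(layout, scenario) {
  stopifnot(inherits(layout, "cell_layout"),
            inherits(scenario, "dynamics_scenario"))
  tp <- scenario$timepoints
  layouts <- vector("list", length(tp))
  layouts[[1]] <- layout

  withr::with_seed(scenario$seed, {
    if (scenario$kind == "static" || length(tp) == 1) {
      for (j in seq_along(tp)[-1]) layouts[[j]] <- layout
    } else if (scenario$kind == "detachment") {
      cur <- layout
      for (j in seq_along(tp)[-1]) {
        dt <- tp[j] - tp[j - 1]
        if (nrow(cur$cells) > 0) {
          keep <- stats::runif(nrow(cur$cells)) < exp(-scenario$rate * dt)
          drop_labels <- cur$cells$label[!keep]
          lg <- cur$label_grid; cov <- cur$coverage
          rm_idx <- lg %in% drop_labels
          lg[rm_idx] <- 0L; cov[rm_idx] <- 0
          cur <- cell_layout(cur$spec, lg, cur$cells[keep, , drop = FALSE], cov)
        }
        layouts[[j]] <- cur
      }
    } else { # proliferation
      cur <- layout
      n0 <- sum(layout$label_grid > 0)
      next_label <- if (nrow(layout$cells)) max(layout$cells$label) else 0L
      for (j in seq_along(tp)[-1]) {
        target <- round(n0 * exp(scenario$rate * (tp[j] - tp[1])))
        attempts <- 0L
        while (sum(cur$label_grid > 0) < target && attempts < 5000L &&
               nrow(cur$cells) > 0) {
          attempts <- attempts + 1L
          parent <- cur$cells[sample.int(nrow(cur$cells), 1), ]
          ang <- stats::runif(1, 0, 2 * pi)
          rb_new <- max(parent$ax_um, parent$ay_um)
          dist <- (max(parent$ax_um, parent$ay_um) + rb_new) *
            stats::runif(1, 1.0, 1.15)
          cx <- parent$cx_um + dist * cos(ang)
          cy <- parent$cy_um + dist * sin(ang)
          ext_x <- cur$spec$n_cols * cur$spec$pitch_col
          ext_y <- cur$spec$n_rows * cur$spec$pitch_row
          if (cx < rb_new || cx > ext_x - rb_new ||
              cy < rb_new || cy > ext_y - rb_new) next
          d2 <- (cur$cells$cx_um - cx)^2 + (cur$cells$cy_um - cy)^2
          rsum <- pmax(cur$cells$ax_um, cur$cells$ay_um) + rb_new
          if (any(d2 < (0.95 * rsum)^2)) next
          ras <- rasterize_ellipse(cur$spec, cx, cy, parent$ax_um,
                                   parent$ay_um, parent$angle_rad)
          free <- ras$idx[cur$label_grid[ras$idx] == 0L]
          if (!length(free)) next
          next_label <- next_label + 1L
          lg <- cur$label_grid; cov <- cur$coverage
          lg[free] <- next_label
          cov[free] <- ras$cover[match(free, ras$idx)]
          cur <- cell_layout(cur$spec, lg, dplyr::bind_rows(
            cur$cells,
            tibble::tibble(label = next_label, cx_um = cx, cy_um = cy,
                           ax_um = parent$ax_um, ay_um = parent$ay_um,
                           angle_rad = parent$angle_rad,
                           r_j_ohm = parent$r_j_ohm,
                           adhesion_fraction = parent$adhesion_fraction)), cov)
        }
        layouts[[j]] <- cur
      }
    }
  })

  truth <- tibble::tibble(
    timepoint_h = tp,
    covered_area_pct = vapply(layouts, covered_area_true, numeric(1)),
    n_cells = vapply(layouts, function(l) nrow(l$cells), integer(1)))
  list(layouts = layouts, truth = truth)
}
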