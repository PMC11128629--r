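#' Mean adhesion noise over cell-detecting sensors
#'
#' Arithmetic mean of the raw (unclamped) adhesion noise over the sensors
#' of a detection mask -- the per-chip summary statistic reported in drug
#' time courses. Raw values are used deliberately: clamping negative bins
#' would bias the mean upward.
#'
#' @param map A `can_map` from [extract_map()].
#' @param mask Logical matrix of cell-detecting sensors (e.g.
#'   `segment_cells(map)$mask`).
#' @return Mean adhesion noise in V^2/Hz.
#' @export
mean_dsv_over_cells <- function(map, mask) {
  stopifnot(inherits(map, "can_map"), is.matrix(mask), is.logical(mask),
            all(dim(mask) == dim(map$raw_values)))
  if (!any(mask))
    stop("empty mask: the mean adhesion noise over zero sensors is undefined",
         call. = FALSE)
  mean(map$raw_values[mask])
}

#' Cell viability from optical densities
#'
#' The colorimetric companion arithmetic:
#' `viability (%) = (sample - blank) / (control - blank) * 100`.
#' Values above 100% are legitimate (samples outgrowing the control) and
#' are not truncated. Adding a common offset to all three readings leaves
#' the result unchanged.
#'
#' @param sample,blank,control Absorbance readings (OD at 450 nm).
#'   Vectorized; `control` must differ from `blank`.
#' @return Viability in percent.
#' @export
#' @examples
#' viability_from_od(0.63, 0.10, 0.96)  # 61.6%
viability_from_od <- function(sample, blank, control) {
  if (any(control == blank))
    stop("`control` equals `blank`: viability is undefined", call. = FALSE)
  (sample - blank) / (control - blank) * 100
}

#' Fold change of covered area between two timepoints
#'
#' Reports the ratio always as a value >= 1 with an explicit direction:
#' an increase is `t1/t0` (`"increase"`), a decline is `t0/t1`
#' (`"decline"`), equality gives 1 (`"flat"`). The direction label
#' disambiguates the common "x-fold" phrasing that is used for both senses.
#'
#' @param area_t1 Later value (e.g. covered area % at 72 h).
#' @param area_t0 Baseline value; must be > 0.
#' @return A tibble with columns `fold` and `direction`. Vectorized.
#' @export
#' @examples
#' fold_change(54, 27)  # 2-fold increase
#' fold_change(22, 40)  # 1.8-fold decline
fold_change <- function(area_t1, area_t0) {
  if (any(area_t0 <= 0))
    stop("zero or negative baseline: fold change undefined", call. = FALSE)
  if (any(area_t1 < 0))
    stop("negative `area_t1`", call. = FALSE)
  tibble::tibble(
    fold = ifelse(area_t1 >= area_t0, area_t1 / area_t0, area_t0 / area_t1),
    direction = dplyr::case_when(area_t1 > area_t0 ~ "increase",
                                 area_t1 < area_t0 ~ "decline",
                                 TRUE ~ "flat"))
}

#' Significance stars
#'
#' The four-level annotation used throughout the reports: `ns` (p > 0.05),
#' `*` (p <= 0.05), `**` (p <= 0.01), `***` (p <= 0.001), `****`
#' (p <= 0.0001). No multiple-testing correction is applied.
#'
#' @param p P-values (vectorized).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p <= 1e-4 ~ "****",
                   p <= 1e-3 ~ "***",
                   p <= 1e-2 ~ "**",
                   p <= 5e-2 ~ "*",
                   TRUE ~ "ns")
}

#' Summarise one chip recording into a time-course record
#'
#' Runs background subtraction, map extraction and segmentation on one
#' culture/bare recording pair and returns the per-chip-per-timepoint
#' record: covered area, mean adhesion noise over cell sensors, sensor
#' count.
#'
#' @param culture,bare Matched [noise_recording()]s of kind `"psd"`.
#' @param chip,condition,timepoint_h Metadata for the record (defaults
#'   taken from `culture$meta` when present).
#' @param analysis_freq Hz (default 300 kHz).
#' @param ... Passed to [segment_cells()].
#' @return A one-row tibble with `chip`, `condition`, `timepoint_h`,
#'   `covered_area_pct`, `mean_delta_sv` (V^2/Hz, `NA` when no sensor
#'   detects a cell), `n_cell_sensors`.
#' @export
chip_record <- function(culture, bare, chip = NULL, condition = NULL,
                        timepoint_h = NULL, analysis_freq = 300e3, ...) {
  map <- extract_map(subtract_background(culture, bare), analysis_freq)
  seg <- segment_cells(map, ...)
  tibble::tibble(
    chip = chip %||% culture$meta$chip %||% NA_character_,
    condition = condition %||% culture$meta$condition %||% NA_character_,
    timepoint_h = timepoint_h %||% culture$meta$timepoint_h %||% NA_real_,
    covered_area_pct = seg$covered_area_pct,
    mean_delta_sv = if (any(seg$mask)) mean_dsv_over_cells(map, seg$mask)
                    else NA_real_,
    n_cell_sensors = sum(seg$mask))
}

#' Analyse a simulated (or assembled) experiment into a time-course table
#'
#' Applies [chip_record()] to every row of an experiment tibble as produced
#' by [simulate_experiment()] (columns `chip`, `condition`, `timepoint_h`
#' and list-columns `culture`, `bare`).
#'
#' @param experiment Experiment tibble.
#' @param ... Passed to [chip_record()].
#' @return A time-course tibble, one record per chip x timepoint, with any
#'   `true_area_pct` column carried through. At most one record per
#'   (chip, timepoint) is enforced.
#' @export
analyze_experiment <- function(experiment, ...) {
  stopifnot(all(c("chip", "condition", "timepoint_h", "culture", "bare")
                %in% names(experiment)))
  out <- purrr::pmap(
    list(experiment$culture, experiment$bare, experiment$chip,
         experiment$condition, experiment$timepoint_h),
    function(cu, ba, ch, co, tp, ...) chip_record(cu, ba, ch, co, tp, ...),
    ...)
  out <- dplyr::bind_rows(out)
  if ("true_area_pct" %in% names(experiment))
    out$true_area_pct <- experiment$true_area_pct
  if (anyDuplicated(out[c("chip", "timepoint_h")]))
    stop("duplicate (chip, timepoint) records", call. = FALSE)
  out
}

#' Group-comparison statistics for a time-course table
#'
#' Standard reporting statistics over a time-course table (one record per
#' chip and timepoint with a `condition` label):
#' \describe{
#'   \item{`"two_group_t"`}{unpaired two-sample t-test between conditions at
#'     each timepoint.}
#'   \item{`"one_way_time"`}{one-way ANOVA of the response across
#'     timepoints, within each condition.}
#'   \item{`"two_way"`}{two-way fixed-effects ANOVA with condition, time and
#'     their interaction.}
#' }
#' This is reporting plumbing around [stats::t.test()] / [stats::aov()],
#' annotated with the four-level star scheme; no multiple-testing
#' correction is applied.
#'
#' @param table Time-course tibble (e.g. from [analyze_experiment()]).
#' @param design One of `"two_group_t"`, `"one_way_time"`, `"two_way"`.
#' @param response Name of the response column (default
#'   `"covered_area_pct"`).
#' @return An object of class `can_group_test`; its [generics::tidy()]
#'   method (also the object itself, printed) is a tibble with `design`,
#'   `comparison`, `n`, `statistic`, `df`, `p.value`, `stars`. Comparisons
#'   with fewer than 2 records per group get `NA` and a warning.
#' @export
group_compare <- function(table,
                          design = c("two_group_t", "one_way_time", "two_way"),
                          response = "covered_area_pct") {
  design <- match.arg(design)
  stopifnot(is.data.frame(table),
            all(c("condition", "timepoint_h", response) %in% names(table)))
  y <- table[[response]]
  res <- list()

  if (design == "two_group_t") {
    for (tp in sort(unique(table$timepoint_h))) {
      sel <- table$timepoint_h == tp & !is.na(y)
      groups <- split(y[sel], table$condition[sel])
      cmp <- sprintf("%s at %g h", paste(names(groups), collapse = " vs "), tp)
      if (length(groups) != 2 || any(lengths(groups) < 2)) {
        warning(sprintf("insufficient replication for '%s'", cmp), call. = FALSE)
        res[[length(res) + 1]] <- tibble::tibble(
          design = design, comparison = cmp, n = sum(sel),
          statistic = NA_real_, df = NA_real_, p.value = NA_real_)
        next
      }
      # degenerate zero-variance limit: t.test errors on constant data
      if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
        p <- if (isTRUE(all.equal(mean(groups[[1]]), mean(groups[[2]])))) 1 else 0
        res[[length(res) + 1]] <- tibble::tibble(
          design = design, comparison = cmp, n = sum(sel),
          statistic = if (p == 1) 0 else Inf,
          df = sum(lengths(groups)) - 2, p.value = p)
        next
      }
      tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      res[[length(res) + 1]] <- tibble::tibble(
        design = design, comparison = cmp, n = sum(sel),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p.value = tt$p.value)
    }
  } else if (design == "one_way_time") {
    for (cond in sort(unique(table$condition))) {
      sel <- table$condition == cond & !is.na(y)
      cmp <- sprintf("time effect (%s)", cond)
      counts <- table(table$timepoint_h[sel])
      if (length(counts) < 2 || any(counts < 2)) {
        warning(sprintf("insufficient replication for '%s'", cmp), call. = FALSE)
        res[[length(res) + 1]] <- tibble::tibble(
          design = design, comparison = cmp, n = sum(sel),
          statistic = NA_real_, df = NA_real_, p.value = NA_real_)
        next
      }
      d <- data.frame(y = y[sel], t = factor(table$timepoint_h[sel]))
      a <- summary(stats::aov(y ~ t, data = d))[[1]]
      res[[length(res) + 1]] <- tibble::tibble(
        design = design, comparison = cmp, n = sum(sel),
        statistic = a$`F value`[1], df = a$Df[1], p.value = a$`Pr(>F)`[1])
    }
  } else { # two_way
    sel <- !is.na(y)
    d <- data.frame(y = y[sel], cond = factor(table$condition[sel]),
                    t = factor(table$timepoint_h[sel]))
    if (nlevels(d$cond) < 2 || nlevels(d$t) < 2 ||
        any(table(d$cond, d$t) < 2)) {
      warning("insufficient replication for the two-way design", call. = FALSE)
      res[[1]] <- tibble::tibble(design = design,
                                 comparison = c("condition", "time",
                                                "condition:time"),
                                 n = sum(sel), statistic = NA_real_,
                                 df = NA_real_, p.value = NA_real_)
    } else {
      a <- summary(stats::aov(y ~ cond * t, data = d))[[1]]
      terms <- trimws(rownames(a))[seq_len(3)]
      terms <- sub("^cond:t$", "condition:time", terms)
      terms <- sub("^cond$", "condition", terms)
      terms <- sub("^t$", "time", terms)
      res[[1]] <- tibble::tibble(design = design, comparison = terms,
                                 n = sum(sel),
                                 statistic = a$`F value`[seq_len(3)],
                                 df = a$Df[seq_len(3)],
                                 p.value = a$`Pr(>F)`[seq_len(3)])
    }
  }

  out <- dplyr::bind_rows(res)
  out$stars <- significance_stars(out$p.value)
  structure(out, class = c("can_group_test", class(out)))
}

#' @export
print.can_group_test <- function(x, ...) {
  cat("<can_group_test>\n")
  NextMethod()
}
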