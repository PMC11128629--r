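test_that("mean adhesion noise over a mask uses raw values", {
  v <- matrix(2.2e-14, 6, 6)
  m <- map_from_matrix(v)
  mask <- matrix(FALSE, 6, 6); mask[2:4, 2:4] <- TRUE
  expect_equal(mean_dsv_over_cells(m, mask), 2.2e-14)

  two <- matrix(0, 6, 6); two[1, 1] <- V2_per_Hz(0.01); two[1, 2] <- V2_per_Hz(0.03)
  mk <- matrix(FALSE, 6, 6); mk[1, 1:2] <- TRUE
  expect_equal(uV2_per_Hz(mean_dsv_over_cells(map_from_matrix(two), mk)), 0.02)

  # negative raw bins pull the mean down (no clamping)
  neg <- two; neg[1, 2] <- -V2_per_Hz(0.01)
  expect_equal(mean_dsv_over_cells(map_from_matrix(neg), mk), 0)

  # bounded by the masked extrema, invariant to mask traversal
  withr::with_seed(91, {
    vv <- matrix(rnorm(36, 1e-14, 5e-15), 6)
    mm <- rand_mask(6, 6, 0.5, seed = 7)
    mu <- mean_dsv_over_cells(map_from_matrix(vv), mm)
    expect_gte(mu, min(vv[mm])); expect_lte(mu, max(vv[mm]))
  })

  expect_error(mean_dsv_over_cells(m, matrix(FALSE, 6, 6)), "empty mask")
})

test_that("simulated clefts at 1.58 MOhm average to the 0.027 plateau", {
  spec <- sensor_array_spec(64, 96, 6.5, 5.6)
  lay <- build_layout(spec, 20, diameter_dist = c(40, 5),
                      rj_dist = c(1.58e6, 0), seed = 92, max_overlap = 0.1)
  rec <- simulate_chip(lay, noise_model_params(), default_freq_grid(),
                       seed = 93)
  map <- extract_map(subtract_background(rec$culture, rec$bare))
  seg <- segment_cells(map)
  # over fully covered sensors the mean recovers 4 k_B T R_J
  full <- seg$mask & lay$coverage == 1
  expect_equal(uV2_per_Hz(mean_dsv_over_cells(map, full)), 0.027,
               tolerance = 0.02)
  # the all-sensor mask mean sits below the plateau (partial coverage)
  expect_lt(mean_dsv_over_cells(map, seg$mask), johnson_psd(1.58e6))
})

test_that("viability arithmetic matches the OD formula", {
  expect_equal(viability_from_od(0.96, 0.10, 0.96), 100)
  expect_equal(viability_from_od(0.10, 0.10, 0.96), 0)
  expect_equal(viability_from_od(0.63, 0.10, 0.96), 61.6, tolerance = 1e-3)
  # proliferating samples may exceed 100%
  expect_gt(viability_from_od(1.63, 0.10, 0.96), 100)
  # common offsets cancel
  expect_equal(viability_from_od(0.63 + 0.2, 0.10 + 0.2, 0.96 + 0.2),
               viability_from_od(0.63, 0.10, 0.96))
  expect_error(viability_from_od(0.5, 0.3, 0.3), "undefined")
})

test_that("fold changes carry magnitude and direction", {
  expect_equal(fold_change(54, 54), tibble::tibble(fold = 1, direction = "flat"))
  expect_equal(fold_change(54, 27)$fold, 2)
  expect_equal(fold_change(54, 27)$direction, "increase")
  d <- fold_change(22, 40)
  expect_equal(d$fold, 40 / 22, tolerance = 1e-12)  # ~1.8-fold decline
  expect_equal(round(d$fold, 1), 1.8)
  expect_equal(d$direction, "decline")
  # reciprocity of the magnitude
  expect_equal(fold_change(22, 40)$fold * 1 / fold_change(40, 22)$fold, 1)
  expect_error(fold_change(10, 0), "baseline")
})

test_that("star annotation follows the four-level scheme", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.01, 0.001, 0.0001, 2e-6)),
               c("ns", "*", "**", "***", "****", "****"))
  expect_true(is.na(significance_stars(NA)))
})

test_that("group comparisons handle degenerate and regular designs", {
  tc <- tibble::tibble(
    chip = rep(sprintf("c%d", 1:8), 2),
    condition = rep(rep(c("untreated", "treated"), each = 4), 2),
    timepoint_h = rep(c(0, 72), each = 8),
    covered_area_pct = c(rep(30, 8), rep(30, 4), rep(30, 4)))

  # identical groups -> ns with p = 1 (zero-variance limit)
  g0 <- group_compare(tc, "two_group_t")
  expect_equal(g0$p.value, c(1, 1))
  expect_equal(g0$stars, c("ns", "ns"))

  # zero within-group variance, different means -> beyond all thresholds
  tc2 <- tc
  tc2$covered_area_pct[tc2$condition == "treated" & tc2$timepoint_h == 72] <- 10
  g2 <- group_compare(tc2, "two_group_t")
  expect_equal(g2$stars[g2$comparison == "treated vs untreated at 72 h"], "****")

  # closed-form check: n = 4 per group, pooled-SD effect of 3
  withr::with_seed(94, {
    y1 <- rnorm(4, 0, 1); y2 <- rnorm(4, 0, 1)
    y1 <- (y1 - mean(y1)) / sd(y1); y2 <- (y2 - mean(y2)) / sd(y2) + 3
  })
  tc3 <- tibble::tibble(chip = sprintf("c%d", 1:8),
                        condition = rep(c("a", "b"), each = 4),
                        timepoint_h = 0, covered_area_pct = c(y1, y2))
  g3 <- group_compare(tc3, "two_group_t")
  tt <- stats::t.test(y1, y2)  # same call path, fixed data: frozen oracle
  expect_equal(g3$p.value, tt$p.value)
  expect_equal(g3$statistic, unname(tt$statistic))
  expect_equal(g3$stars, significance_stars(tt$p.value))

  # insufficient replication -> NA with warning
  expect_warning(g4 <- group_compare(tc3[c(1, 5), ], "two_group_t"),
                 "insufficient")
  expect_true(is.na(g4$p.value))
})

test_that("one-way and two-way ANOVA tables match stats::aov", {
  withr::with_seed(95, {
    tc <- tidyr::expand_grid(chip = sprintf("c%d", 1:4),
                             condition = c("untreated", "treated"),
                             timepoint_h = c(0, 24, 48, 72))
    tc$covered_area_pct <- 30 +
      5 * (tc$condition == "untreated") * tc$timepoint_h / 24 -
      3 * (tc$condition == "treated") * tc$timepoint_h / 24 +
      rnorm(nrow(tc), 0, 2)
  })

  g1 <- group_compare(tc, "one_way_time")
  expect_equal(nrow(g1), 2)
  a <- summary(stats::aov(covered_area_pct ~ factor(timepoint_h),
                          data = tc[tc$condition == "treated", ]))[[1]]
  expect_equal(g1$p.value[g1$comparison == "time effect (treated)"],
               a$`Pr(>F)`[1])

  g2 <- group_compare(tc, "two_way")
  expect_equal(g2$comparison, c("condition", "time", "condition:time"))
  aa <- summary(stats::aov(covered_area_pct ~ condition * factor(timepoint_h),
                           data = tc))[[1]]
  expect_equal(g2$p.value, aa$`Pr(>F)`[1:3])
  expect_s3_class(tidy(g2), "tbl_df")
})

test_that("chip records and experiment analysis produce tidy tables", {
  spec <- sensor_array_spec(48, 64, 6.5, 5.6)
  ex <- simulate_experiment(spec, n_chips = 2, n_cells = 12,
                            timepoints = c(0, 72), seed = 96)
  tc <- analyze_experiment(ex)
  expect_equal(nrow(tc), 8)
  expect_true(all(c("chip", "condition", "timepoint_h", "covered_area_pct",
                    "mean_delta_sv", "n_cell_sensors", "true_area_pct")
                  %in% names(tc)))
  expect_false(anyDuplicated(tc[c("chip", "timepoint_h")]) > 0)
  expect_true(all(tc$covered_area_pct >= 0 & tc$covered_area_pct <= 100))
  # pipeline tracks truth on every record
  expect_true(all(abs(tc$covered_area_pct - tc$true_area_pct) < 3))
  # qualitative drug pattern: untreated grows, treated shrinks
  wide <- tidyr::pivot_wider(tc[c("chip", "condition", "timepoint_h",
                                  "covered_area_pct")],
                             names_from = timepoint_h,
                             values_from = covered_area_pct)
  expect_true(all(wide$`72`[wide$condition == "untreated"] >
                    wide$`0`[wide$condition == "untreated"]))
  expect_true(all(wide$`72`[wide$condition == "treated"] <
                    wide$`0`[wide$condition == "treated"]))

  # duplicated records are rejected
  expect_error(analyze_experiment(dplyr::bind_rows(ex[1, ], ex[1, ])),
               "duplicate")
})

test_that("tidiers expose maps, segmentations and layouts as tibbles", {
  v <- matrix(0, 5, 5); v[2:3, 2:3] <- 2.7e-14
  m <- map_from_matrix(v)
  td <- tidy(m, units = "uV2")
  expect_equal(max(td$value), 0.027)
  expect_equal(nrow(td), 25)

  seg <- segment_cells(map_from_matrix(kronecker(v, matrix(1, 3, 3))))
  expect_equal(tidy(seg), seg$components)
  gl <- glance(seg)
  expect_equal(gl$covered_area_pct, seg$covered_area_pct)

  lay <- build_layout(tiny_spec(10, 10), 2, diameter_dist = c(15, 0), seed = 97)
  expect_equal(nrow(tidy(lay)), 2)
  expect_equal(glance(lay)$covered_area_pct, covered_area_true(lay))
})
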