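test_that("grayscale mapping clips percentiles and ignores scale", {
  z <- matrix(0, 8, 8)
  expect_true(all(to_gray(z)$pixels == 0))

  # two-valued map: bare sensors -> 0, cell sensors -> 255
  v <- matrix(0, 10, 10); v[3:6, 3:6] <- 2.7e-14
  g <- to_gray(v)
  expect_true(all(g$pixels[v == 0] == 0))
  expect_true(all(g$pixels[v > 0] == 255))

  # positive rescaling leaves the image unchanged
  expect_equal(to_gray(v * 1e7)$pixels, g$pixels)
})

test_that("Gaussian blur is identity at kernel 1 and conserves mass", {
  v <- matrix(0L, 9, 9); v[5, 5] <- 200L
  img <- structure(list(pixels = v, scaling = NULL, spec = NULL),
                   class = "can_image")
  expect_equal(gaussian_blur(img, kernel = 1)$pixels, v)

  b <- gaussian_blur(img, kernel = 5, sigma = 1)
  # mass preserved up to per-pixel integer rounding (25 pixels, +-0.5 each)
  expect_lt(abs(sum(b$pixels) - 200), 13)
  expect_lt(max(b$pixels), 200)          # impulse spread out
  expect_equal(which.max(b$pixels), 41L) # peak stays at the centre
  expect_error(gaussian_blur(img, kernel = 4), "odd")
})

test_that("blur plus Otsu removes single-pixel spikes but keeps blocks", {
  px <- matrix(0L, 16, 16)
  px[3, 3] <- 255L          # isolated spike
  px[8:10, 8:10] <- 255L    # 3x3 object
  img <- structure(list(pixels = px, scaling = NULL, spec = NULL),
                   class = "can_image")
  ot <- otsu_binarize(gaussian_blur(img))
  expect_false(ot$mask[3, 3])       # blurred spike peak (~41) below threshold
  expect_true(ot$mask[9, 9])        # block core survives
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  # the documented two-level case: threshold strictly between the classes
  px <- matrix(c(rep(20L, 60), rep(200L, 40)), 10, 10)
  ot <- otsu_binarize(px)
  expect_gt(ot$threshold_gray, 20)
  expect_lt(ot$threshold_gray, 200)
  expect_equal(ot$threshold_gray, otsu_oracle(px))
  expect_equal(sum(ot$mask), 40)

  # inverted image partitions complementarily
  inv <- 255L - px
  oti <- otsu_binarize(inv)
  expect_equal(oti$threshold_gray, otsu_oracle(inv))
  expect_equal(sum(oti$mask), 60)

  # oracle equivalence over random 8-bit histograms
  withr::with_seed(83, {
    for (i in 1:120) {
      n <- sample(20:200, 1)
      mode2 <- sample(0:255, 2)
      px <- matrix(as.integer(pmin(pmax(round(c(
        rnorm(n, mode2[1], sample(1:40, 1)),
        rnorm(n, mode2[2], sample(1:40, 1)))), 0), 255)), 2)
      expect_equal(otsu_binarize(px)$threshold_gray, otsu_oracle(px))
    }
  })

  # constant image: no two-class structure, empty mask by convention
  expect_equal(sum(otsu_binarize(matrix(7L, 5, 5))$mask), 0)
})

test_that("Otsu partitions well-separated classes like the library route", {
  # EBImage bins [0,1]-scaled images, so thresholds differ by a few levels
  # on overlapping histograms; on separated two-level images both must land
  # in the inter-mode gap and induce the identical mask.
  withr::with_seed(84, {
    for (i in 1:20) {
      lv <- sort(sample(0:255, 2))
      if (diff(lv) < 20) next
      px <- matrix(sample(as.integer(lv), 120, replace = TRUE,
                          prob = c(0.6, 0.4)), 10)
      if (length(unique(as.vector(px))) < 2) next
      ours <- otsu_binarize(px)$threshold_gray
      ebi <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1),
                           levels = 256) * 255
      expect_true(ours >= lv[1] && ours < lv[2])
      expect_true(ebi >= lv[1] && ebi < lv[2])
      expect_equal(px > ours, px > ebi)
    }
  })
})

test_that("morphological cleanup removes speckle and fills holes", {
  expect_equal(sum(morph_cleanup(matrix(FALSE, 8, 8))), 0)

  single <- matrix(FALSE, 8, 8); single[4, 4] <- TRUE
  expect_equal(sum(morph_cleanup(single)), 0)

  # hole closing needs the object comfortably larger than the 3x3 element:
  # opening an 8x8 block with a single interior hole reproduces it exactly
  # (worked out by hand: the eroded ring re-dilates to the block minus the
  # hole), and the subsequent closing fills the hole.
  block <- matrix(FALSE, 12, 12); block[3:10, 3:10] <- TRUE
  holed <- block; holed[6, 6] <- FALSE
  cleaned <- morph_cleanup(holed)
  expect_true(cleaned[6, 6])              # interior hole closed
  expect_equal(sum(cleaned), 64)          # block preserved
})

test_that("opening is anti-extensive and closing extensive", {
  kern <- EBImage::makeBrush(3, "box")
  withr::with_seed(85, {
    for (i in 1:200) {
      m <- rand_mask(12, 12, runif(1, 0.2, 0.7), seed = sample.int(1e6, 1))
      op <- EBImage::imageData(EBImage::opening(EBImage::Image(m * 1), kern)) > 0.5
      cl <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1), kern)) > 0.5
      expect_true(all(op <= m))  # opening never adds
      expect_true(all(cl >= m))  # closing never removes
    }
  })
})

test_that("component labeling is 8-connected and matches flood fill", {
  two <- matrix(FALSE, 8, 8); two[2:3, 2:3] <- TRUE; two[6:7, 5:7] <- TRUE
  cc <- label_components(two)
  expect_equal(nrow(cc$components), 2)
  expect_setequal(cc$components$n_sensors, c(4L, 6L))

  diagn <- matrix(FALSE, 5, 5); diagn[2, 2] <- TRUE; diagn[3, 3] <- TRUE
  expect_equal(nrow(label_components(diagn)$components), 1)

  withr::with_seed(86, {
    for (i in 1:30) {
      m <- rand_mask(32, 32, runif(1, 0.1, 0.5), seed = sample.int(1e6, 1))
      expect_equal(nrow(label_components(m)$components), flood_fill_count(m))
    }
  })

  # centroids and contours agree with the geometry
  sq <- matrix(FALSE, 8, 8); sq[3:5, 4:6] <- TRUE
  cc2 <- label_components(sq)
  expect_equal(cc2$components$centroid_row, 3)  # 0-based mean of rows 2:4
  expect_equal(cc2$components$centroid_col, 4)
  ct <- cc2$contours[[1]]
  expect_true(all(ct[, "row"] >= 2 & ct[, "row"] <= 4))
  expect_true(all(ct[, "col"] >= 3 & ct[, "col"] <= 5))
})

test_that("covered area is the exact sensor count ratio", {
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  expect_equal(covered_area(m), 25)
  expect_equal(covered_area(matrix(FALSE, 7, 3)), 0)
  expect_equal(covered_area(m, sensor_array_spec(10, 10, 6, 6)), 25)
  expect_error(covered_area(m, tiny_spec(4, 5)), "shape")
  # traversal order irrelevant
  expect_equal(covered_area(m[10:1, 10:1]), covered_area(m))
})

test_that("per-sensor threshold rule detects cells against calibration", {
  spec <- tiny_spec(6, 8)
  fg <- default_freq_grid()
  params <- noise_model_params()
  bare_lay <- build_layout(spec, 0)

  # culture identical to calibration statistics -> empty mask
  ba <- synth_psd(bare_lay, params, fg, seed = 1, n_averages = Inf)
  st <- bare_sensor_stats(ba)
  st$sd[] <- 1e-16  # give the rule a finite noise scale
  m0 <- detect_cells_threshold(ba, st)
  expect_equal(sum(m0), 0)

  # one sensor raised 10 sigma above background -> detected
  v <- ba$values
  v[10, ] <- v[10, ] + 10 * 1e-16
  cu <- noise_recording(spec, v, "psd", freq_grid = fg)
  m1 <- detect_cells_threshold(cu, st)
  expect_equal(which(grid_to_sensor_vector(m1)), 10L)

  expect_error(detect_cells_threshold(cu, list(mean = NULL)), "calibration")
})

test_that("both detectors exceed 0.95 balanced accuracy at high SNR", {
  spec <- sensor_array_spec(64, 96, 6.5, 5.6)
  lay <- build_layout(spec, 12, diameter_dist = c(60, 10), seed = 87,
                      max_overlap = 0.1)
  rec <- simulate_chip(lay, noise_model_params(), default_freq_grid(),
                       seed = 88)
  truth <- lay$label_grid > 0

  seg <- segment_cells(extract_map(subtract_background(rec$culture,
                                                       rec$bare)))
  ba_otsu <- (mean(seg$mask[truth]) + mean(!seg$mask[!truth])) / 2
  expect_gt(ba_otsu, 0.95)

  thr <- detect_cells_threshold(rec$culture, bare_sensor_stats(rec$bare))
  ba_thr <- (mean(thr[truth]) + mean(!thr[!truth])) / 2
  expect_gt(ba_thr, 0.95)
})

test_that("overlay draws transformed contours in red", {
  ct <- list(cbind(row = c(2, 2, 5, 5), col = c(2, 6, 6, 2)))
  img <- overlay(ct, matrix(0.5, 12, 12))
  expect_equal(dim(img), c(12, 12, 3))
  expect_equal(img[3, 3, ], c(1, 0, 0))       # vertex (2,2) -> pixel [3,3]
  expect_equal(img[3, 5, ], c(1, 0, 0))       # along the top edge
  expect_equal(img[4, 4, ], c(0.5, 0.5, 0.5)) # interior untouched

  sh <- overlay(ct, matrix(0, 12, 12),
                overlay_transform(offset_row = 3, offset_col = 1))
  expect_equal(sh[6, 4, 1], 1)  # (2,2) shifted by (3,1) -> pixel [6,4]

  # affine round-trip: transform then invert recovers the contour
  A <- overlay_transform(scale_row = 1.3, scale_col = 0.8,
                         offset_row = 4.5, offset_col = -2)
  pts <- cbind(c(1, 7, 3), c(2, 5, 9))
  fwd <- t(A %*% rbind(t(pts), 1))
  Ainv <- cbind(solve(A[, 1:2]), -solve(A[, 1:2]) %*% A[, 3])
  back <- t(Ainv %*% rbind(t(fwd), 1))
  expect_true(all(abs(back - pts) < 0.5))
})

test_that("pipeline area tracks simulator ground truth", {
  spec <- sensor_array_spec(64, 96, 6.5, 5.6)
  withr::with_seed(89, {
    for (i in 1:4) {
      target <- runif(1, 10, 50)
      n <- round(target / 100 * 6144 / 26)
      lay <- build_layout(spec, n, diameter_dist = c(35, 8),
                          seed = sample.int(1e6, 1), max_tries = 500,
                          max_overlap = 0.25)
      rec <- simulate_chip(lay, noise_model_params(), default_freq_grid(),
                           seed = sample.int(1e6, 1))
      seg <- segment_cells(extract_map(subtract_background(rec$culture,
                                                           rec$bare)))
      expect_lt(abs(seg$covered_area_pct - covered_area_true(lay)), 3)
    }
  })
})
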