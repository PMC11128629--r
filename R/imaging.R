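#' Grayscale electrical image from an adhesion-noise map
#'
#' Maps the clamped adhesion-noise values linearly onto 8-bit gray levels:
#' the `clip_percentiles` of the value distribution define the black and
#' white points, values outside are clipped. The mapping is invariant to a
#' positive rescaling of the map. A constant map (no dynamic range) yields
#' an all-zero image by convention.
#'
#' @param map A [extract_map()] result (`can_map`), or a non-negative
#'   numeric matrix.
#' @param clip_percentiles `c(lo, hi)` percentiles in `[0, 100]`,
#'   default `c(1, 99)`.
#' @return An object of class `can_image`: integer matrix `pixels` in
#'   0-255, the `scaling` (lo, hi) used, and the grid `spec` when known.
#' @export
to_gray <- function(map, clip_percentiles = c(1, 99)) {
  v <- if (inherits(map, "can_map")) map$values else map
  stopifnot(is.matrix(v), all(v >= 0),
            clip_percentiles[1] < clip_percentiles[2])
  q <- stats::quantile(v, clip_percentiles / 100, names = FALSE)
  if (q[2] <= q[1]) {
    px <- matrix(0L, nrow(v), ncol(v))
  } else {
    px <- matrix(as.integer(round(255 * (pmin(pmax(v, q[1]), q[2]) - q[1]) /
                                    (q[2] - q[1]))), nrow(v), ncol(v))
  }
  structure(list(pixels = px, scaling = q,
                 spec = if (inherits(map, "can_map")) map$spec else NULL),
            class = "can_image")
}

#' @export
print.can_image <- function(x, ...) {
  cat(sprintf("<can_image> %d x %d px, gray range %d-%d\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

gaussian_kernel <- function(size, sigma) {
  h <- (size - 1) / 2
  d <- outer((-h:h)^2, (-h:h)^2, "+")
  k <- exp(-d / (2 * sigma^2))
  k / sum(k)
}

# reflective index: 1,2,..,n,n,..,2,1 mirroring at the border
reflect_index <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  ifelse(i > n, 2 * n + 1 - i, i)
}

#' Gaussian blur of an electrical image
#'
#' Discrete Gaussian convolution with a reflective border, suppressing
#' single-pixel noise before thresholding. `kernel = 1` is the identity.
#'
#' @param img A `can_image` (or integer matrix).
#' @param kernel Odd kernel size (default 5).
#' @param sigma Gaussian SD in pixels (default 1).
#' @return A `can_image` with blurred 8-bit pixels.
#' @export
gaussian_blur <- function(img, kernel = 5, sigma = 1.0) {
  px <- if (inherits(img, "can_image")) img$pixels else img
  stopifnot(is.matrix(px))
  if (kernel %% 2 != 1 || kernel < 1)
    stop("`kernel` must be an odd positive size", call. = FALSE)
  out <- px
  if (kernel > 1) {
    k <- gaussian_kernel(kernel, sigma)
    h <- (kernel - 1) / 2
    acc <- matrix(0, nrow(px), ncol(px))
    for (dr in -h:h) for (dc in -h:h) {
      rr <- reflect_index(seq_len(nrow(px)) + dr, nrow(px))
      cc <- reflect_index(seq_len(ncol(px)) + dc, ncol(px))
      acc <- acc + k[dr + h + 1, dc + h + 1] * px[rr, cc]
    }
    out <- matrix(as.integer(round(acc)), nrow(px), ncol(px))
  }
  structure(list(pixels = out,
                 scaling = if (inherits(img, "can_image")) img$scaling else NULL,
                 spec = if (inherits(img, "can_image")) img$spec else NULL),
            class = "can_image")
}

#' Otsu threshold of an 8-bit image
#'
#' The classic histogram criterion: the threshold `t` maximising the
#' between-class variance of the two classes `{<= t}` and `{> t}` over all
#' 256 gray levels (exhaustive scan -- the criterion's definition). Every
#' level inside an empty histogram gap induces the same partition; such tie
#' plateaus resolve to their midpoint, the common library convention. The
#' mask is `pixels > t`; cells are the high-noise class by construction of
#' the electrical image. A constant image has no two-class structure and
#' yields an empty mask (threshold 255) by documented convention.
#'
#' @param img A `can_image` or integer matrix with values in 0-255.
#' @return A list with `mask` (logical matrix) and `threshold_gray`.
#' @export
otsu_binarize <- function(img) {
  px <- if (inherits(img, "can_image")) img$pixels else img
  stopifnot(is.matrix(px), length(px) > 0, all(px >= 0), all(px <= 255))
  h <- tabulate(as.vector(px) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_cand <- 1:255  # threshold levels 0..254
  sb <- (mu_t * omega[t_cand] - mu[t_cand])^2 /
    (omega[t_cand] * (1 - omega[t_cand]))
  sb[!is.finite(sb)] <- -Inf
  if (all(sb == -Inf))  # constant image
    return(list(mask = matrix(FALSE, nrow(px), ncol(px)),
                threshold_gray = 255L))
  # thresholds inside an empty histogram gap give identical partitions;
  # resolve the tie plateau to its midpoint
  ties <- which(sb >= max(sb) * (1 - 1e-10)) - 1L
  thr <- as.integer(floor(mean(range(ties))))
  list(mask = px > thr, threshold_gray = thr)
}

mask_to_ebi <- function(mask) EBImage::Image(mask * 1)
ebi_to_mask <- function(img) EBImage::imageData(img) > 0.5

#' Morphological cleanup of a binary mask
#'
#' Opening (removes speckle; anti-extensive) followed by closing (fills
#' small holes; extensive) with square structuring elements, then removal
#' of connected components (8-connectivity) smaller than `min_size`
#' sensors. The default minimum of 4 sensors corresponds to roughly one
#' 15 um cell at ~6 um pitch.
#'
#' @param mask Logical matrix.
#' @param open_kernel,close_kernel Odd box sizes (default 3); 0 skips the
#'   operation.
#' @param min_size Minimum component size in sensors (default 4).
#' @return Logical matrix.
#' @export
morph_cleanup <- function(mask, open_kernel = 3, close_kernel = 3,
                          min_size = 4) {
  stopifnot(is.matrix(mask), is.logical(mask))
  m <- mask
  if (any(m)) {
    if (open_kernel >= 2)
      m <- ebi_to_mask(EBImage::opening(mask_to_ebi(m),
                                        EBImage::makeBrush(open_kernel, "box")))
    if (close_kernel >= 2)
      m <- ebi_to_mask(EBImage::closing(mask_to_ebi(m),
                                        EBImage::makeBrush(close_kernel, "box")))
    if (min_size > 1 && any(m)) {
      lab <- label_mask_8(m)
      sizes <- tabulate(lab[lab > 0])
      small <- which(sizes < min_size)
      if (length(small)) m[lab %in% small] <- FALSE
    }
  }
  m
}

# 8-connected labeling by vectorized breadth-first flood fill.
label_mask_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  if (!length(todo)) return(lab)
  nbr_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur_lab <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur_lab <- cur_lab + 1L
    lab[seed] <- cur_lab
    frontier <- seed
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (k in 1:8) {
        rr <- r + nbr_dr[k]; cc <- c + nbr_dc[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[mask[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- cur_lab
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Connected components and contours of a cell mask
#'
#' 8-connected component labeling (diagonal-touching sensors belong to one
#' object) with per-component pixel counts, centroids, and polygonal
#' contours in 0-based sensor coordinates.
#'
#' @param mask Logical matrix.
#' @return A list with `labels` (integer matrix), `components` (tibble:
#'   `label`, `n_sensors`, `centroid_row`, `centroid_col`), and `contours`
#'   (list of two-column matrices `(row, col)`, 0-based, one per
#'   component).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- label_mask_8(mask)
  n <- max(lab)
  if (n == 0) {
    return(list(labels = lab,
                components = tibble::tibble(label = integer(),
                                            n_sensors = integer(),
                                            centroid_row = numeric(),
                                            centroid_col = numeric()),
                contours = list()))
  }
  idx <- which(lab > 0)
  r0 <- ((idx - 1L) %% nrow(lab))        # 0-based row
  c0 <- ((idx - 1L) %/% nrow(lab))       # 0-based col
  l <- lab[idx]
  comp <- tibble::tibble(
    label = seq_len(n),
    n_sensors = tabulate(l, n),
    centroid_row = as.numeric(tapply(r0, l, mean)),
    centroid_col = as.numeric(tapply(c0, l, mean)))
  oc <- EBImage::ocontour(EBImage::Image(lab))
  contours <- lapply(seq_len(n), function(k) {
    m <- oc[[as.character(k)]] %||% oc[[k]]
    out <- cbind(row = m[, 1], col = m[, 2])  # ocontour is 0-based, dim1 = row
    out
  })
  list(labels = lab, components = comp, contours = contours)
}

#' Cell-covered area of a mask
#'
#' `100 * (# cell-covered sensors) / (# sensors)` -- the exact counting
#' formula, no approximation.
#'
#' @param mask Logical matrix.
#' @param spec Optional [sensor_array_spec()]; when given, the mask shape
#'   must match.
#' @return Covered area in percent.
#' @export
covered_area <- function(mask, spec = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "sensor_array_spec"))
    if (!all(dim(mask) == c(spec$n_rows, spec$n_cols)))
      stop("mask shape does not match the array spec", call. = FALSE)
  }
  100 * sum(mask) / length(mask)
}

#' Segment adherent cells in an adhesion-noise map
#'
#' The full electrical-imaging pipeline: percentile grayscale mapping,
#' Gaussian blur, Otsu binarization, morphological opening/closing with
#' small-component removal, 8-connected component labeling, and
#' covered-area quantification. Otsu runs on the blurred 8-bit image of
#' the clamped single-frequency map.
#'
#' @param map A `can_map` from [extract_map()].
#' @param clip_percentiles Passed to [to_gray()].
#' @param kernel,sigma Passed to [gaussian_blur()].
#' @param open_kernel,close_kernel,min_size Passed to [morph_cleanup()].
#' @return An object of class `can_segmentation`: `mask`, `threshold_gray`,
#'   `components`, `contours`, `labels`, `covered_area_pct`, `spec`,
#'   `params`.
#' @export
segment_cells <- function(map, clip_percentiles = c(1, 99), kernel = 5,
                          sigma = 1.0, open_kernel = 3, close_kernel = 3,
                          min_size = 4) {
  stopifnot(inherits(map, "can_map"))
  img <- gaussian_blur(to_gray(map, clip_percentiles), kernel, sigma)
  ot <- otsu_binarize(img)
  mask <- morph_cleanup(ot$mask, open_kernel, close_kernel, min_size)
  cc <- label_components(mask)
  structure(list(mask = mask, threshold_gray = ot$threshold_gray,
                 components = cc$components, contours = cc$contours,
                 labels = cc$labels,
                 covered_area_pct = covered_area(mask, map$spec),
                 spec = map$spec,
                 params = list(clip_percentiles = clip_percentiles,
                               kernel = kernel, sigma = sigma,
                               open_kernel = open_kernel,
                               close_kernel = close_kernel,
                               min_size = min_size)),
            class = "can_segmentation")
}

#' @export
print.can_segmentation <- function(x, ...) {
  cat(sprintf("<can_segmentation> %d objects, covered area %.1f%% (Otsu gray %d)\n",
              nrow(x$components), x$covered_area_pct, x$threshold_gray))
  invisible(x)
}

#' Per-sensor threshold detection rule
#'
#' The alternative to the Otsu pipeline: a sensor detects a cell when its
#' culture PSD at the analysis frequency exceeds its own bare-sensor
#' background mean by more than `max(dsv_min, k_sigma * bare SD)`. Supplied
#' for comparison with the image-based segmentation; both agree on
#' well-separated layouts.
#'
#' @param culture A [noise_recording()] of kind `"psd"`.
#' @param stats Calibration statistics from [bare_sensor_stats()].
#' @param analysis_freq Hz (default 300 kHz).
#' @param k_sigma Multiplier on the per-sensor background SD (default 3).
#' @param dsv_min Absolute floor on the required adhesion noise, V^2/Hz
#'   (default 0).
#' @return Logical `n_rows x n_cols` detection mask.
#' @export
detect_cells_threshold <- function(culture, stats, analysis_freq = 300e3,
                                   k_sigma = 3, dsv_min = 0) {
  stopifnot(inherits(culture, "noise_recording"), culture$kind == "psd")
  if (is.null(stats$mean) || is.null(stats$sd))
    stop("missing calibration statistics: run `bare_sensor_stats()` on a bare recording",
         call. = FALSE)
  fg <- culture$freq_grid
  if (analysis_freq < min(fg) || analysis_freq > max(fg))
    stop("`analysis_freq` outside the frequency grid", call. = FALSE)
  bin <- which.min(abs(fg - analysis_freq))
  v <- culture$values[, bin]
  pos <- v > stats$mean + pmax(dsv_min, k_sigma * stats$sd)
  sensor_vector_to_grid(pos, culture$spec)
}

#' Affine transform helper for overlays
#'
#' Builds the 2x3 matrix mapping sensor `(row, col)` coordinates to image
#' pixel coordinates: `pixel = A %*% c(row, col, 1)`. The default identity
#' maps sensor indices straight to pixels; pitch-aware scaling maps via the
#' physical sensor spacing.
#'
#' @param scale_row,scale_col Scale factors (e.g. pitch / pixel size).
#' @param offset_row,offset_col Pixel offsets.
#' @return A 2x3 numeric matrix.
#' @export
overlay_transform <- function(scale_row = 1, scale_col = 1,
                              offset_row = 0, offset_col = 0) {
  matrix(c(scale_row, 0, 0, scale_col, offset_row, offset_col), 2, 3)
}

#' Draw segmentation contours onto a micrograph
#'
#' Transforms each contour polygon from sensor coordinates to image pixels
#' with the user-supplied affine transform and draws it in red on a copy of
#' the micrograph. Registration is the caller's responsibility; the package
#' performs no automatic alignment.
#'
#' @param contours List of `(row, col)` contour matrices (0-based sensor
#'   coordinates), e.g. from [segment_cells()].
#' @param micrograph Grayscale matrix (values in 0-1) or `h x w x 3` array.
#' @param transform 2x3 affine matrix from [overlay_transform()].
#' @return An `h x w x 3` array with the contours drawn in red.
#' @export
overlay <- function(contours, micrograph, transform = overlay_transform()) {
  stopifnot(is.list(contours), is.matrix(transform),
            all(dim(transform) == c(2, 3)))
  if (is.matrix(micrograph)) {
    img <- array(rep(micrograph, 3), c(dim(micrograph), 3))
  } else {
    stopifnot(length(dim(micrograph)) == 3, dim(micrograph)[3] == 3)
    img <- micrograph
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  for (ct in contours) {
    if (!nrow(ct)) next
    px <- t(transform %*% rbind(t(ct), 1))  # n x 2 (pixel row, col)
    px <- rbind(px, px[1, , drop = FALSE])  # close the polygon
    for (i in seq_len(nrow(px) - 1)) {
      n_pts <- max(2, ceiling(2 * max(abs(px[i + 1, ] - px[i, ]))) + 1)
      rr <- round(seq(px[i, 1], px[i + 1, 1], length.out = n_pts)) + 1
      cc <- round(seq(px[i, 2], px[i + 1, 2], length.out = n_pts)) + 1
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      if (any(ok)) {
        img[cbind(rr[ok], cc[ok], 1)] <- 1
        img[cbind(rr[ok], cc[ok], 2)] <- 0
        img[cbind(rr[ok], cc[ok], 3)] <- 0
      }
    }
  }
  img
}
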