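# Shared fixtures and independent oracles. Oracles are deliberately written
# in a different style from the package code paths they check.

tiny_spec <- function(nr = 4, nc = 5) sensor_array_spec(nr, nc, 6.5, 5.6)

# Random binary mask with occupancy p.
rand_mask <- function(nr, nc, p, seed) {
  withr::with_seed(seed, matrix(stats::runif(nr * nc) < p, nr, nc))
}

# Independent Otsu oracle: exhaustive scan computing the two class means
# and weights directly from the pixel values (not from cumulative sums).
otsu_oracle <- function(px) {
  v <- as.vector(px)
  bc <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc[t + 1] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  # ties (equal partitions) resolve to the plateau midpoint
  ties <- which(bc >= max(bc) * (1 - 1e-10)) - 1L
  as.integer(floor(mean(range(ties))))
}

# Independent 8-connected component counter: scalar stack-based flood fill.
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || seen[r, c]) next
    count <- count + 1L
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  count
}

# A can_map built directly from a value matrix (bypasses the spectral path).
map_from_matrix <- function(v, spec = NULL) {
  if (is.null(spec)) spec <- sensor_array_spec(nrow(v), ncol(v), 6.5, 5.6)
  structure(list(spec = spec, analysis_freq = 300e3,
                 values = pmax(v, 0), raw_values = v, meta = list()),
            class = "can_map")
}

# Noiseless model: no mismatch, no drift, no estimation noise.
noiseless_params <- function(...) {
  noise_model_params(sensor_variability = 0, session_drift = 0, ...)
}
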