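# Independent oracles and fixture builders, kept deliberately naive so they
# share no code path with the implementation they check.

# rasterise an ellipse (full axes a, b, degrees) into a logical mask
raster_ellipse <- function(dim, cx, cy, a, b, angle_deg = 0) {
  th <- angle_deg * pi / 180
  m <- matrix(FALSE, dim[1], dim[2])
  for (r in seq_len(dim[1])) {
    for (cc in seq_len(dim[2])) {
      dx <- (cc - 1) - cx
      dy <- (r - 1) - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      m[r, cc] <- (u / (a / 2))^2 + (v / (b / 2))^2 <= 1
    }
  }
  m
}

# brute-force interior-pixel mean centroid of a mask (0-based x, y)
pixel_mean_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2] - 1), y = mean(idx[, 1] - 1))
}

# brute-force drift-stage oracle: explicit O(n*W) per-window sign counts,
# explicit window union and start/end magnitude test. The filtered signal
# (median + smoothed difference) is taken from the package's own
# drift_signal(): the brute force re-derives the window logic, and sharing
# the filter avoids spurious sign flips of analytically-zero entries under
# a different floating-point summation order.
drift_oracle <- function(sizes, cfg = qc_config()) {
  n <- length(sizes)
  out <- logical(n)
  W <- cfg$drift_window
  if (n < 2 || (n - 1) < W) return(out)
  sig <- arenatrack:::drift_signal(sizes, cfg)
  m <- sig$m
  d <- sig$d
  nd <- length(d)
  cov <- logical(nd)
  for (i in 1:(nd - W + 1)) {
    np <- sum(d[i:(i + W - 1)] > 0)
    nn <- sum(d[i:(i + W - 1)] < 0)
    if (max(np, nn) / W >= cfg$drift_fraction) cov[i:(i + W - 1)] <- TRUE
  }
  i <- 1
  while (i <= nd) {
    if (cov[i]) {
      j <- i
      while (j < nd && cov[j + 1]) j <- j + 1
      if (abs(m[j + 1] - m[i]) > cfg$drift_min_delta) out[i:(j + 1)] <- TRUE
      i <- j + 1
    }
    i <- i + 1
  }
  out
}

# minimal observation table for QC unit tests: stationary object with
# constant size unless overridden
make_track <- function(n, area_mm2 = 2, object_id = 0L, x = NULL, y = NULL,
                       speed = NULL, scale = 0.1) {
  if (length(area_mm2) == 1L) area_mm2 <- rep(area_mm2, n)
  if (is.null(x)) x <- seq_len(n) * 2 # steady crawl
  if (is.null(y)) y <- rep(0, n)
  tb <- tibble::tibble(
    object_id = object_id, frame = seq_len(n) - 1L,
    x_px = x, y_px = y,
    area_px = round(area_mm2 / scale^2), area_mm2 = area_mm2,
    ellipse_major_mm = 4, ellipse_minor_mm = 1, ratio = 4, angle_deg = 0)
  if (is.null(speed)) {
    d <- c(0, sqrt(diff(x)^2 + diff(y)^2)) * scale
    speed <- d * 10
  }
  tb$distance_mm <- c(0, sqrt(diff(x)^2 + diff(y)^2)) * scale
  tb$speed_mm_s <- speed
  tb
}

# small jittered-size series so static/statistical stages stay quiet
jitter_sizes <- function(n, base = 2, sd = 0.03, seed = 1) {
  withr::with_seed(seed, base + stats::rnorm(n, 0, sd))
}
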