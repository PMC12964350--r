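test_that("mask_to_polygon traces the largest component, rejects empties", {
  m <- matrix(FALSE, 10, 10)
  m[3:8, 3:8] <- TRUE
  poly <- mask_to_polygon(m)
  # boundary encloses exactly the square: all vertices on its border
  expect_true(all(poly[, "x"] >= 2 & poly[, "x"] <= 7))
  expect_true(all(poly[, "y"] >= 2 & poly[, "y"] <= 7))
  expect_true(any(poly[, "x"] == 2) && any(poly[, "x"] == 7))

  m2 <- matrix(FALSE, 20, 20)
  m2[2:11, 2:6] <- TRUE          # 50 px component
  m2[15:19, 15]  <- TRUE         # 5 px component
  expect_warning(p2 <- mask_to_polygon(m2), "largest")
  expect_true(all(p2[, "x"] <= 6)) # polygon follows the big component

  expect_error(mask_to_polygon(matrix(FALSE, 5, 5)), "Empty")
})

test_that("polygon centroid matches symmetry and brute-force pixel mean", {
  expect_equal(unname(polygon_centroid(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))),
               c(1, 1))
  expect_equal(unname(polygon_centroid(rbind(c(0, 0), c(3, 0), c(0, 3)))),
               c(1, 1))
  # L-shaped blob: traced-polygon centroid vs rasterised interior mean
  m <- matrix(FALSE, 30, 30)
  m[5:24, 5:10] <- TRUE
  m[19:24, 5:24] <- TRUE
  poly <- mask_to_polygon(m)
  got <- polygon_centroid(poly)
  ref <- pixel_mean_centroid(m)
  expect_lt(max(abs(got - ref)), 0.5)
  # degenerate polygon falls back to vertex mean with a warning
  expect_warning(fc <- polygon_centroid(rbind(c(0, 0), c(1, 1), c(2, 2))),
                 "degenerate")
  expect_equal(unname(fc), c(1, 1))
})

test_that("mask_area is pixel count times scale squared", {
  cal <- calibration(0.1, 10)
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(mask_area(m, cal), 100 * 0.01)
  expect_equal(mask_area(matrix(FALSE, 5, 5), cal), 0)
  m37 <- matrix(FALSE, 10, 10); m37[seq_len(37)] <- TRUE
  expect_equal(mask_area(m37, calibration(0.25, 10)), 2.3125)
})

test_that("ellipse fit recovers circles and rendered ellipses", {
  circ <- raster_ellipse(c(50, 50), 24, 24, 40, 40)
  f <- fit_object_ellipse(mask_to_polygon(circ))
  expect_lt(abs(f$major - 40) / 40, 0.05)
  expect_lt(abs(f$minor - 40) / 40, 0.05)
  expect_gte(axis_ratio(f), 1.0)
  expect_lte(axis_ratio(f), 1.1)

  ell <- raster_ellipse(c(100, 100), 49, 49, 60, 20, angle_deg = 30)
  fe <- fit_object_ellipse(mask_to_polygon(ell))
  expect_lt(abs(fe$major - 60) / 60, 0.05)
  expect_lt(abs(fe$minor - 20) / 20, 0.05)
  expect_lt(abs(fe$angle - 30), 5)

  expect_error(fit_object_ellipse(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               "at least 5")
})

test_that("axis ratio follows major/minor with guarded zero minor", {
  e <- structure(list(center = c(0, 0), major = 60, minor = 20, angle = 0),
                 class = "ellipse_fit")
  expect_equal(axis_ratio(e), 3)
  e$minor <- e$major <- 40
  expect_equal(axis_ratio(e), 1)
  e$minor <- 0
  expect_error(axis_ratio(e), "minor")
})

test_that("rotating a mask by 90 degrees preserves area exactly, R to 2%", {
  m <- raster_ellipse(c(80, 80), 39, 39, 50, 16, angle_deg = 10)
  mr <- t(m)[, rev(seq_len(nrow(m)))] # 90 degree rotation
  cal <- calibration(0.1, 10)
  expect_identical(mask_area(m, cal), mask_area(mr, cal))
  r1 <- axis_ratio(fit_object_ellipse(mask_to_polygon(m)))
  r2 <- axis_ratio(fit_object_ellipse(mask_to_polygon(mr)))
  expect_lt(abs(r1 - r2) / r1, 0.02)
})

test_that("extract_features builds one calibrated row per object-frame", {
  cal <- calibration(0.1, 10)
  fr1 <- list(`0` = raster_ellipse(c(130, 130), 32, 32, 60, 20),
              `1` = raster_ellipse(c(130, 130), 95, 95, 60, 20, 90))
  fr2 <- list(`0` = raster_ellipse(c(130, 130), 34, 32, 60, 20))
  ft <- extract_features(list(fr1, fr2), cal)
  expect_equal(nrow(ft), 3L)
  expect_setequal(names(ft), c("frame", "object_id", "x_px", "y_px",
                               "area_px", "area_mm2", "ellipse_major_mm",
                               "ellipse_minor_mm", "ratio", "angle_deg"))
  expect_equal(ft$frame, c(0L, 1L, 0L))
  r0 <- ft[ft$object_id == 0L & ft$frame == 0L, ]
  expect_lt(abs(r0$x_px - 32), 0.6)
  expect_lt(abs(r0$ratio - 3), 0.25)
  expect_equal(r0$area_mm2, r0$area_px * 0.01)
})
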