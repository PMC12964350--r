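cal10 <- calibration(0.1, 10)

test_that("frame displacement and speed follow the centroid and fps", {
  expect_equal(frame_displacement(c(0, 3), c(0, 4), cal10), c(0, 0.5))
  expect_equal(frame_displacement(rep(2, 5), rep(3, 5), cal10), rep(0, 5))
  expect_equal(frame_speed(c(0, 0.5), cal10), c(0, 5))
  expect_equal(frame_speed(0.2, calibration(0.1, 30)), 6)
})

test_that("straight-line track aggregates match closed form exactly", {
  # 100 frames, 1 mm per frame (10 px at 0.1 mm/px), 10 fps
  fr <- tibble::tibble(
    object_id = 0L, frame = 0:99, x_px = (0:99) * 10, y_px = 0,
    area_mm2 = 3, ellipse_major_mm = 4, ellipse_minor_mm = 1,
    state = "elongated")
  s <- summarise_tracks(fr, cal10)
  expect_equal(s$total_distance_mm, 99, tolerance = 1e-9)
  expect_equal(s$mean_speed_mm_s, 99 / 100 * 10, tolerance = 1e-9) # frame-0 zero included
  expect_equal(s$body_length_mm, 4)
  expect_equal(s$normalised_distance, 99 / 4, tolerance = 1e-9)

  # removing an interior block of 20 frames severs the 21 consecutive-frame
  # pairs touching it; the gap is not bridged, so 99 - 21 = 78 mm remain
  fr2 <- fr[!(fr$frame %in% 40:59), ]
  s2 <- summarise_tracks(fr2, cal10,
                         frames_total = c(`0` = 100L))
  expect_equal(s2$total_distance_mm, 78, tolerance = 1e-9)
  expect_equal(s2$frames_removed, 20L)
  expect_lt(s2$total_distance_mm, s$total_distance_mm) # strict decrease

  # brute-force oracle: sum over consecutive retained pairs only
  brute <- sum(vapply(seq_len(nrow(fr2))[-1], function(i) {
    if (fr2$frame[i] - fr2$frame[i - 1] == 1L) {
      sqrt((fr2$x_px[i] - fr2$x_px[i - 1])^2 +
             (fr2$y_px[i] - fr2$y_px[i - 1])^2) * 0.1
    } else 0
  }, numeric(1)))
  expect_equal(s2$total_distance_mm, brute, tolerance = 1e-12)
})

test_that("state-resolved metrics restrict to elongated frames", {
  fr <- tibble::tibble(
    object_id = 0L, frame = 0:9, x_px = (0:9) * 10, y_px = 0,
    area_mm2 = 3, ellipse_major_mm = 4, ellipse_minor_mm = 1,
    state = rep(c("elongated", "bent"), each = 5))
  s <- summarise_tracks(fr, cal10)
  expect_equal(s$time_elongated_s, 0.5)
  expect_equal(s$time_bent_s, 0.5)
  expect_lt(s$distance_elongated_mm, s$total_distance_mm)
  allbent <- dplyr::mutate(fr, state = "bent")
  sb <- summarise_tracks(allbent, cal10)
  expect_equal(sb$distance_elongated_mm, 0)
  expect_true(is.na(sb$body_length_mm)) # no elongated frame -> undefined
  expect_true(is.na(sb$normalised_distance))
})

test_that("body length is the median elongated major axis", {
  fr <- tibble::tibble(state = "elongated",
                       ellipse_major_mm = rep(c(3.9, 4.1), 10))
  expect_equal(body_length(fr), 4.0)
  expect_equal(body_length(tibble::tibble(state = "elongated",
                                          ellipse_major_mm = rep(4, 5))), 4)
  expect_true(is.na(body_length(tibble::tibble(state = "bent",
                                               ellipse_major_mm = 4))))
})

test_that("total distance dominates the straight-line chord", {
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- 50
      x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
      fr <- tibble::tibble(object_id = 0L, frame = seq_len(n) - 1L,
                           x_px = x, y_px = y, area_mm2 = 3,
                           ellipse_major_mm = 4, ellipse_minor_mm = 1,
                           state = "elongated")
      s <- summarise_tracks(fr, cal10)
      chord <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2) * 0.1
      expect_gte(s$total_distance_mm + 1e-12, chord)
    }
  })
})

test_that("removing frames never increases total distance", {
  withr::with_seed(13, {
    n <- 200
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    fr <- tibble::tibble(object_id = 0L, frame = seq_len(n) - 1L,
                         x_px = x, y_px = y, area_mm2 = 3,
                         ellipse_major_mm = 4, ellipse_minor_mm = 1,
                         state = "elongated")
    d_full <- summarise_tracks(fr, cal10)$total_distance_mm
    for (i in 1:10) {
      drop <- sample(n, 30)
      d_sub <- summarise_tracks(fr[-drop, ], cal10,
                                frames_total = c(`0` = n))$total_distance_mm
      expect_lte(d_sub, d_full + 1e-12)
    }
  })
})

test_that("downsampling a smooth trajectory never increases distance", {
  sc <- simulate_scene(scene_spec(duration_s = 60, fps = 30, seed = 4))
  fr <- frames_from_truth(sc)
  cal30 <- calibration(0.1, 30)
  d30 <- fr |>
    dplyr::mutate(state = "elongated") |>
    summarise_tracks(cal30)
  fr10 <- fr[fr$frame %% 3L == 0L, ] |>
    dplyr::mutate(frame = frame %/% 3L, state = "elongated")
  d10 <- summarise_tracks(fr10, calibration(0.1, 10))
  expect_true(all(d10$total_distance_mm <= d30$total_distance_mm + 1e-9))
})
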