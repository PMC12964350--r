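cfg <- qc_config()

test_that("static-size rule flags runs strictly longer than 20 frames", {
  s <- c(rep(5, 25), jitter_sizes(30))
  f <- flag_static_size(s, cfg)
  expect_true(all(f[1:25]))
  expect_false(any(f[26:55]))
  expect_false(any(flag_static_size(c(rep(5, 15), jitter_sizes(30)), cfg)[1:15]))
  expect_false(any(flag_static_size(seq_len(50), cfg)))
})

test_that("segmenting produces maximal alternating inlier/outlier runs", {
  segs <- segment_track(c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(segs$label, c("inlier", "outlier", "inlier"))
  expect_equal(segs$start_frame, c(0L, 2L, 4L))
  expect_equal(segs$end_frame, c(1L, 3L, 4L))
  expect_equal(segment_track(rep(FALSE, 10))$label, "inlier")
  expect_equal(segment_track(rep(TRUE, 10))$label, "outlier")
  expect_equal(nrow(segment_track(logical(0))), 0L)
})

test_that("infilling re-flags short gaps bounded by outliers on both sides", {
  f <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 10))
  expect_true(all(infill_flags(f, cfg)[11:20]))
  f2 <- c(rep(TRUE, 10), rep(FALSE, 100), rep(TRUE, 10))
  expect_false(any(infill_flags(f2, cfg)))
  # leading inlier segment has one neighbour only: never infilled
  f3 <- c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 10))
  inf3 <- infill_flags(f3, cfg)
  expect_false(any(inf3[1:5]))
  expect_true(all(inf3[16:20]))
})

test_that("size-jump boundary is strict at 1.5 mm^2", {
  expect_true(flag_size_jump(c(2.0, 3.6), cfg)[2])   # delta 1.6
  expect_false(flag_size_jump(c(2.0, 3.4), cfg)[2])  # delta 1.4
  expect_false(any(flag_size_jump(rep(2, 50), cfg)))
})

test_that("lowering the jump threshold never unflags a frame", {
  withr::with_seed(3, {
    s <- cumsum(rnorm(300, 0, 0.8))
  })
  f_high <- flag_size_jump(s, qc_config(jump_threshold = 1.5))
  f_low <- flag_size_jump(s, qc_config(jump_threshold = 0.8))
  expect_true(all(f_low[f_high]))
})

test_that("drift stage flags sustained ramps and ignores noise and small rises", {
  n <- 600
  ramp <- c(jitter_sizes(150, base = 2), 2 + 0.02 * seq_len(300),
            jitter_sizes(150, base = 8, seed = 2))
  got <- flag_size_drift(ramp, cfg)
  expect_identical(got, drift_oracle(ramp, cfg))
  expect_gt(mean(got[151:450]), 0.5)     # ramp region mostly flagged
  # (the 201-frame median filter smears the ramp up to ~100+window frames
  # outward; flat-series cleanliness is asserted on the pure-noise case)

  noise <- jitter_sizes(1000, base = 2, sd = 0.05, seed = 4)
  expect_false(any(flag_size_drift(noise, cfg)))
  expect_identical(flag_size_drift(noise, cfg), drift_oracle(noise, cfg))

  small <- c(jitter_sizes(200, base = 2), 2 + 0.5 * seq_len(200) / 200,
             jitter_sizes(200, base = 2.5, seed = 5))
  expect_false(any(flag_size_drift(small, cfg))) # rise 0.5 <= 1 mm^2
  # a track shorter than the window skips the stage with a notice
  expect_message(out <- flag_size_drift(jitter_sizes(40), cfg), "skipped")
  expect_false(any(out))
})

test_that("drift stage equals the brute-force window oracle on random walks", {
  withr::with_seed(21, {
    for (i in 1:10) {
      s <- 2 + cumsum(rnorm(500, 0, 0.02)) + rnorm(500, 0, 0.02)
      expect_identical(flag_size_drift(s, cfg), drift_oracle(s, cfg))
    }
  })
})

test_that("identity switches are caught by segment median comparison", {
  # baseline 300 frames median ~2, second segment median ~3.5
  s <- c(jitter_sizes(300, base = 2), jitter_sizes(150, base = 3.5, seed = 7))
  flags <- c(rep(FALSE, 299), TRUE, rep(FALSE, 150)) # boundary outlier splits
  got <- flag_id_switch(s, flags, cfg)
  expect_true(all(got[301:450]))
  expect_false(any(got[1:299]))

  s2 <- c(jitter_sizes(300, base = 2), jitter_sizes(150, base = 2.5, seed = 8))
  expect_false(any(flag_id_switch(s2, flags, cfg))) # 0.5 <= 1 mm^2
  # no qualifying baseline: stage skipped
  s3 <- jitter_sizes(150, base = 2)
  expect_message(out <- flag_id_switch(s3, rep(FALSE, 150), cfg), "skipped")
  expect_false(any(out))
})

test_that("statistical outliers use inlier moments and strict limits", {
  withr::with_seed(9, {
    sp <- rnorm(500, 1, 0.1)
  })
  sp[250] <- 2.0 # 10 s.d.
  sizes <- jitter_sizes(500)
  got <- flag_statistical_outliers(sizes, sp, rep(FALSE, 500), cfg)
  expect_equal(got[250], "speed_outlier")
  expect_equal(sum(got != "none"), 1L)
  # independent verification of the exceedance
  mu <- mean(sp); sdv <- sd(sp)
  expect_gt(abs(sp[250] - mu), 5 * sdv)

  expect_true(all(flag_statistical_outliers(sizes, rep(1, 500),
                                            rep(FALSE, 500), cfg) == "none"))
  # a value at exactly mean + 4 sd is NOT flagged (strict inequality)
  x <- rep(c(1, 3), 50) # mean 2, population-ish symmetric
  mu <- mean(x); sdv <- sd(x)
  x2 <- c(x, mu + 4 * sdv)
  got2 <- flag_statistical_outliers(x2, rep(1, length(x2)),
                                    rep(FALSE, length(x2)), cfg)
  # moments shift slightly once the new point joins; recompute directly
  expect_equal(got2[length(x2)] == "size_outlier",
               abs(x2[length(x2)] - mean(x2)) > 4 * sd(x2))
})

test_that("duplicate tracks are resolved by outlier count with id tie-break", {
  dupA <- make_track(400, area_mm2 = jitter_sizes(400))
  dupB <- make_track(400, area_mm2 = jitter_sizes(400, seed = 2),
                     object_id = 1L)
  dupB$y_px <- dupB$y_px + 200 # elsewhere in the arena outside the overlap
  # B shares A's centroids for 150 frames and has more flagged frames
  dupB$x_px[100:249] <- dupA$x_px[100:249]
  dupB$y_px[100:249] <- dupA$y_px[100:249]
  fr <- dplyr::bind_rows(dupA, dupB)
  fr$flagged <- c(rep(FALSE, 400), rep(c(TRUE, FALSE), c(30, 370)))
  res <- detect_duplicates(fr, cfg)
  expect_equal(res$removed_ids, 1L)
  expect_true(all(res$duplicate_flags$object_id == 1L))
  # widened by the infill radius
  expect_true(min(res$duplicate_flags$frame) <= 99 - 0)
  expect_gte(min(res$duplicate_flags$frame), 99 - cfg$infill_radius)

  # 90 matching frames: below the >100 rule, nobody removed
  dupB2 <- dupB
  dupB2$x_px <- make_track(400, object_id = 1L)$x_px + 50
  dupB2$x_px[100:189] <- dupA$x_px[100:189]
  dupB2$y_px[100:189] <- dupA$y_px[100:189]
  fr2 <- dplyr::bind_rows(dupA, dupB2)
  fr2$flagged <- FALSE
  expect_length(detect_duplicates(fr2, cfg)$removed_ids, 0L)

  # tie in outlier counts: keep the first (lower) id
  fr$flagged <- FALSE
  res3 <- detect_duplicates(fr, cfg)
  expect_equal(res3$removed_ids, 1L)
})

test_that("full pipeline partitions tracks and recommends omission", {
  sc <- simulate_scene(scene_spec(duration_s = 120, seed = 17))
  frames <- frames_from_truth(sc) |>
    add_posture(posture_config(bent_direction = "below")) |>
    add_kinematics(calibration(0.1, 10))
  qc <- run_qc(frames)
  expect_equal(sum(qc$report$frames_flagged), 0L) # clean world stays clean
  expect_equal(nrow(good_frames(qc)) + nrow(problematic_frames(qc)),
               nrow(frames))

  # inject a frozen run: exactly that run (plus infill) becomes problematic
  inj <- tibble::tibble(object_id = 0L, mode = "detachment",
                        start_frame = 400L, end_frame = 449L)
  corr <- inject_failures(frames, inj, scale = 0.1)
  qc2 <- run_qc(add_kinematics(corr$frames, calibration(0.1, 10)))
  fl <- qc2$frames[qc2$frames$object_id == 0L, ]
  expect_true(all(fl$flagged[fl$frame %in% 400:449]))
  flagged_frames <- fl$frame[fl$flagged]
  expect_true(all(flagged_frames >= 400 - cfg$infill_radius - 2 &
                    flagged_frames <= 449 + cfg$infill_radius + 2))

  # 40% corruption triggers the omit recommendation (> 1/3)
  n0 <- sum(frames$object_id == 0L)
  inj3 <- tibble::tibble(object_id = 0L, mode = "detachment",
                         start_frame = 100L,
                         end_frame = 100L + ceiling(0.4 * n0) - 1L)
  corr3 <- inject_failures(frames, inj3, scale = 0.1)
  qc3 <- run_qc(add_kinematics(corr3$frames, calibration(0.1, 10)))
  expect_true(qc3$report$omit_recommended[qc3$report$object_id == 0L])
})

test_that("pipeline is idempotent on its own good output", {
  sc <- simulate_scene(scene_spec(duration_s = 120, seed = 19))
  frames <- frames_from_truth(sc) |>
    add_posture(posture_config(bent_direction = "below")) |>
    add_kinematics(calibration(0.1, 10))
  qc1 <- run_qc(frames)
  good <- good_frames(qc1)
  qc2 <- run_qc(dplyr::select(good, -"flagged", -"flag_reason"))
  expect_lt(sum(qc2$report$frames_flagged) / nrow(good), 0.01)
})

test_that("tidy and glance summarise a qc_result", {
  sc <- simulate_scene(scene_spec(duration_s = 60, seed = 2))
  frames <- frames_from_truth(sc) |>
    add_posture(posture_config(bent_direction = "below")) |>
    add_kinematics(calibration(0.1, 10))
  qc <- run_qc(frames)
  td <- tidy(qc)
  expect_setequal(names(td), c("object_id", "flag_reason", "n_frames"))
  expect_equal(sum(td$n_frames), sum(qc$report$frames_flagged))
  gl <- glance(qc)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_tracks, 5L)
})
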