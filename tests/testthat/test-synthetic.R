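test_that("scene simulation is deterministic from its seed", {
  s1 <- simulate_scene(scene_spec(duration_s = 20, seed = 42))
  s2 <- simulate_scene(scene_spec(duration_s = 20, seed = 42))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_scene(scene_spec(duration_s = 20, seed = 43))
  expect_false(identical(s1$truth, s3$truth))
})

test_that("behavioural state machine controls displacement", {
  all_pause <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE,
                      dimnames = list(c("run", "cast", "pause"),
                                      c("run", "cast", "pause")))
  # start state is 'run' but every transition lands in pause
  sp <- scene_spec(n_objects = 1, duration_s = 30, transition = all_pause,
                   seed = 2)
  tr <- simulate_scene(sp)$truth
  moved <- sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
  expect_lt(moved, sp$run_speed_mm_s / sp$fps * 2) # only the first step

  run_only <- diag(3)
  dimnames(run_only) <- dimnames(all_pause)
  sp2 <- scene_spec(n_objects = 1, duration_s = 180, transition = run_only,
                    run_speed_mm_s = 1, seed = 3)
  tr2 <- simulate_scene(sp2)$truth
  path <- sum(sqrt(diff(tr2$x_mm)^2 + diff(tr2$y_mm)^2))
  expect_equal(path, 180, tolerance = 0.05) # 1 mm/s for 180 s
  expect_equal(tr2$state, rep("run", nrow(tr2)))
  # confined to the arena
  r <- sqrt((tr2$x_mm - 30)^2 + (tr2$y_mm - 30)^2)
  expect_true(all(r <= 30))
})

test_that("rendered blob area matches the analytic ellipse area", {
  sc <- simulate_scene(scene_spec(duration_s = 2, seed = 5))
  v <- render_scene(sc, return_masks = TRUE, noise_sd = 0)
  masks <- attr(v, "masks")$masks[[1]]
  spec <- sc$spec
  expected_px <- pi * (spec$blob_major_mm / 2) * (spec$blob_minor_mm / 2) /
    spec$scale^2
  for (m in masks) {
    expect_lt(abs(sum(m) - expected_px) / expected_px, 0.05)
  }
  expect_equal(length(masks), 5L) # disjoint objects: one component each
  # empty scene renders an empty video
  v0 <- render_scene(simulate_scene(scene_spec(duration_s = 0)))
  expect_equal(length(v0$frames), 0L)
})

test_that("failure injection writes the exact advertised signatures", {
  sc <- simulate_scene(scene_spec(duration_s = 120, seed = 9))
  fr <- frames_from_truth(sc)

  det <- inject_failures(fr, tibble::tibble(
    object_id = 0L, mode = "detachment", start_frame = 100L,
    end_frame = 149L), scale = 0.1)
  d0 <- det$frames[det$frames$object_id == 0L, ]
  expect_equal(length(unique(d0$x_px[d0$frame %in% 100:149])), 1L)
  expect_equal(length(unique(d0$area_mm2[d0$frame %in% 100:149])), 1L)

  mrg <- inject_failures(fr, tibble::tibble(
    object_id = 1L, mode = "collision_merge", start_frame = 200L,
    end_frame = 349L, magnitude = 2.0), scale = 0.1)
  m1 <- mrg$frames[mrg$frames$object_id == 1L, ]
  o1 <- fr[fr$object_id == 1L, ]
  step <- m1$area_mm2[m1$frame == 200] - o1$area_mm2[o1$frame == 200]
  expect_equal(step, 2.0, tolerance = 1e-6)

  dup <- inject_failures(fr, tibble::tibble(
    object_id = 2L, mode = "duplicate", start_frame = 300L,
    end_frame = 449L, source_id = 3L), scale = 0.1)
  d2 <- dup$frames[dup$frames$object_id == 2L & dup$frames$frame %in% 300:449, ]
  d3 <- dup$frames[dup$frames$object_id == 3L & dup$frames$frame %in% 300:449, ]
  expect_equal(d2$x_px, d3$x_px)

  expect_error(inject_failures(fr, tibble::tibble(
    object_id = 0L, mode = c("detachment", "jump"),
    start_frame = c(100L, 120L), end_frame = c(149L, 121L)), scale = 0.1),
    "overlapping")
})

test_that("detection scoring counts events by flagged-frame overlap", {
  sc <- simulate_scene(scene_spec(duration_s = 60, seed = 10))
  fr <- frames_from_truth(sc) |>
    add_posture(posture_config(bent_direction = "below")) |>
    add_kinematics(calibration(0.1, 10))
  ev <- tibble::tibble(object_id = 0L, mode = "detachment",
                       start_frame = 200L, end_frame = 249L)
  qc_clean <- run_qc(fr) # nothing flagged: rate 0
  expect_equal(score_detection(qc_clean, ev)$rate, 0)

  corr <- inject_failures(fr, ev, scale = 0.1)
  qc <- run_qc(add_kinematics(corr$frames, calibration(0.1, 10)))
  res <- score_detection(qc, corr$events)
  expect_equal(res$rate, 1) # fully flagged event
  expect_gte(res$events$flagged_fraction, 0.5)
})
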