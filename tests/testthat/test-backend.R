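mk_video <- function(n, fps = 30, dim = c(20, 20)) {
  frame_video(replicate(n, matrix(0, dim[1], dim[2]), simplify = FALSE), fps)
}

test_that("fps downsampling keeps every stride-th frame from frame 0", {
  v <- mk_video(90)
  out <- downsample_fps(v, 10)
  expect_equal(length(out$frames), 30L)
  expect_equal(out$fps, 10)
  expect_identical(downsample_fps(v, 30)$frames, v$frames)
  expect_equal(length(downsample_fps(mk_video(91), 10)$frames), 31L) # ceiling
  expect_error(downsample_fps(v, 60), "exceeds")
})

test_that("reference backend recovers well-separated blobs to sub-pixel", {
  sc <- simulate_scene(scene_spec(duration_s = 10, seed = 42))
  v <- render_scene(sc)
  cal <- calibration(sc$spec$scale, sc$spec$fps)
  ft <- segment_and_extract(v, scene_prompts(sc), cal)
  expect_equal(nrow(ft), 5L * 100L) # every id present every frame
  j <- dplyr::inner_join(ft, sc$truth, by = c("object_id", "frame"),
                         suffix = c("", ".t"))
  err <- sqrt((j$x_px - j$x_px.t)^2 + (j$y_px - j$y_px.t)^2)
  expect_lt(max(err), 1) # within 1 px of ground truth every frame
})

test_that("reference backend is deterministic and collision-free ids stable", {
  sc <- simulate_scene(scene_spec(duration_s = 8, seed = 3))
  v <- render_scene(sc)
  cal <- calibration(sc$spec$scale, sc$spec$fps)
  f1 <- segment_and_extract(v, scene_prompts(sc), cal)
  f2 <- segment_and_extract(v, scene_prompts(sc), cal)
  expect_identical(f1, f2)
  # lazy stream renders bit-identically to the materialised video
  f3 <- segment_and_extract(scene_video(sc), scene_prompts(sc), cal)
  expect_identical(f1, f3)
})

test_that("prompts outside any component raise a named error", {
  sc <- simulate_scene(scene_spec(duration_s = 5, seed = 6))
  v <- render_scene(sc)
  bad <- tibble::tibble(object_id = 9L, x = 3, y = 3, frame = 0L)
  expect_error(segment_video(v, bad), "unresolvable prompt.*object 9")
})

test_that("backend contract check validates shape, ids and binarity", {
  sc <- simulate_scene(scene_spec(duration_s = 3, seed = 8))
  v <- render_scene(sc)
  pr <- scene_prompts(sc)
  seg <- segment_video(v, pr)
  chk <- backend_contract_check(seg, v, pr)
  expect_true(chk$pass)

  seg_missing <- seg
  seg_missing$masks[[1]][["0"]] <- NULL
  chk2 <- backend_contract_check(seg_missing, v, pr)
  expect_false(chk2$pass)
  expect_match(paste(chk2$messages, collapse = "; "), "missing id")

  seg_nb <- seg
  seg_nb$masks[[2]][["1"]] <- seg_nb$masks[[2]][["1"]] * 3
  chk3 <- backend_contract_check(seg_nb, v, pr)
  expect_false(chk3$pass)
  expect_match(paste(chk3$messages, collapse = "; "), "not binary")
})

test_that("touching blobs merge and leave a size-jump/drift signature for QC", {
  # two blobs converge, touch for a stretch, then separate: the kept id
  # swallows both bodies, so its area steps far beyond the jump threshold
  sc <- simulate_scene(scene_spec(n_objects = 2, duration_s = 30, seed = 1))
  tr <- sc$truth
  # force object 1 onto a collision course with object 0 for frames 100-129
  t0 <- tr[tr$object_id == 0L, ]
  collide <- tr$object_id == 1L & tr$frame %in% 100:129
  tr$x_px[collide] <- t0$x_px[t0$frame %in% 100:129] + 6
  tr$y_px[collide] <- t0$y_px[t0$frame %in% 100:129]
  sc$truth <- tr
  v <- render_scene(sc)
  cal <- calibration(sc$spec$scale, sc$spec$fps)
  ft <- segment_and_extract(v, scene_prompts(sc), cal)
  obs <- add_posture(ft, posture_config(bent_direction = "below")) |>
    add_kinematics(cal)
  qc <- run_qc(obs)
  flagged <- problematic_frames(qc)
  expect_gt(nrow(flagged), 0)
  expect_true(any(flagged$flag_reason %in%
                    c("size_jump", "size_drift", "id_switch", "size_outlier")))
})
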