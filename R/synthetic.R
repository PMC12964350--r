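#' Specify a synthetic arena scene
#'
#' The generator emulates the recording conditions the pipeline was designed
#' around: five late third-instar larvae crawling in a 60 mm circular arena,
#' filmed at 10 fps for 3 minutes. Each animal is an elliptical blob driven
#' by a first-order Markov state machine over run / pause / head-cast
#' states: runs are sustained forward crawling with an elongated body (large
#' axis ratio R), casts are lateral head sweeps with a rounder, bent body
#' (small R, well separated from the elongated mode), pauses are stationary.
#' Area is conserved when the body bends; the arena wall reflects headings.
#'
#' @param arena_diameter_mm Arena diameter (default 60 mm).
#' @param n_objects Number of animals (default 5).
#' @param fps Frame rate (default 10).
#' @param duration_s Recording length (default 180 s).
#' @param scale mm per pixel of the rendered canvas (default 0.1, a 60 mm
#'   arena filling a 600 px frame as in a 720p recording).
#' @param blob_major_mm,blob_minor_mm Resting body axes (default 4 x 1 mm,
#'   a typical wandering third-instar larva).
#' @param run_speed_mm_s Crawling speed during runs (default 0.8 mm/s).
#' @param cast_speed_mm_s Residual speed during head casts.
#' @param transition Named 3x3 row-stochastic matrix over states
#'   `run`, `cast`, `pause`.
#' @param bent_ratio Mean axis ratio while bent (default 2.2; elongated mean
#'   is `blob_major_mm / blob_minor_mm`).
#' @param ratio_noise_sd Per-frame noise on R.
#' @param area_noise_mm2 Per-frame area jitter (segmentation noise).
#' @param heading_noise_sd Heading random-walk s.d. (rad/frame) during runs.
#' @param peristalsis_hz,peristalsis_amp,area_osc_amp Frequency (Hz) and
#'   relative amplitudes of the slow peristaltic length/area oscillation a
#'   crawling larva shows even when not advancing; this is what keeps a
#'   genuine pause distinguishable from a frozen (detached) track.
#' @param seed Random seed; the scene is reproducible from it.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(arena_diameter_mm = 60, n_objects = 5, fps = 10,
                       duration_s = 180, scale = 0.1,
                       blob_major_mm = 4, blob_minor_mm = 1,
                       run_speed_mm_s = 0.8, cast_speed_mm_s = 0.12,
                       transition = NULL, bent_ratio = 2.2,
                       ratio_noise_sd = 0.15, area_noise_mm2 = 0.05,
                       heading_noise_sd = 0.25, peristalsis_hz = 1.1,
                       peristalsis_amp = 0.025, area_osc_amp = 0.015,
                       seed = 1L) {
  if (is.null(transition)) {
    transition <- matrix(c(0.95, 0.03, 0.02,
                           0.13, 0.85, 0.02,
                           0.06, 0.02, 0.92),
                         3, 3, byrow = TRUE,
                         dimnames = list(c("run", "cast", "pause"),
                                         c("run", "cast", "pause")))
  }
  stopifnot(arena_diameter_mm > 0, n_objects >= 1, fps > 0, duration_s >= 0,
            scale > 0, blob_major_mm > blob_minor_mm, blob_minor_mm > 0,
            all(abs(rowSums(transition) - 1) < 1e-9))
  structure(list(arena_diameter_mm = arena_diameter_mm,
                 n_objects = as.integer(n_objects), fps = fps,
                 duration_s = duration_s, scale = scale,
                 blob_major_mm = blob_major_mm, blob_minor_mm = blob_minor_mm,
                 run_speed_mm_s = run_speed_mm_s,
                 cast_speed_mm_s = cast_speed_mm_s,
                 transition = transition, bent_ratio = bent_ratio,
                 ratio_noise_sd = ratio_noise_sd,
                 area_noise_mm2 = area_noise_mm2,
                 heading_noise_sd = heading_noise_sd,
                 peristalsis_hz = peristalsis_hz,
                 peristalsis_amp = peristalsis_amp,
                 area_osc_amp = area_osc_amp,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Simulate ground-truth trajectories for a scene
#'
#' Produces per-object, per-frame centroid (mm and px), heading, behavioural
#' state, posture, ellipse axes and area, reproducibly from the spec's seed.
#' Objects softly repel each other (headings deflect towards the arena
#' centre when two blobs come within 1.5 body lengths), so default scenes
#' are collision-free; the wall is reflective.
#'
#' @param spec A [scene_spec()].
#' @return A `scene` object: list with `truth` (tibble) and `spec`.
#' @export
simulate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n_frames <- as.integer(round(spec$duration_s * spec$fps))
  n <- spec$n_objects
  if (n_frames == 0L) {
    return(structure(list(truth = tibble::tibble(), spec = spec),
                     class = "scene"))
  }
  R_arena <- spec$arena_diameter_mm / 2
  margin <- spec$blob_major_mm / 2 + 1
  states <- c("run", "cast", "pause")
  tr_cum <- t(apply(spec$transition, 1, cumsum))

  # initial positions: rejection-sample well-separated points
  px <- numeric(n); py <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      r <- sqrt(stats::runif(1)) * (R_arena - margin) * 0.85
      th <- stats::runif(1, 0, 2 * pi)
      cx <- r * cos(th); cy <- r * sin(th)
      if (i == 1L || all(sqrt((px[seq_len(i - 1)] - cx)^2 +
                                (py[seq_len(i - 1)] - cy)^2) >
                           2.5 * spec$blob_major_mm)) break
    }
    px[i] <- cx; py[i] <- cy
  }
  heading <- stats::runif(n, 0, 2 * pi)
  st <- rep(1L, n) # start in run

  X <- matrix(0, n_frames, n); Y <- matrix(0, n_frames, n)
  S <- matrix(1L, n_frames, n); H <- matrix(0, n_frames, n)
  speed_by_state <- c(spec$run_speed_mm_s, spec$cast_speed_mm_s, 0)
  for (t in seq_len(n_frames)) {
    if (t > 1L) {
      u <- stats::runif(n)
      st <- vapply(seq_len(n),
                   function(i) which(u[i] <= tr_cum[st[i], ])[1], integer(1))
    }
    hsd <- ifelse(st == 1L, spec$heading_noise_sd,
                  ifelse(st == 2L, 2.5 * spec$heading_noise_sd, 0))
    heading <- heading + stats::rnorm(n, 0, hsd)
    step <- speed_by_state[st] / spec$fps
    nx <- px + step * cos(heading)
    ny <- py + step * sin(heading)
    # soft mutual repulsion keeps default scenes collision-free: when two
    # animals close within two body lengths, each heads away from its
    # nearest neighbour
    if (n > 1L) {
      d <- as.matrix(stats::dist(cbind(nx, ny)))
      diag(d) <- Inf
      nn <- apply(d, 1, which.min)
      close <- d[cbind(seq_len(n), nn)] < 2 * spec$blob_major_mm
      if (any(close)) {
        heading[close] <- atan2(py[close] - py[nn[close]],
                                px[close] - px[nn[close]]) +
          stats::rnorm(sum(close), 0, 0.2)
        nx[close] <- px[close] + step[close] * cos(heading[close])
        ny[close] <- py[close] + step[close] * sin(heading[close])
      }
    }
    # arena wall: project back inside and turn towards the centre
    rr <- sqrt(nx^2 + ny^2)
    out <- rr > (R_arena - margin)
    if (any(out)) {
      fac <- (R_arena - margin) / rr[out]
      nx[out] <- nx[out] * fac
      ny[out] <- ny[out] * fac
      heading[out] <- atan2(-ny[out], -nx[out]) +
        stats::rnorm(sum(out), 0, 0.2)
    }
    px <- nx; py <- ny
    X[t, ] <- px; Y[t, ] <- py; S[t, ] <- st; H[t, ] <- heading
  }

  base_area <- pi * spec$blob_major_mm * spec$blob_minor_mm / 4
  R_elong <- spec$blob_major_mm / spec$blob_minor_mm
  phase <- stats::runif(n, 0, 2 * pi)
  truth <- purrr::map(seq_len(n), function(i) {
    state <- states[S[, i]]
    posture <- ifelse(state == "cast", "bent", "elongated")
    Rmean <- ifelse(posture == "bent", spec$bent_ratio, R_elong)
    # the length oscillation is the stride cycle: full amplitude while
    # crawling, residual amplitude during casts and pauses
    amp_fac <- c(1, 0.5, 0.25)[S[, i]]
    osc <- amp_fac * sin(2 * pi * spec$peristalsis_hz *
                           (seq_len(n_frames) - 1L) / spec$fps + phase[i])
    ratio <- pmax(1.05, Rmean * (1 + 2 * spec$peristalsis_amp * osc) +
                    stats::rnorm(n_frames, 0, spec$ratio_noise_sd))
    area <- pmax(0.2, base_area * (1 + spec$area_osc_amp * osc) +
                   stats::rnorm(n_frames, 0, spec$area_noise_mm2))
    major <- sqrt(4 * area * ratio / pi)
    tibble::tibble(
      object_id = i - 1L, frame = seq_len(n_frames) - 1L,
      x_mm = X[, i] + R_arena, y_mm = Y[, i] + R_arena, # origin: arena corner
      x_px = (X[, i] + R_arena) / spec$scale,
      y_px = (Y[, i] + R_arena) / spec$scale,
      heading = H[, i], state = state, posture = posture, osc = osc,
      area_mm2 = area, major_mm = major, minor_mm = major / ratio,
      ratio_true = ratio)
  }) |> purrr::list_rbind()
  structure(list(truth = truth, spec = spec), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d objects, %d frames, %.6g mm arena, seed %d\n",
              x$spec$n_objects,
              if (nrow(x$truth)) max(x$truth$frame) + 1L else 0L,
              x$spec$arena_diameter_mm, x$spec$seed))
  invisible(x)
}

#' Synthesise an observation table directly from ground truth
#'
#' Bypasses rendering and segmentation: converts a scene's ground truth into
#' the observation tibble the feature module would produce from perfect
#' masks (pixel-quantised areas, ellipse axes, axis ratio). Used to test
#' posture, kinematics and QC at scale without image processing.
#'
#' @param scene A `scene` from [simulate_scene()].
#' @return Observation tibble with the [extract_features()] schema plus
#'   ground-truth `state`/`posture` columns dropped (kept separately in the
#'   scene).
#' @export
frames_from_truth <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  s <- scene$spec$scale
  scene$truth |>
    dplyr::transmute(
      .data$frame, .data$object_id,
      x_px = .data$x_px, y_px = .data$y_px,
      area_px = round(.data$area_mm2 / s^2),
      area_mm2 = area_px * s^2,
      ellipse_major_mm = .data$major_mm,
      ellipse_minor_mm = .data$minor_mm,
      ratio = .data$ratio_true,
      angle_deg = (.data$heading * 180 / pi) %% 180)
}

#' Render a scene to grayscale video frames
#'
#' Bright filled ellipses (oriented by heading) on a dark circular arena
#' disc, with optional Gaussian pixel noise; the synthetic stand-in for a
#' real arena recording. Optionally also returns per-frame ground-truth
#' masks.
#'
#' @param scene A `scene`.
#' @param return_masks Also build per-object logical masks per frame
#'   (memory-heavy; default `FALSE`).
#' @param noise_sd Pixel noise s.d. (default 2 grey levels).
#' @return A [frame_video()]; if `return_masks`, the result carries a
#'   `masks` attribute shaped like a segmentation result.
#' @export
render_scene <- function(scene, return_masks = FALSE, noise_sd = 2) {
  stopifnot(inherits(scene, "scene"))
  n_frames <- if (nrow(scene$truth)) max(scene$truth$frame) + 1L else 0L
  frames <- vector("list", n_frames)
  masks <- if (return_masks) vector("list", n_frames) else NULL
  ctx <- render_context(scene, noise_sd)
  for (t in seq_len(n_frames)) {
    r <- render_one_frame(ctx, t, return_masks)
    frames[[t]] <- r$frame
    if (return_masks) masks[[t]] <- r$masks
  }
  video <- frame_video(frames, scene$spec$fps)
  if (return_masks) {
    attr(video, "masks") <- structure(
      list(masks = masks, prompts = NULL, n_frames = n_frames),
      class = "segmentation_result")
  }
  video
}

# Shared renderer state: arena background and per-frame truth lookup.
render_context <- function(scene, noise_sd) {
  spec <- scene$spec
  D <- as.integer(ceiling(spec$arena_diameter_mm / spec$scale))
  xs <- seq_len(D) - 1
  cx <- (D - 1) / 2
  dist2 <- outer((xs - cx)^2, (xs - cx)^2, "+") # [row=y, col=x] symmetric
  base <- matrix(5, D, D)
  base[dist2 <= (D / 2)^2] <- 30
  list(spec = spec, D = D, base = base, noise_sd = noise_sd,
       truth_by_frame = if (nrow(scene$truth)) {
         split(scene$truth, scene$truth$frame)
       } else {
         list()
       })
}

# Render frame t (1-based). Pixel noise is seeded per frame so lazy and
# materialised rendering produce bit-identical videos.
render_one_frame <- function(ctx, t, return_masks = FALSE) {
  spec <- ctx$spec; D <- ctx$D
  set.seed((spec$seed + 10007L) %% 1000000L * 2000L + t)
  fr <- ctx$base
  if (ctx$noise_sd > 0) {
    fr <- fr + matrix(stats::rnorm(D * D, 0, ctx$noise_sd), D, D)
  }
  tf <- ctx$truth_by_frame[[as.character(t - 1L)]]
  frame_masks <- list()
  for (i in seq_len(nrow(tf))) {
    # render the true body for the frame's posture and peristaltic phase;
    # measurement noise then arises from rasterisation and segmentation,
    # as in a real imaging chain, instead of being painted into the video
    base_area <- pi * spec$blob_major_mm * spec$blob_minor_mm / 4
    Rr <- if (tf$posture[i] == "bent") spec$bent_ratio else
      spec$blob_major_mm / spec$blob_minor_mm
    Rr <- Rr * (1 + 2 * spec$peristalsis_amp * tf$osc[i])
    Ar <- base_area * (1 + spec$area_osc_amp * tf$osc[i])
    a <- sqrt(4 * Ar * Rr / pi) / 2 / spec$scale
    b <- sqrt(4 * Ar / Rr / pi) / 2 / spec$scale
    x0 <- tf$x_px[i]; y0 <- tf$y_px[i]; th <- tf$heading[i]
    half <- ceiling(a) + 2L
    colr <- max(1L, floor(x0) - half):min(D, ceiling(x0) + half)
    rowr <- max(1L, floor(y0) - half):min(D, ceiling(y0) + half)
    dx <- outer(rep(1, length(rowr)), colr - 1 - x0)
    dy <- outer(rowr - 1 - y0, rep(1, length(colr)))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- fr[rowr, colr]
    sub[inside] <- 220
    fr[rowr, colr] <- sub
    if (return_masks) {
      m <- matrix(FALSE, D, D)
      msub <- m[rowr, colr]
      msub[inside] <- TRUE
      m[rowr, colr] <- msub
      frame_masks[[as.character(tf$object_id[i])]] <- m
    }
  }
  fr[fr < 0] <- 0; fr[fr > 255] <- 255
  list(frame = fr, masks = frame_masks)
}

#' Lazy video view of a scene
#'
#' Returns a `frame_stream` that renders each frame on demand instead of
#' materialising the whole recording (a 3-minute 600 px scene does not fit
#' comfortably in memory as doubles). Bit-identical to [render_scene()].
#'
#' @param scene A `scene`.
#' @param noise_sd Pixel noise s.d. (default 2 grey levels).
#' @return A `frame_stream` usable wherever a [frame_video()] is.
#' @export
scene_video <- function(scene, noise_sd = 2) {
  stopifnot(inherits(scene, "scene"))
  n_frames <- if (nrow(scene$truth)) max(scene$truth$frame) + 1L else 0L
  ctx <- render_context(scene, noise_sd)
  structure(list(
    frame_fn = function(t) render_one_frame(ctx, t)$frame,
    index = seq_len(n_frames), n_frames = n_frames,
    fps = scene$spec$fps, dim = c(ctx$D, ctx$D)),
    class = "frame_stream")
}

#' Point prompts for a scene's annotation frame
#'
#' @param scene A `scene`.
#' @param frame Annotation frame (default 0).
#' @return Prompt tibble (`object_id`, `x`, `y`, `frame`).
#' @export
scene_prompts <- function(scene, frame = 0L) {
  scene$truth |>
    dplyr::filter(.data$frame == !!frame) |>
    dplyr::transmute(.data$object_id, x = .data$x_px, y = .data$y_px,
                     frame = !!as.integer(frame))
}

failure_modes <- c("detachment", "collision_merge", "size_drift",
                   "id_switch", "jump", "duplicate")

#' Default magnitude and duration of an injected failure
#'
#' Magnitudes are chosen to satisfy the corresponding QC rule's trigger
#' condition with realistic margin: a detachment freezes centroid and size
#' for 50 frames (> 20-frame static rule); a collision merge steps area up
#' by 2 mm^2 (> 1.5 mm^2 jump rule) for 150 frames; a size drift ramps area
#' by 2 mm^2 (> 1 mm^2 rise) over 200 frames (>= 80-frame window); an
#' identity switch steps area by 2 mm^2 (> 1 mm^2 segment-median rule) and
#' displaces the centroid for 300 frames; a jump teleports the centroid by
#' 8 mm for 2 frames (speed spike far beyond 5 s.d. at 10 fps); a duplicate
#' copies another object's centroids for 150 frames (> 100-frame rule).
#'
#' @param mode One of `r paste(failure_modes, collapse = ", ")`.
#' @return List with `duration` (frames) and `magnitude` (mm^2 for size
#'   modes, mm for displacement modes, NA for duplicate).
#' @export
failure_defaults <- function(mode) {
  switch(match.arg(mode, failure_modes),
         detachment = list(duration = 50L, magnitude = NA_real_),
         collision_merge = list(duration = 150L, magnitude = 2.0),
         size_drift = list(duration = 200L, magnitude = 2.0),
         id_switch = list(duration = 300L, magnitude = 2.0),
         jump = list(duration = 2L, magnitude = 8.0),
         duplicate = list(duration = 150L, magnitude = NA_real_))
}

#' Inject tracking-failure signatures into an observation table
#'
#' Corrupts an observation tibble with the six failure signatures the QC
#' pipeline is built to catch, and returns exact per-frame ground truth for
#' scoring detection. `injections` is a tibble with columns `object_id`,
#' `mode`, `start_frame`, `end_frame`, optional `magnitude` (filled from
#' [failure_defaults()]) and, for `duplicate`, `source_id`.
#'
#' Signatures: `detachment` freezes centroid and size; `collision_merge`
#' adds `magnitude` mm^2 to the area; `size_drift` ramps the area linearly
#' by `magnitude` over the event and holds the offset afterwards (an
#' identity that crept onto another animal stays there); `id_switch` adds
#' `magnitude` mm^2 and displaces the centroid by 10 mm for the event
#' (tracking a different, larger animal); `jump` displaces the centroid by
#' `magnitude` mm; `duplicate` overwrites the centroid with `source_id`'s.
#'
#' @param frames Observation tibble (schema of [frames_from_truth()]).
#' @param injections Injection table; overlapping events on one object are
#'   an error.
#' @param scale mm per pixel (to convert centroid displacements).
#' @return List with `frames` (corrupted copy) and `events` (the injection
#'   table with any defaulted magnitudes filled in).
#' @export
inject_failures <- function(frames, injections, scale) {
  stopifnot(is.data.frame(frames), is.data.frame(injections))
  inj <- tibble::as_tibble(injections)
  if (!"magnitude" %in% names(inj)) inj$magnitude <- NA_real_
  if (!"source_id" %in% names(inj)) inj$source_id <- NA_integer_
  inj$mode <- as.character(inj$mode)
  bad <- setdiff(inj$mode, failure_modes)
  if (length(bad)) stop("unknown failure mode(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  # overlap check per object
  for (oid in unique(inj$object_id)) {
    e <- inj[inj$object_id == oid, ]
    if (nrow(e) > 1L) {
      o <- order(e$start_frame)
      if (any(e$start_frame[o][-1] <= e$end_frame[o][-nrow(e)])) {
        stop(sprintf("overlapping injections on object %s", oid), call. = FALSE)
      }
    }
  }
  out <- dplyr::arrange(frames, .data$object_id, .data$frame)
  s2 <- scale^2
  for (i in seq_len(nrow(inj))) {
    mode <- inj$mode[i]
    def <- failure_defaults(mode)
    if (is.na(inj$magnitude[i])) inj$magnitude[i] <- def$magnitude
    oid <- inj$object_id[i]
    f0 <- inj$start_frame[i]; f1 <- inj$end_frame[i]
    sel <- which(out$object_id == oid & out$frame >= f0 & out$frame <= f1)
    if (length(sel) == 0L) stop("injection window outside track", call. = FALSE)
    mag <- inj$magnitude[i]
    if (mode == "detachment") {
      out$x_px[sel] <- out$x_px[sel[1]]
      out$y_px[sel] <- out$y_px[sel[1]]
      out$area_px[sel] <- out$area_px[sel[1]]
      out$area_mm2[sel] <- out$area_mm2[sel[1]]
    } else if (mode == "collision_merge") {
      out$area_mm2[sel] <- out$area_mm2[sel] + mag
      out$area_px[sel] <- round(out$area_mm2[sel] / s2)
    } else if (mode == "size_drift") {
      ramp <- seq(0, mag, length.out = length(sel))
      out$area_mm2[sel] <- out$area_mm2[sel] + ramp
      after <- which(out$object_id == oid & out$frame > f1)
      out$area_mm2[after] <- out$area_mm2[after] + mag
      upd <- c(sel, after)
      out$area_px[upd] <- round(out$area_mm2[upd] / s2)
    } else if (mode == "id_switch") {
      out$area_mm2[sel] <- out$area_mm2[sel] + mag
      out$area_px[sel] <- round(out$area_mm2[sel] / s2)
      out$x_px[sel] <- out$x_px[sel] + 10 / scale
      out$y_px[sel] <- out$y_px[sel] + 10 / scale
    } else if (mode == "jump") {
      out$x_px[sel] <- out$x_px[sel] + mag / scale
      out$y_px[sel] <- out$y_px[sel] + mag / scale
    } else if (mode == "duplicate") {
      src <- inj$source_id[i]
      if (is.na(src)) stop("duplicate injection needs `source_id`", call. = FALSE)
      ssel <- which(out$object_id == src & out$frame >= f0 & out$frame <= f1)
      if (length(ssel) != length(sel)) {
        stop("duplicate injection: source frames do not align", call. = FALSE)
      }
      out$x_px[sel] <- out$x_px[ssel]
      out$y_px[sel] <- out$y_px[ssel]
    }
  }
  list(frames = out, events = inj)
}

#' Score event-level detection of injected failures
#'
#' An injected event counts as detected when at least `min_overlap` of its
#' frames carry any QC flag (for a duplicate event, removal of the target
#' track also counts). The rate is detected events over injected events —
#' event-level scoring, mirroring per-case validation over curated tracks.
#'
#' @param qc A `qc_result` from [run_qc()] on the corrupted observations.
#' @param events Injection table (from [inject_failures()]).
#' @param min_overlap Minimum flagged fraction of an event's frames
#'   (default 0.5).
#' @return List with `events` (the table plus `flagged_fraction` and
#'   `detected`) and `rate` (detected / injected).
#' @export
score_detection <- function(qc, events, min_overlap = 0.5) {
  stopifnot(inherits(qc, "qc_result"))
  all_frames <- dplyr::bind_rows(qc$frames, qc$removed)
  flag_key <- all_frames[all_frames$flagged, c("object_id", "frame")]
  key <- paste(flag_key$object_id, flag_key$frame)
  res <- events
  res$flagged_fraction <- NA_real_
  res$detected <- FALSE
  for (i in seq_len(nrow(res))) {
    f <- res$start_frame[i]:res$end_frame[i]
    frac <- mean(paste(res$object_id[i], f) %in% key)
    res$flagged_fraction[i] <- frac
    res$detected[i] <- frac >= min_overlap ||
      (res$mode[i] == "duplicate" && res$object_id[i] %in% qc$removed_ids)
  }
  list(events = tibble::as_tibble(res), rate = mean(res$detected))
}
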