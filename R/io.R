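track_csv_cols <- c("frame", "object_id", "x_px", "y_px", "area_mm2",
                    "ellipse_major_mm", "ellipse_minor_mm", "ratio",
                    "angle_deg", "ratio_zscore", "state", "distance_mm",
                    "speed_mm_s", "flag_reason")

# fill schema defaults for columns a pre-QC table does not carry yet
complete_track_schema <- function(track) {
  if (!"ratio_zscore" %in% names(track)) track$ratio_zscore <- NA_real_
  if (!"state" %in% names(track)) track$state <- "undefined"
  if (!"distance_mm" %in% names(track)) track$distance_mm <- NA_real_
  if (!"speed_mm_s" %in% names(track)) track$speed_mm_s <- NA_real_
  if (!"flag_reason" %in% names(track)) track$flag_reason <- "none"
  track
}

#' Write / read a per-track CSV
#'
#' The raw/good/problematic per-object files share one fixed schema:
#' `frame, object_id, x_px, y_px, area_mm2, ellipse_major_mm,
#' ellipse_minor_mm, ratio, angle_deg, ratio_zscore, state, distance_mm,
#' speed_mm_s, flag_reason`. Reading back a written file reproduces the
#' numeric values to at least 6 decimal places. An empty track writes a
#' header-only file; a file missing a schema column is a named parse error.
#'
#' @param track Observation tibble (extra columns are dropped).
#' @param path Output CSV path.
#' @return `write_track_csv` returns `path` invisibly; `read_track_csv`
#'   returns the tibble.
#' @export
write_track_csv <- function(track, path) {
  track <- complete_track_schema(tibble::as_tibble(track))
  miss <- setdiff(track_csv_cols, names(track))
  if (length(miss)) {
    stop("track is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(track[track_csv_cols], path)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(track_csv_cols, hdr)
  if (length(miss)) {
    stop(sprintf("malformed track file %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(), object_id = readr::col_integer(),
    state = readr::col_character(), flag_reason = readr::col_character(),
    .default = readr::col_double()))
}

#' Serialise / restore analysis configuration
#'
#' Round-trips the QC and posture settings (and optionally a calibration)
#' through a JSON config file.
#'
#' @param path JSON file path.
#' @param qc A [qc_config()].
#' @param posture A [posture_config()].
#' @param calibration Optional [calibration()].
#' @return `write_config` returns `path` invisibly; `read_config` a list
#'   with restored `qc`, `posture` and (optionally) `calibration`.
#' @export
write_config <- function(path, qc = qc_config(), posture = posture_config(),
                         calibration = NULL) {
  rlang::check_installed("jsonlite")
  obj <- list(qc = unclass(qc), posture = unclass(posture))
  if (!is.null(calibration)) obj$calibration <- unclass(calibration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  rlang::check_installed("jsonlite")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(qc = do.call(qc_config, obj$qc),
              posture = do.call(posture_config, obj$posture))
  if (!is.null(obj$calibration)) {
    out$calibration <- calibration(obj$calibration$scale, obj$calibration$fps)
  }
  out
}

#' Analyse an observation table end to end
#'
#' The orchestration core shared by [run_single()] and [run_batch()]:
#' posture classification (on the raw track, before any QC removal), per
#' frame kinematics, the QC pipeline, and good-frame aggregation.
#'
#' @param frames Observation tibble from [extract_features()],
#'   [segment_and_extract()] or [frames_from_truth()].
#' @param calibration A [calibration()].
#' @param qc_config A [qc_config()].
#' @param posture_config A [posture_config()].
#' @return An `arena_analysis` object: list with `raw` (full observation
#'   table), `qc` (the `qc_result`), `summary` (per-track aggregates joined
#'   with QC counts) and `calibration`.
#' @export
analyze_observations <- function(frames, calibration,
                                 qc_config = arenatrack::qc_config(),
                                 posture_config = arenatrack::posture_config()) {
  raw <- frames |>
    add_posture(posture_config) |>
    add_kinematics(calibration)
  qc <- run_qc(raw, qc_config)
  totals <- raw |>
    dplyr::count(.data$object_id, name = "frames_total")
  good <- good_frames(qc)
  summary <- summarise_tracks(good, calibration, frames_total = totals,
                              omit_fraction = qc_config$omit_fraction) |>
    dplyr::left_join(dplyr::select(qc$report, "object_id", "frames_flagged",
                                   "static_size":"infill"),
                     by = "object_id")
  structure(list(raw = raw, qc = qc, summary = summary,
                 calibration = calibration),
            class = "arena_analysis")
}

#' @export
print.arena_analysis <- function(x, ...) {
  cat(sprintf("<arena_analysis> %d tracks, %d frames\n",
              nrow(x$summary), sum(x$summary$frames_total)))
  print(x$qc)
  invisible(x)
}

#' Run a single recording through the full pipeline and write its outputs
#'
#' Accepts either a `scene` (synthetic; segmented with the reference
#' backend after rendering, or analysed directly from ground truth with
#' `use_truth = TRUE`) or a [frame_video()] plus prompts. Writes the full
#' output tree:
#' `raw_frames/<id>.csv`, `good_frames/<id>.csv`,
#' `problematic_frames/<id>.csv` (present only for objects with flagged
#' frames), `paths/<id>.png` (state-shaded track tracings), `output.csv`
#' (per-track aggregates), `problematic_frames_visualisation/<id>.png`
#' (size and speed scatterplots with removed frames highlighted),
#' optionally `tracking/frame_<n>.png` overlays, and `run.log`.
#'
#' @param input A `scene` or [frame_video()].
#' @param out_dir Output directory (created if needed).
#' @param calibration A [calibration()]; defaulted from the scene spec for
#'   synthetic input.
#' @param prompts Prompt tibble/CSV path (required for raw video input;
#'   defaulted to ground-truth prompts for a scene).
#' @param target_fps Optional frame-rate downsampling before analysis.
#' @param qc_config,posture_config Pipeline settings.
#' @param use_truth For scenes only: skip rendering/segmentation and analyse
#'   the ground-truth observations (fast; default `FALSE`).
#' @param write_tracking_frames Write per-frame annotated PNG overlays
#'   (slow; default `FALSE`).
#' @return The `arena_analysis`, invisibly; side effect is the output tree.
#' @export
run_single <- function(input, out_dir, calibration = NULL, prompts = NULL,
                       target_fps = NULL,
                       qc_config = arenatrack::qc_config(),
                       posture_config = arenatrack::posture_config(),
                       use_truth = FALSE, write_tracking_frames = FALSE) {
  if (inherits(input, "scene")) {
    if (is.null(calibration)) {
      calibration <- calibration(input$spec$scale, input$spec$fps)
    }
    if (use_truth) {
      frames <- frames_from_truth(input)
      video <- NULL
    } else {
      video <- scene_video(input) # lazy: frames rendered on demand
      if (is.null(prompts)) prompts <- scene_prompts(input)
    }
  } else if (inherits(input, "frame_video") || inherits(input, "frame_stream")) {
    video <- input
    if (is.null(calibration)) stop("`calibration` is required", call. = FALSE)
    if (is.null(prompts)) stop("`prompts` are required", call. = FALSE)
  } else {
    stop("`input` must be a scene or a frame_video", call. = FALSE)
  }
  if (!is.null(target_fps) && !is.null(video)) {
    video <- downsample_fps(video, target_fps)
    calibration <- calibration(calibration$scale, target_fps)
  }
  if (!inherits(input, "scene") || !use_truth) {
    if (is.character(prompts)) prompts <- read_prompts_csv(prompts)
    frames <- segment_and_extract(video, prompts, calibration)
  }
  an <- analyze_observations(frames, calibration, qc_config, posture_config)
  write_output_tree(an, out_dir, video = if (isTRUE(write_tracking_frames))
    video else NULL)
  invisible(an)
}

write_output_tree <- function(an, out_dir, video = NULL) {
  dirs <- file.path(out_dir, c("raw_frames", "good_frames",
                               "problematic_frames", "paths",
                               "problematic_frames_visualisation"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  qc <- an$qc
  all_frames <- dplyr::bind_rows(qc$frames, qc$removed)
  log_lines <- character(0)
  for (oid in sort(unique(all_frames$object_id))) {
    tr <- dplyr::filter(all_frames, .data$object_id == oid)
    write_track_csv(tr, file.path(out_dir, "raw_frames",
                                  paste0(oid, ".csv")))
    if (!oid %in% qc$removed_ids) {
      write_track_csv(dplyr::filter(tr, !.data$flagged),
                      file.path(out_dir, "good_frames", paste0(oid, ".csv")))
    }
    prob <- dplyr::filter(tr, .data$flagged)
    if (oid %in% qc$removed_ids) prob <- tr
    if (nrow(prob) > 0L) {
      write_track_csv(prob, file.path(out_dir, "problematic_frames",
                                      paste0(oid, ".csv")))
    }
    if (!oid %in% qc$removed_ids) {
      p <- plot_paths(dplyr::filter(qc$frames, .data$object_id == oid))
      ggplot2::ggsave(file.path(out_dir, "paths", paste0(oid, ".png")), p,
                      width = 5, height = 5, dpi = 96)
      ps <- plot_problem_scatter(qc, oid)
      ggplot2::ggsave(file.path(out_dir, "problematic_frames_visualisation",
                                paste0(oid, ".png")), ps,
                      width = 6, height = 5, dpi = 96)
    }
    log_lines <- c(log_lines, sprintf("object %d: %d/%d frames flagged%s",
                                      oid, sum(tr$flagged), nrow(tr),
                                      if (oid %in% qc$removed_ids)
                                        " [removed: duplicate]" else ""))
  }
  readr::write_csv(an$summary, file.path(out_dir, "output.csv"))
  if (!is.null(video)) {
    render_tracking_frames(video, qc, file.path(out_dir, "tracking"))
  }
  writeLines(c(sprintf("tracks kept: %d; removed as duplicates: %d",
                       nrow(an$summary), length(qc$removed_ids)), log_lines),
             file.path(out_dir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(out_dir)
}

#' Batch-process several recordings
#'
#' Processes a named list of inputs (scenes or frame videos with prompts),
#' writing an independent output tree per entry under `out_dir/<name>/`. A
#' failure in one entry is logged and does not abort the batch.
#'
#' @param inputs Named list of inputs accepted by [run_single()].
#' @param out_dir Parent output directory.
#' @param ... Passed on to [run_single()].
#' @return Named list of `arena_analysis` objects (or `try-error` for
#'   failures), invisibly.
#' @export
run_batch <- function(inputs, out_dir, ...) {
  if (length(inputs) == 0L) stop("no inputs to process", call. = FALSE)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- sprintf("video_%03d", seq_along(inputs))
  }
  out <- purrr::imap(inputs, function(inp, nm) {
    tryCatch(run_single(inp, file.path(out_dir, nm), ...),
             error = function(e) {
               message(sprintf("batch entry '%s' failed: %s", nm,
                               conditionMessage(e)))
               structure(conditionMessage(e), class = "try-error")
             })
  })
  invisible(out)
}

#' Path tracing of one or more tracks, shaded by posture state
#'
#' Draws the centroid polyline of each track with a darker shade while the
#' animal is elongated and a lighter shade while it is bent.
#'
#' @param frames Observation tibble with `x_px`, `y_px`, `state`,
#'   `object_id`.
#' @return A ggplot object.
#' @export
plot_paths <- function(frames) {
  if (nrow(frames) == 0L) {
    warning("empty track: blank path canvas")
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  frames$state <- factor(
    ifelse(frames$state == "bent", "bent", "elongated"),
    levels = c("elongated", "bent"))
  ggplot2::ggplot(frames,
                  ggplot2::aes(x = .data$x_px, y = .data$y_px,
                               group = .data$object_id)) +
    ggplot2::geom_path(ggplot2::aes(colour = factor(.data$object_id),
                                    alpha = .data$state),
                       linewidth = 0.6) +
    ggplot2::scale_alpha_manual(values = c(elongated = 1, bent = 0.35)) +
    ggplot2::scale_y_reverse() + # image convention: y grows downward
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "object",
                  alpha = "state") +
    ggplot2::theme_minimal()
}

#' Size and speed scatterplots with problematic frames highlighted
#'
#' Two stacked panels (object size and speed versus frame) with the frames
#' removed by QC drawn in a highlight colour, one object at a time — the
#' diagnostic view used to decide whether a track should be omitted.
#'
#' @param qc A `qc_result`.
#' @param object_id Which track to plot.
#' @return A ggplot object.
#' @export
plot_problem_scatter <- function(qc, object_id) {
  stopifnot(inherits(qc, "qc_result"))
  df <- dplyr::bind_rows(qc$frames, qc$removed) |>
    dplyr::filter(.data$object_id == !!object_id) |>
    tidyr::pivot_longer(cols = c("area_mm2", "speed_mm_s"),
                        names_to = "signal", values_to = "value") |>
    dplyr::mutate(signal = dplyr::recode(.data$signal,
                                         area_mm2 = "size (mm^2)",
                                         speed_mm_s = "speed (mm/s)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$value,
                                   colour = .data$flagged)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 labels = c(`FALSE` = "kept",
                                            `TRUE` = "removed")) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL, colour = NULL,
                  title = sprintf("object %s", object_id)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_problem_scatter
#' @param object A `qc_result`.
#' @param ... Unused.
#' @export
autoplot.qc_result <- function(object, ...) {
  ids <- unique(object$frames$object_id)
  plot_problem_scatter(object, ids[1])
}

#' @rdname plot_paths
#' @param object An `arena_analysis`.
#' @param ... Unused.
#' @export
autoplot.arena_analysis <- function(object, ...) {
  plot_paths(object$qc$frames)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write annotated tracking frames
#'
#' Renders each video frame as a PNG with object outlines and id labels
#' overlaid — the frame-sequence equivalent of an annotated tracking video
#' (this environment carries no video encoder). Frame count is preserved;
#' a frame in which an id was not segmented simply lacks that overlay.
#'
#' @param video A [frame_video()].
#' @param qc A `qc_result` (for centroids and ids).
#' @param out_dir Directory for `frame_<n>.png` files.
#' @return `out_dir`, invisibly.
#' @export
render_tracking_frames <- function(video, qc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frames_tbl <- dplyr::bind_rows(qc$frames, qc$removed)
  pal <- grDevices::hcl.colors(max(10, length(unique(frames_tbl$object_id))),
                               "Dark 3")
  for (t in seq_len(video_n_frames(video))) {
    f <- video_get(video, t)
    grDevices::png(file.path(out_dir, sprintf("frame_%05d.png", t - 1L)),
                   width = ncol(f), height = nrow(f))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, ncol(f)), ylim = c(nrow(f), 0),
                          xaxs = "i", yaxs = "i")
    graphics::rasterImage(grDevices::as.raster(f / 255), 0, nrow(f),
                          ncol(f), 0)
    ft <- dplyr::filter(frames_tbl, .data$frame == t - 1L)
    for (r in seq_len(nrow(ft))) {
      col <- pal[(ft$object_id[r] %% length(pal)) + 1L]
      graphics::points(ft$x_px[r], ft$y_px[r], col = col, pch = 3)
      graphics::text(ft$x_px[r], ft$y_px[r] - 6, labels = ft$object_id[r],
                     col = col, cex = 0.8)
    }
    grDevices::dev.off()
  }
  invisible(out_dir)
}
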