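#' Per-frame displacement of a track
#'
#' Euclidean centroid displacement between consecutive frames, converted to
#' mm with the scale factor. Frame 0 has displacement 0 by convention.
#'
#' @param x_px,y_px Numeric centroid series in pixels, frame order.
#' @param calibration A [calibration()].
#' @return Numeric mm displacement series of the same length.
#' @export
frame_displacement <- function(x_px, y_px, calibration) {
  stopifnot(inherits(calibration, "calibration"), length(x_px) == length(y_px))
  n <- length(x_px)
  if (n == 0L) return(numeric(0))
  d <- c(0, sqrt(diff(x_px)^2 + diff(y_px)^2)) * calibration$scale
  d
}

#' Per-frame speed from displacements
#'
#' `speed_t = distance_t * fps`: displacement over one inter-frame interval.
#'
#' @param distance_mm Numeric per-frame displacement series (mm).
#' @param calibration A [calibration()].
#' @return Speeds in mm/s.
#' @export
frame_speed <- function(distance_mm, calibration) {
  stopifnot(inherits(calibration, "calibration"))
  distance_mm * calibration$fps
}

#' Add displacement and speed columns to an observation table
#'
#' Groups by `object_id` and computes per-frame `distance_mm` and
#' `speed_mm_s` from the pixel centroids. Rows must be frame-ordered within
#' each object (as produced by [extract_features()]).
#'
#' @param frames Observation tibble with `object_id`, `frame`, `x_px`, `y_px`.
#' @param calibration A [calibration()].
#' @return The input with `distance_mm` and `speed_mm_s` added.
#' @export
add_kinematics <- function(frames, calibration) {
  stopifnot(is.data.frame(frames),
            all(c("object_id", "frame", "x_px", "y_px") %in% names(frames)))
  frames |>
    dplyr::arrange(.data$object_id, .data$frame) |>
    dplyr::group_by(.data$object_id) |>
    dplyr::mutate(
      distance_mm = frame_displacement(.data$x_px, .data$y_px, calibration),
      speed_mm_s = frame_speed(.data$distance_mm, calibration)
    ) |>
    dplyr::ungroup()
}

#' Reference body length of a track
#'
#' The median ellipse major-axis length (mm) over *elongated* good frames —
#' an approximation of larval length used to length-normalise distance and
#' speed when genotypes differ in body size. Undefined (NA) when the track
#' has no elongated frame with a fitted ellipse.
#'
#' @param frames Observation rows of one track, with `ellipse_major_mm` and
#'   `state`.
#' @return Body length in mm, or `NA_real_`.
#' @export
body_length <- function(frames) {
  sel <- frames$state == "elongated" & is.finite(frames$ellipse_major_mm)
  if (!any(sel)) return(NA_real_)
  stats::median(frames$ellipse_major_mm[sel])
}

#' Aggregate per-track summaries over good frames
#'
#' Computes, per object, the total distance travelled, mean speed,
#' state-resolved time and distance, body length, and length-normalised
#' distance and speed, over the retained (QC-good) frames only. Gaps left by
#' frame removal are **not** bridged: displacement only accrues between
#' temporally consecutive retained frames, so excising frames shortens
#' distance, never lengthens it. Mean speed is the mean of retained
#' per-frame speeds (frame 0's conventional zero included).
#'
#' @param frames Observation tibble (good frames) with kinematics and
#'   posture columns; typically `good_frames(qc)`.
#' @param calibration A [calibration()].
#' @param frames_total Optional named lookup (or tibble) of total raw frame
#'   counts per object, used to report `frames_removed`; defaults to the
#'   rows present.
#' @param omit_fraction Flagged-frame fraction above which a track is
#'   recommended for omission from analysis (default 1/3).
#' @return A tibble, one row per `object_id`, with columns
#'   `total_distance_mm`, `mean_speed_mm_s`, `time_elongated_s`,
#'   `time_bent_s`, `distance_elongated_mm`, `mean_speed_elongated_mm_s`,
#'   `body_length_mm`, `normalised_distance`, `normalised_mean_speed`,
#'   `frames_total`, `frames_removed`, `omit_recommended`.
#' @export
summarise_tracks <- function(frames, calibration, frames_total = NULL,
                             omit_fraction = 1 / 3) {
  stopifnot(inherits(calibration, "calibration"))
  fps <- calibration$fps
  scale <- calibration$scale
  summarise_one <- function(df) {
    df <- dplyr::arrange(df, .data$frame)
    n <- nrow(df)
    if (n == 0L) {
      return(tibble::tibble(
        total_distance_mm = 0, mean_speed_mm_s = 0,
        time_elongated_s = 0, time_bent_s = 0,
        distance_elongated_mm = 0, mean_speed_elongated_mm_s = 0,
        body_length_mm = NA_real_, normalised_distance = NA_real_,
        normalised_mean_speed = NA_real_, frames_kept = 0L))
    }
    # displacement only between temporally consecutive retained frames
    consec <- c(FALSE, diff(df$frame) == 1L)
    step <- c(0, sqrt(diff(df$x_px)^2 + diff(df$y_px)^2)) * scale
    step[!consec] <- 0
    speed <- step * fps
    elong <- df$state == "elongated"
    bl <- body_length(df)
    total <- sum(step)
    msp <- mean(speed)
    tibble::tibble(
      total_distance_mm = total,
      mean_speed_mm_s = msp,
      time_elongated_s = sum(df$state == "elongated") / fps,
      time_bent_s = sum(df$state == "bent") / fps,
      distance_elongated_mm = sum(step[elong]),
      mean_speed_elongated_mm_s = if (any(elong)) mean(speed[elong]) else 0,
      body_length_mm = bl,
      normalised_distance = if (is.na(bl)) NA_real_ else total / bl,
      normalised_mean_speed = if (is.na(bl)) NA_real_ else msp / bl,
      frames_kept = n)
  }
  out <- frames |>
    dplyr::group_by(.data$object_id) |>
    dplyr::group_modify(~ summarise_one(.x)) |>
    dplyr::ungroup()
  tot <- if (is.null(frames_total)) {
    stats::setNames(out$frames_kept, out$object_id)
  } else if (is.data.frame(frames_total)) {
    stats::setNames(frames_total$frames_total, frames_total$object_id)
  } else {
    frames_total
  }
  out |>
    dplyr::mutate(
      frames_total = as.integer(tot[as.character(.data$object_id)]),
      frames_removed = .data$frames_total - .data$frames_kept,
      omit_recommended = .data$frames_removed / .data$frames_total > omit_fraction
    ) |>
    dplyr::select(-"frames_kept")
}
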