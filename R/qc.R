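#' Trajectory quality-control settings
#'
#' Every threshold of the tracking-error pipeline, all user-configurable.
#' Defaults follow the published pipeline: flag runs of identical object
#' size longer than 20 frames (detachment onto static background); absolute
#' frame-to-frame size steps greater than 1.5 mm^2 (collision merges);
#' gradual drift found with a 201-frame median filter, an 11-frame smoothed
#' difference signal and an 80-frame window in which at least 75% of entries
#' share one strict sign, kept only when the filtered size rises or falls by
#' more than 1 mm^2; segment medians differing by more than 1 mm^2 from a
#' baseline segment of at least 200 frames (identity switches); statistical
#' outliers beyond 4 size s.d. or 5 speed s.d.; and duplicate tracks whose
#' centroids match for more than 100 frames. Short inlier gaps within 20
#' frames of flanking outlier segments are infilled. All size/speed
#' comparisons are strict inequalities.
#'
#' @param static_run_min Frames; identical-size runs longer than this flag.
#' @param jump_threshold mm^2; strict frame-to-frame size-step threshold.
#' @param drift_median_kernel Odd frames; median-filter kernel for drift.
#' @param drift_smooth_kernel Odd frames; moving-average kernel for the
#'   differenced signal.
#' @param drift_window Frames; sliding window over the difference signal.
#' @param drift_fraction Proportion of one-signed entries a window needs.
#' @param drift_min_delta mm^2; required filtered-size change over a
#'   candidate drift segment (strict).
#' @param baseline_min_frames Frames; minimum baseline segment length for
#'   identity-switch detection.
#' @param segment_median_delta mm^2; strict median-difference threshold.
#' @param size_sd_limit,speed_sd_limit Standard-deviation multiples for the
#'   statistical outlier stage (strict). Note the published figure quotes
#'   4 s.d. for speed while the written pipeline uses 5; the default is 5.
#' @param duplicate_min_frames Frames; matched-centroid count above which a
#'   pair of tracks is a duplicate.
#' @param duplicate_match_tol_px Pixels; centroids closer than this count
#'   as identical for duplicate detection.
#' @param infill_radius Frames; inlier frames within this distance of two
#'   flanking outlier segments are re-flagged.
#' @param omit_fraction Flagged fraction above which a track is recommended
#'   for omission.
#' @return A `qc_config` list.
#' @export
qc_config <- function(static_run_min = 20,
                      jump_threshold = 1.5,
                      drift_median_kernel = 201,
                      drift_smooth_kernel = 11,
                      drift_window = 80,
                      drift_fraction = 0.75,
                      drift_min_delta = 1.0,
                      baseline_min_frames = 200,
                      segment_median_delta = 1.0,
                      size_sd_limit = 4,
                      speed_sd_limit = 5,
                      duplicate_min_frames = 100,
                      duplicate_match_tol_px = 0.5,
                      infill_radius = 20,
                      omit_fraction = 1 / 3) {
  cfg <- list(static_run_min = static_run_min, jump_threshold = jump_threshold,
              drift_median_kernel = drift_median_kernel,
              drift_smooth_kernel = drift_smooth_kernel,
              drift_window = drift_window, drift_fraction = drift_fraction,
              drift_min_delta = drift_min_delta,
              baseline_min_frames = baseline_min_frames,
              segment_median_delta = segment_median_delta,
              size_sd_limit = size_sd_limit, speed_sd_limit = speed_sd_limit,
              duplicate_min_frames = duplicate_min_frames,
              duplicate_match_tol_px = duplicate_match_tol_px,
              infill_radius = infill_radius, omit_fraction = omit_fraction)
  if (!all(vapply(cfg, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, logical(1)))) {
    stop("all qc_config values must be single positive numbers", call. = FALSE)
  }
  if (cfg$drift_median_kernel %% 2 != 1 || cfg$drift_smooth_kernel %% 2 != 1) {
    stop("drift kernels must be odd", call. = FALSE)
  }
  if (cfg$drift_fraction > 1 || cfg$omit_fraction > 1) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "qc_config")
}

#' Flag static-size runs (track detachment)
#'
#' A track locked onto static background keeps an exactly constant object
#' size; every maximal run of identical consecutive size values longer than
#' `static_run_min` frames is flagged. Sizes should be passed as exact
#' values (raw pixel counts) so float equality is not fragile.
#'
#' @param sizes Per-frame size series (pixel counts recommended).
#' @param config A [qc_config()].
#' @return Logical flag series.
#' @export
flag_static_size <- function(sizes, config = qc_config()) {
  n <- length(sizes)
  if (n == 0L) return(logical(0))
  r <- rle(sizes)
  rep(r$lengths > config$static_run_min, r$lengths)
}

#' Partition a flag series into inlier/outlier segments
#'
#' Maximal alternating runs of flagged and unflagged frames. Segments are
#' contiguous, ordered and cover the track.
#'
#' @param flags Logical per-frame flag series.
#' @return Tibble with `start_frame`, `end_frame` (0-based, inclusive) and
#'   `label` (`"inlier"`/`"outlier"`).
#' @export
segment_track <- function(flags) {
  if (length(flags) == 0L) {
    return(tibble::tibble(start_frame = integer(), end_frame = integer(),
                          label = character()))
  }
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  tibble::tibble(start_frame = as.integer(ends - r$lengths),
                 end_frame = as.integer(ends - 1L),
                 label = ifelse(r$values, "outlier", "inlier"))
}

#' Infill short inlier gaps between outlier segments
#'
#' An inlier frame bounded by outlier segments on *both* sides is re-flagged
#' when its distance to the end of the preceding outlier segment and to the
#' start of the following one are both at most `infill_radius` frames.
#' Leading and trailing inlier segments (one neighbour only) are never
#' infilled.
#'
#' @param flags Logical flag series.
#' @param config A [qc_config()].
#' @return Logical series marking the *newly* infilled frames.
#' @export
infill_flags <- function(flags, config = qc_config()) {
  n <- length(flags)
  fill <- logical(n)
  segs <- segment_track(flags)
  if (nrow(segs) < 3L) return(fill)
  r <- config$infill_radius
  for (i in seq_len(nrow(segs))) {
    if (segs$label[i] != "inlier") next
    if (i == 1L || i == nrow(segs)) next
    prev_end <- segs$end_frame[i - 1L]   # outlier
    next_start <- segs$start_frame[i + 1L]
    f <- (segs$start_frame[i]:segs$end_frame[i])
    hit <- (f - prev_end) <= r & (next_start - f) <= r
    fill[f[hit] + 1L] <- TRUE
  }
  fill
}

#' Flag abrupt size jumps (collision merges)
#'
#' Frame t is flagged when the absolute size difference to frame t-1 is
#' strictly greater than `jump_threshold` (mm^2) — the signature of two
#' animals merging under a single identity.
#'
#' @param sizes Per-frame size series in mm^2.
#' @param config A [qc_config()].
#' @return Logical flag series.
#' @export
flag_size_jump <- function(sizes, config = qc_config()) {
  n <- length(sizes)
  if (n < 2L) return(logical(n))
  c(FALSE, abs(diff(sizes)) > config$jump_threshold)
}

# filtered size signal for drift detection: m = reflect-padded running
# median; d = smoothed first difference of m
drift_signal <- function(sizes, config = qc_config()) {
  m <- reflect_runmed(sizes, config$drift_median_kernel)
  list(m = m, d = reflect_ma(diff(m), config$drift_smooth_kernel))
}

# reflect-padded running median, kernel clamped to the largest odd <= n
reflect_runmed <- function(x, k) {
  n <- length(x)
  k <- min(k, if (n %% 2 == 1) n else n - 1L)
  if (k <= 1L) return(x)
  h <- (k - 1L) / 2L
  pad <- c(rev(x[2:(h + 1L)]), x, rev(x[(n - h):(n - 1L)]))
  as.numeric(stats::runmed(pad, k, endrule = "keep"))[(h + 1L):(h + n)]
}

# reflect-padded centred moving average
reflect_ma <- function(x, k) {
  n <- length(x)
  k <- min(k, if (n %% 2 == 1) n else n - 1L)
  if (k <= 1L) return(x)
  h <- (k - 1L) / 2L
  pad <- c(rev(x[2:(h + 1L)]), x, rev(x[(n - h):(n - 1L)]))
  as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))[(h + 1L):(h + n)]
}

#' Flag gradual size drift (slow identity transfer)
#'
#' During prolonged contact an identity can creep from one animal to
#' another, producing a progressive one-directional change in object area.
#' The size series is median-filtered (`drift_median_kernel`, clamped to the
#' track length, reflect-padded), differenced, and the difference smoothed
#' (`drift_smooth_kernel`). A sliding `drift_window` is a drift candidate
#' when at least `drift_fraction` of its entries share one strict sign;
#' overlapping candidate windows merge into candidate segments, and a
#' segment is kept as flagged only when the filtered size changes by
#' strictly more than `drift_min_delta` mm^2 between its start and end.
#'
#' @param sizes Per-frame size series in mm^2.
#' @param config A [qc_config()].
#' @return Logical flag series.
#' @export
flag_size_drift <- function(sizes, config = qc_config()) {
  n <- length(sizes)
  out <- logical(n)
  W <- config$drift_window
  if (n < 2L || (n - 1L) < W) {
    message(sprintf("size-drift stage skipped: track length %d < window %d",
                    n, W))
    return(out)
  }
  sig <- drift_signal(sizes, config)
  m <- sig$m
  d <- sig$d
  nd <- length(d)
  cpos <- cumsum(c(0, d > 0))
  cneg <- cumsum(c(0, d < 0))
  i <- seq_len(nd - W + 1L)
  pos <- cpos[i + W] - cpos[i]
  neg <- cneg[i + W] - cneg[i]
  cand <- pmax(pos, neg) / W >= config$drift_fraction
  if (!any(cand)) return(out)
  # union of overlapping candidate windows, via a difference array
  delta <- integer(nd + 1L)
  ci <- i[cand]
  tb <- tabulate(ci, nbins = nd)
  te <- tabulate(ci + W, nbins = nd + 1L)
  cov <- cumsum(tb - te[seq_len(nd)]) > 0
  segs <- segment_track(cov)
  segs <- segs[segs$label == "outlier", , drop = FALSE]
  for (s in seq_len(nrow(segs))) {
    a <- segs$start_frame[s] + 1L      # d-index range (1-based)
    b <- segs$end_frame[s] + 1L
    f0 <- a; f1 <- b + 1L              # frame range covered by d[a..b]
    if (abs(m[f1] - m[f0]) > config$drift_min_delta) {
      out[f0:f1] <- TRUE
    }
  }
  out
}

#' Flag identity-switched segments by median size
#'
#' The first inlier segment with at least `baseline_min_frames` frames sets
#' the baseline median object size (if none qualifies the stage is skipped
#' with a notice). Every other inlier segment whose median size differs from
#' the baseline by strictly more than `segment_median_delta` mm^2 is flagged
#' in its entirety.
#'
#' @param sizes Per-frame size series in mm^2.
#' @param flags Current logical flag state (defines the segments).
#' @param config A [qc_config()].
#' @return Logical series marking newly flagged frames.
#' @export
flag_id_switch <- function(sizes, flags, config = qc_config()) {
  out <- logical(length(sizes))
  segs <- segment_track(flags)
  inl <- segs[segs$label == "inlier", , drop = FALSE]
  if (nrow(inl) == 0L) return(out)
  lens <- inl$end_frame - inl$start_frame + 1L
  bi <- which(lens >= config$baseline_min_frames)
  if (length(bi) == 0L) {
    message("id-switch stage skipped: no inlier segment reaches the baseline length")
    return(out)
  }
  bi <- bi[1]
  baseline <- stats::median(sizes[(inl$start_frame[bi]:inl$end_frame[bi]) + 1L])
  for (s in seq_len(nrow(inl))) {
    if (s == bi) next
    f <- (inl$start_frame[s]:inl$end_frame[s]) + 1L
    if (abs(stats::median(sizes[f]) - baseline) > config$segment_median_delta) {
      out[f] <- TRUE
    }
  }
  out
}

#' Flag statistical size and speed outliers
#'
#' Over the currently-inlier frames of a track, mean and standard deviation
#' of size and of speed are estimated (inliers only, so corruption caught by
#' earlier stages cannot inflate the moments); an inlier frame is flagged
#' when it lies strictly more than `size_sd_limit` size s.d. or
#' `speed_sd_limit` speed s.d. from the respective mean. A zero-variance
#' signal yields no flags.
#'
#' @param sizes Size series (mm^2).
#' @param speeds Speed series (mm/s).
#' @param flags Current logical flag state.
#' @param config A [qc_config()].
#' @return Character vector: `"none"`, `"size_outlier"` or `"speed_outlier"`
#'   per frame (size takes precedence when both trigger).
#' @export
flag_statistical_outliers <- function(sizes, speeds, flags,
                                      config = qc_config()) {
  n <- length(sizes)
  out <- rep("none", n)
  inl <- !flags
  if (sum(inl) < 2L) return(out)
  exceeds <- function(x, limit) {
    mu <- mean(x[inl], na.rm = TRUE)
    s <- stats::sd(x[inl], na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(logical(n))
    abs(x - mu) > limit * s & !is.na(x)
  }
  sp <- exceeds(speeds, config$speed_sd_limit)
  sz <- exceeds(sizes, config$size_sd_limit)
  out[inl & sp] <- "speed_outlier"
  out[inl & sz] <- "size_outlier"
  out
}

#' Detect duplicate tracks
#'
#' Pairwise, two tracks are duplicates when their centroids are identical
#' (within `duplicate_match_tol_px`) for strictly more than
#' `duplicate_min_frames` frames. The track with the more outlier frames is
#' removed; on a tie the track is assigned to the first (lower) object id.
#' On the removed track the matched region, widened by `infill_radius`
#' frames (the centroids do not always identically match), is flagged
#' `duplicate`.
#'
#' @param frames Observation tibble with `object_id`, `frame`, `x_px`,
#'   `y_px` and a logical `flagged` column (current state).
#' @param config A [qc_config()].
#' @return List with `removed_ids` (integer vector) and `duplicate_flags`
#'   (tibble `object_id`, `frame` of frames to flag as duplicates).
#' @export
detect_duplicates <- function(frames, config = qc_config()) {
  ids <- sort(unique(frames$object_id))
  removed <- integer(0)
  dup <- list()
  if (length(ids) < 2L) {
    return(list(removed_ids = removed,
                duplicate_flags = tibble::tibble(object_id = integer(),
                                                 frame = integer())))
  }
  tol <- config$duplicate_match_tol_px
  by_id <- split(frames, frames$object_id)
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      ia <- ids[a]; ib <- ids[b]
      if (ia %in% removed || ib %in% removed) next
      fa <- by_id[[as.character(ia)]]
      fb <- by_id[[as.character(ib)]]
      j <- dplyr::inner_join(
        dplyr::select(fa, "frame", xa = "x_px", ya = "y_px"),
        dplyr::select(fb, "frame", xb = "x_px", yb = "y_px"),
        by = "frame")
      match_f <- j$frame[sqrt((j$xa - j$xb)^2 + (j$ya - j$yb)^2) <= tol]
      if (length(match_f) <= config$duplicate_min_frames) next
      na_out <- sum(fa$flagged); nb_out <- sum(fb$flagged)
      loser <- if (nb_out >= na_out) ib else ia # tie -> keep first object
      removed <- c(removed, loser)
      lf <- by_id[[as.character(loser)]]$frame
      widened <- lf[lf >= (min(match_f) - config$infill_radius) &
                      lf <= (max(match_f) + config$infill_radius)]
      dup[[length(dup) + 1L]] <- tibble::tibble(object_id = loser,
                                                frame = widened)
    }
  }
  list(removed_ids = removed,
       duplicate_flags = if (length(dup)) purrr::list_rbind(dup) else
         tibble::tibble(object_id = integer(), frame = integer()))
}

#' Run the full trajectory quality-control pipeline
#'
#' Applies the six error detectors in their fixed published order —
#' static-size runs, segmenting + infilling, size jumps, size drift,
#' identity switches, statistical outliers (on remaining inliers) — per
#' track, then duplicate-track resolution across tracks and a final infill
#' pass. The stage order is not configurable (determinism).
#'
#' @param frames Observation tibble with one row per (object, frame) and
#'   columns `object_id`, `frame`, `x_px`, `y_px`, `area_mm2`, `speed_mm_s`
#'   (and optionally `area_px`, used for exact static-size equality).
#' @param config A [qc_config()].
#' @return An object of class `qc_result`: list with
#'   \describe{
#'     \item{frames}{retained tracks with `flagged` and `flag_reason`
#'       columns (`flag_reason` one of none, static_size, size_jump,
#'       size_drift, id_switch, size_outlier, speed_outlier, duplicate,
#'       infill);}
#'     \item{removed}{rows of duplicate-removed tracks, same columns;}
#'     \item{report}{per-track flag counts by reason, flagged fraction and
#'       omit recommendation;}
#'     \item{removed_ids, config}{bookkeeping.}
#'   }
#' @seealso [good_frames()], [problematic_frames()], [tidy.qc_result()],
#'   [autoplot.qc_result()]
#' @export
run_qc <- function(frames, config = qc_config()) {
  stopifnot(is.data.frame(frames))
  need <- c("object_id", "frame", "x_px", "y_px", "area_mm2", "speed_mm_s")
  miss <- setdiff(need, names(frames))
  if (length(miss)) {
    stop("run_qc: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  frames <- dplyr::arrange(frames, .data$object_id, .data$frame)

  qc_one <- function(df) {
    n <- nrow(df)
    reason <- rep("none", n)
    static_sizes <- if ("area_px" %in% names(df)) df$area_px else df$area_mm2
    # 1. static size
    st <- flag_static_size(static_sizes, config)
    reason[st] <- "static_size"
    # 2. segment + infill
    inf1 <- infill_flags(reason != "none", config)
    reason[inf1 & reason == "none"] <- "infill"
    # 3. size jump
    jp <- flag_size_jump(df$area_mm2, config)
    reason[jp & reason == "none"] <- "size_jump"
    # 4. size drift
    dr <- suppressMessages(flag_size_drift(df$area_mm2, config))
    reason[dr & reason == "none"] <- "size_drift"
    # 5. identity switch
    sw <- suppressMessages(
      flag_id_switch(df$area_mm2, reason != "none", config))
    reason[sw & reason == "none"] <- "id_switch"
    # 6. statistical outliers on remaining inliers
    so <- flag_statistical_outliers(df$area_mm2, df$speed_mm_s,
                                    reason != "none", config)
    reason[so != "none" & reason == "none"] <- so[so != "none" & reason == "none"]
    reason
  }

  frames <- frames |>
    dplyr::group_by(.data$object_id) |>
    dplyr::mutate(flag_reason = qc_one(dplyr::pick(dplyr::everything())),
                  flagged = .data$flag_reason != "none") |>
    dplyr::ungroup()

  # 7. duplicates across tracks
  dup <- detect_duplicates(frames, config)
  if (nrow(dup$duplicate_flags)) {
    key <- paste(dup$duplicate_flags$object_id, dup$duplicate_flags$frame)
    hit <- paste(frames$object_id, frames$frame) %in% key
    frames$flag_reason[hit] <- "duplicate"
    frames$flagged[hit] <- TRUE
  }
  # 8. final infill pass over the combined flag state
  frames <- frames |>
    dplyr::group_by(.data$object_id) |>
    dplyr::mutate(.fill = infill_flags(.data$flagged, config),
                  flag_reason = ifelse(.data$.fill & !.data$flagged,
                                       "infill", .data$flag_reason),
                  flagged = .data$flagged | .data$.fill) |>
    dplyr::ungroup() |>
    dplyr::select(-".fill")

  removed <- dplyr::filter(frames, .data$object_id %in% dup$removed_ids)
  kept <- dplyr::filter(frames, !.data$object_id %in% dup$removed_ids)

  report <- kept |>
    dplyr::group_by(.data$object_id) |>
    dplyr::summarise(
      frames_total = dplyr::n(),
      frames_flagged = sum(.data$flagged),
      static_size = sum(.data$flag_reason == "static_size"),
      size_jump = sum(.data$flag_reason == "size_jump"),
      size_drift = sum(.data$flag_reason == "size_drift"),
      id_switch = sum(.data$flag_reason == "id_switch"),
      size_outlier = sum(.data$flag_reason == "size_outlier"),
      speed_outlier = sum(.data$flag_reason == "speed_outlier"),
      duplicate = sum(.data$flag_reason == "duplicate"),
      infill = sum(.data$flag_reason == "infill"),
      flagged_fraction = .data$frames_flagged / .data$frames_total,
      omit_recommended = .data$flagged_fraction > config$omit_fraction,
      .groups = "drop")

  structure(list(frames = kept, removed = removed, report = report,
                 removed_ids = dup$removed_ids, config = config),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d tracks kept, %d removed as duplicates\n",
              length(unique(x$frames$object_id)), length(x$removed_ids)))
  cat(sprintf("  %d / %d frames flagged (%.1f%%); %d track(s) recommended for omission\n",
              sum(x$report$frames_flagged), sum(x$report$frames_total),
              100 * sum(x$report$frames_flagged) / sum(x$report$frames_total),
              sum(x$report$omit_recommended)))
  invisible(x)
}

#' Retained (good) frames of a QC result
#' @param qc A `qc_result`.
#' @return Tibble of unflagged frames of retained tracks.
#' @export
good_frames <- function(qc) {
  stopifnot(inherits(qc, "qc_result"))
  dplyr::filter(qc$frames, !.data$flagged)
}

#' Problematic (flagged) frames of a QC result
#' @param qc A `qc_result`.
#' @param include_removed Also include frames of duplicate-removed tracks.
#' @return Tibble of flagged frames.
#' @export
problematic_frames <- function(qc, include_removed = TRUE) {
  stopifnot(inherits(qc, "qc_result"))
  out <- dplyr::filter(qc$frames, .data$flagged)
  if (include_removed && nrow(qc$removed)) {
    out <- dplyr::bind_rows(out, qc$removed)
  }
  out
}

#' Tidy a QC result into per-track flag counts
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return Long tibble: `object_id`, `flag_reason`, `n_frames`.
#' @export
tidy.qc_result <- function(x, ...) {
  x$report |>
    tidyr::pivot_longer(
      cols = c("static_size", "size_jump", "size_drift", "id_switch",
               "size_outlier", "speed_outlier", "duplicate", "infill"),
      names_to = "flag_reason", values_to = "n_frames") |>
    dplyr::select("object_id", "flag_reason", "n_frames")
}

#' One-row summary of a QC result
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return Tibble with track/frame counts, flagged fraction and the number
#'   of removal/omission decisions.
#' @export
glance.qc_result <- function(x, ...) {
  tibble::tibble(
    n_tracks = nrow(x$report),
    n_removed_tracks = length(x$removed_ids),
    n_frames = sum(x$report$frames_total),
    n_flagged = sum(x$report$frames_flagged),
    flagged_fraction = sum(x$report$frames_flagged) / sum(x$report$frames_total),
    n_omit_recommended = sum(x$report$omit_recommended))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
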