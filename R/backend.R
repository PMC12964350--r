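#' Construct an in-memory grayscale video
#'
#' Videos are represented as a list of grayscale frame matrices (`[row,
#' col]`, values 0-255, pixel `(x, y) = (col-1, row-1)`) plus a frame rate.
#' Decoding MP4/MOV/AVI containers is delegated to whatever produced the
#' frames (a foundation-model adapter, an external decoder, or the built-in
#' synthetic renderer); everything downstream of the backend contract is
#' format-agnostic.
#'
#' @param frames List of numeric matrices with identical dimensions.
#' @param fps Frames per second.
#' @return A `frame_video` object.
#' @export
frame_video <- function(frames, fps) {
  stopifnot(is.list(frames), is.numeric(fps), fps > 0)
  if (length(frames) > 0L) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == d),
                 logical(1))
    if (!all(ok)) stop("all frames must be matrices of identical dimensions",
                       call. = FALSE)
  }
  structure(list(frames = frames, fps = as.numeric(fps)),
            class = "frame_video")
}

#' @export
print.frame_video <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0)
  cat(sprintf("<frame_video> %d frames, %dx%d px, %.6g fps\n",
              length(x$frames), d[2], d[1], x$fps))
  invisible(x)
}

#' Downsample a video to a lower frame rate
#'
#' High capture rates (~30 fps) oversample slow larval motion and inflate
#' path length through jitter; downsampling to ~10 fps before analysis
#' removes the overhead with no loss of tracking resolution. Retains every
#' `round(source_fps / target_fps)`-th frame starting at frame 0, so the
#' output has `ceiling(n / stride)` frames.
#'
#' @param video A [frame_video()].
#' @param target_fps Target frame rate; must not exceed the source rate.
#' @return A `frame_video` at the target rate.
#' @export
downsample_fps <- function(video, target_fps) {
  stopifnot(inherits(video, "frame_video") || inherits(video, "frame_stream"))
  if (!is.numeric(target_fps) || target_fps <= 0) {
    stop("`target_fps` must be positive", call. = FALSE)
  }
  if (target_fps > video$fps) {
    stop("`target_fps` exceeds the source frame rate", call. = FALSE)
  }
  stride <- max(1L, as.integer(round(video$fps / target_fps)))
  keep <- seq(1L, video_n_frames(video), by = stride)
  if (inherits(video, "frame_stream")) {
    out <- video
    out$index <- video$index[keep]
    out$n_frames <- length(keep)
    out$fps <- target_fps
    return(out)
  }
  frame_video(video$frames[keep], target_fps)
}

# Accessors working for both in-memory frame_video and lazy frame_stream
video_n_frames <- function(v) {
  if (inherits(v, "frame_stream")) v$n_frames else length(v$frames)
}
video_get <- function(v, i) {
  if (inherits(v, "frame_stream")) v$frame_fn(v$index[i]) else v$frames[[i]]
}
video_dim <- function(v) {
  if (inherits(v, "frame_stream")) v$dim else
    if (length(v$frames)) dim(v$frames[[1]]) else c(0L, 0L)
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames, %dx%d px, %.6g fps (lazy)\n",
              x$n_frames, x$dim[2], x$dim[1], x$fps))
  invisible(x)
}

# Automatic threshold for bright objects on a dark arena: Otsu's bimodal
# split, applied recursively when the scene is trimodal (dark surround,
# arena disc, bright animals) and the first split only separates the
# surround — detected as an implausibly large foreground fraction.
select_threshold <- function(frame, max_fg = 0.2, max_iter = 3L) {
  v <- as.vector(frame)
  thr <- otsu_threshold(v)
  for (i in seq_len(max_iter)) {
    fg <- v > thr
    if (mean(fg) <= max_fg) break
    thr <- otsu_threshold(v[fg])
  }
  thr
}

# Otsu's automatic bimodal threshold on a 0-255 grayscale frame.
otsu_threshold <- function(frame) {
  v <- as.integer(round(as.vector(frame)))
  v[v < 0L] <- 0L; v[v > 255L] <- 255L
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  wb <- as.numeric(cumsum(h))
  sb <- cumsum(as.numeric(h) * lev)
  total <- sb[256]
  wf <- n - wb
  mb <- sb / wb
  mf <- (total - sb) / wf
  between <- wb * wf * (mb - mf)^2
  between[!is.finite(between)] <- -Inf
  lev[which.max(between)] + 0.5
}

#' Read point prompts from CSV
#'
#' Prompt files have the header `object_id,x,y,frame` with 0-based pixel
#' coordinates on the annotation frame (default frame 0).
#'
#' @param path CSV file path.
#' @return Tibble with `object_id`, `x`, `y`, `frame`.
#' @export
read_prompts_csv <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("object_id", "x", "y")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("prompts file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"frame" %in% names(p)) p$frame <- 0L
  tibble::as_tibble(p)
}

# Per-frame segmentation state: threshold, components, size filter.
frame_components <- function(frame, min_area, max_area) {
  thr <- select_threshold(frame)
  mask <- frame > thr
  runs <- cc_runs(mask)
  if (is.null(runs)) return(NULL)
  st <- component_stats(runs)
  st <- st[st$area_px >= min_area & st$area_px <= max_area, , drop = FALSE]
  if (nrow(st) == 0L) return(NULL)
  list(runs = runs, stats = st, dim = dim(frame))
}

# Greedy nearest-centroid assignment of known ids to frame components.
# last: tibble object_id, x_px, y_px. st: component stats. Returns tibble
# object_id, component for matches within max_dist.
greedy_match <- function(last, st, max_dist) {
  if (nrow(last) == 0L || nrow(st) == 0L) {
    return(tibble::tibble(object_id = integer(), component = integer()))
  }
  dm <- outer(seq_len(nrow(last)), seq_len(nrow(st)),
              function(i, j) sqrt((last$x_px[i] - st$x_px[j])^2 +
                                    (last$y_px[i] - st$y_px[j])^2))
  out_id <- integer(0); out_comp <- integer(0)
  repeat {
    mn <- min(dm)
    if (!is.finite(mn) || mn > max_dist) break
    w <- which(dm == mn, arr.ind = TRUE)[1, ]
    out_id <- c(out_id, last$object_id[w[1]])
    out_comp <- c(out_comp, st$component[w[2]])
    dm[w[1], ] <- Inf
    dm[, w[2]] <- Inf
  }
  tibble::tibble(object_id = out_id, component = out_comp)
}

# Shared driver for the reference backend. `emit` is called once per
# (frame, object) with the component's runs/bbox so callers can either
# store the mask or extract features immediately (streaming).
reference_backend_drive <- function(video, prompts, min_area, max_area,
                                    max_match_distance, emit) {
  n <- video_n_frames(video)
  if (n == 0L) stop("empty video", call. = FALSE)
  f0 <- unique(prompts$frame)
  if (length(f0) != 1L) {
    stop("reference backend expects all prompts on a single annotation frame",
         call. = FALSE)
  }
  f0 <- as.integer(f0)
  if (f0 != 0L) {
    message("reference backend propagates forward only; frames before the ",
            "annotation frame are left unsegmented")
  }
  fc <- frame_components(video_get(video, f0 + 1L), min_area, max_area)
  if (is.null(fc)) stop("no foreground components on the annotation frame",
                        call. = FALSE)
  assign0 <- integer(nrow(prompts))
  for (i in seq_len(nrow(prompts))) {
    k <- component_at(fc$runs, prompts$x[i], prompts$y[i])
    if (is.na(k) || !k %in% fc$stats$component) {
      stop(sprintf(
        "unresolvable prompt: object %d at (%g, %g) is not inside any component",
        prompts$object_id[i], prompts$x[i], prompts$y[i]), call. = FALSE)
    }
    assign0[i] <- k
  }
  if (anyDuplicated(assign0)) {
    stop("two prompts fall inside the same component", call. = FALSE)
  }
  if (is.null(max_match_distance)) {
    areas <- fc$stats$area_px[match(assign0, fc$stats$component)]
    max_match_distance <- 5 * mean(sqrt(areas / pi))
  }
  last <- tibble::tibble(object_id = as.integer(prompts$object_id),
                         x_px = NA_real_, y_px = NA_real_)
  for (fi in (f0 + 1L):n) { # 1-based frame index into the video
    fcur <- if (fi == f0 + 1L) fc else
      frame_components(video_get(video, fi), min_area, max_area)
    if (is.null(fcur)) next
    st <- fcur$stats
    if (fi == f0 + 1L) {
      match_tbl <- tibble::tibble(object_id = as.integer(prompts$object_id),
                                  component = assign0)
    } else {
      match_tbl <- greedy_match(last, st, max_match_distance)
    }
    for (r in seq_len(nrow(match_tbl))) {
      id <- match_tbl$object_id[r]
      k <- match_tbl$component[r]
      srow <- st[st$component == k, ]
      li <- which(last$object_id == id)
      last$x_px[li] <- srow$x_px
      last$y_px[li] <- srow$y_px
      emit(fi - 1L, id, fcur$runs, k, fcur$dim)
    }
  }
  invisible(NULL)
}

#' Segment a video with the classical reference backend
#'
#' The reference backend stands behind the same contract a foundation-model
#' adapter would implement: given point prompts on one annotation frame it
#' returns one binary mask per object per frame. It thresholds each frame
#' automatically (Otsu), labels connected components, filters them to an
#' area range, assigns identities on the annotation frame by
#' prompt-in-component, and propagates identities forward by greedy
#' nearest-centroid matching under a maximum match distance (default 5x the
#' mean blob radius on the annotation frame). An id with no acceptable
#' match in a frame is simply absent from that frame; downstream QC deals
#' with the gap. The backend is deterministic.
#'
#' @param video A [frame_video()].
#' @param prompts Tibble `object_id`, `x`, `y`, `frame` (one annotation
#'   frame), or a path to a prompts CSV.
#' @param min_area,max_area Component area filter in pixels.
#' @param max_match_distance Maximum centroid displacement (px) between
#'   consecutive frames; `NULL` for the default.
#' @return A `segmentation_result`: list with `masks` (per frame, a named
#'   list mapping object id to logical mask) and `prompts`.
#' @export
segment_video <- function(video, prompts, min_area = 20, max_area = Inf,
                          max_match_distance = NULL) {
  stopifnot(inherits(video, "frame_video") || inherits(video, "frame_stream"))
  if (is.character(prompts)) prompts <- read_prompts_csv(prompts)
  masks <- replicate(video_n_frames(video), list(), simplify = FALSE)
  reference_backend_drive(video, prompts, min_area, max_area,
                          max_match_distance,
                          emit = function(frame0, id, runs, k, dm) {
    m <- runs_to_mask(runs, k, dm)
    masks[[frame0 + 1L]][[as.character(id)]] <<- m
  })
  structure(list(masks = masks, prompts = prompts,
                 n_frames = video_n_frames(video)),
            class = "segmentation_result")
}

#' Segment a video and extract features in one streaming pass
#'
#' Equivalent to `extract_features(segment_video(...), calibration)` but
#' never materialises per-frame masks for the whole video, so long
#' recordings fit in memory.
#'
#' @inheritParams segment_video
#' @param calibration A [calibration()].
#' @return Observation tibble as from [extract_features()].
#' @export
segment_and_extract <- function(video, prompts, calibration, min_area = 20,
                                max_area = Inf, max_match_distance = NULL) {
  stopifnot(inherits(video, "frame_video") || inherits(video, "frame_stream"),
            inherits(calibration, "calibration"))
  if (is.character(prompts)) prompts <- read_prompts_csv(prompts)
  acc <- vector("list", video_n_frames(video) * nrow(prompts))
  n_acc <- 0L
  reference_backend_drive(video, prompts, min_area, max_area,
                          max_match_distance,
                          emit = function(frame0, id, runs, k, dm) {
    sel <- runs$comp == k
    c0 <- min(runs$col[sel]); c1 <- max(runs$col[sel])
    r0 <- min(runs$r0[sel]); r1 <- max(runs$r1[sel])
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    for (i in which(sel)) {
      sub[(runs$r0[i]:runs$r1[i]) - r0 + 1L, runs$col[i] - c0 + 1L] <- TRUE
    }
    ft <- mask_features(sub, calibration)
    ft$x_px <- ft$x_px + (c0 - 1L)
    ft$y_px <- ft$y_px + (r0 - 1L)
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- dplyr::mutate(ft, frame = frame0,
                                   object_id = as.integer(id), .before = 1)
  })
  purrr::list_rbind(acc[seq_len(n_acc)]) |>
    dplyr::select(-"n_components") |>
    dplyr::arrange(.data$object_id, .data$frame)
}

#' Validate a segmentation result against the backend contract
#'
#' Any backend (reference or foundation-model adapter) must produce: one
#' entry per video frame; masks shaped like the frames; strictly binary
#' masks; and every prompted id present on the annotation frame.
#'
#' @param result A `segmentation_result`.
#' @param video The [frame_video()] that was segmented.
#' @param prompts The prompts used.
#' @return List with `pass` (logical) and `messages` (character).
#' @export
backend_contract_check <- function(result, video, prompts) {
  msgs <- character(0)
  if (!inherits(result, "segmentation_result") || !is.list(result$masks)) {
    return(list(pass = FALSE, messages = "not a segmentation_result"))
  }
  if (length(result$masks) != video_n_frames(video)) {
    msgs <- c(msgs, sprintf("mask list has %d entries for %d frames",
                            length(result$masks), video_n_frames(video)))
  }
  d <- if (video_n_frames(video)) video_dim(video) else NULL
  f0 <- unique(prompts$frame)[1] + 1L
  if (f0 <= length(result$masks)) {
    have <- names(result$masks[[f0]])
    want <- as.character(prompts$object_id)
    missing_ids <- setdiff(want, have)
    if (length(missing_ids)) {
      msgs <- c(msgs, paste("annotation frame missing id(s):",
                            paste(missing_ids, collapse = ", ")))
    }
  }
  for (fi in seq_along(result$masks)) {
    for (id in names(result$masks[[fi]])) {
      m <- result$masks[[fi]][[id]]
      if (!is.null(d) && !all(dim(m) == d)) {
        msgs <- c(msgs, sprintf("frame %d id %s: mask shape mismatch", fi - 1L, id))
      }
      if (!(is.logical(m) || all(m %in% c(0, 1)))) {
        msgs <- c(msgs, sprintf("frame %d id %s: mask is not binary", fi - 1L, id))
      }
    }
  }
  list(pass = length(msgs) == 0L, messages = msgs)
}
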