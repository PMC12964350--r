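#' Extract the outer polygon of the largest object in a binary mask
#'
#' Traces the outer boundary of the largest 8-connected foreground component
#' with Moore neighbour tracing, returning an ordered vertex list of pixel
#' centres (consistent winding). If the mask holds several components the
#' largest is kept and a warning records the fact; collisions and split
#' masks are dealt with downstream by trajectory QC, not here.
#'
#' @param mask Logical or 0/1 numeric matrix; `[row, col]` indexing, pixel
#'   `(x, y) = (col-1, row-1)`.
#' @return A two-column matrix (`x`, `y`) of ordered boundary pixel centres.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[3:8, 3:8] <- TRUE
#' poly <- mask_to_polygon(m)
#' polygon_centroid(poly)
#' @export
mask_to_polygon <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask)) stop("Empty object: mask has no foreground pixels.", call. = FALSE)
  runs <- cc_runs(mask)
  k <- which.max(runs$comp_sizes)
  if (length(runs$comp_sizes) > 1L) {
    warning(sprintf(
      "mask has %d foreground components; keeping the largest (%d px)",
      length(runs$comp_sizes), as.integer(runs$comp_sizes[k])))
  }
  comp <- runs_to_mask(runs, k, dim(mask))
  trace_boundary(comp)
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion.
# `mask` must contain exactly one 8-connected component.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad by one pixel so neighbour lookups never leave the matrix
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # clockwise Moore neighbourhood starting W, in (drow, dcol):
  # W, NW, N, NE, E, SE, S, SW  (N = smaller row = smaller y)
  dro <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dco <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  # start: first foreground pixel in row-major scan (topmost, then leftmost)
  fg <- which(pad, arr.ind = TRUE)
  ord <- order(fg[, 1], fg[, 2])
  s <- fg[ord[1], ]
  if (nrow(fg) == 1L) {
    return(matrix(c(s[2] - 2L, s[1] - 2L), ncol = 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  bx <- c(s[1], s[2] - 1L) # backtrack: the W neighbour (background by scan order)
  cur <- c(s[1], s[2])
  start <- cur; start_back <- bx
  out_r <- integer(0); out_c <- integer(0)
  out_r <- cur[1]; out_c <- cur[2]
  max_steps <- 4L * (nr + nc) * 8L + 64L
  for (step in seq_len(max_steps)) {
    # index of backtrack pixel within cur's clockwise neighbourhood
    rel <- c(bx[1] - cur[1], bx[2] - cur[2])
    k0 <- which(dro == rel[1] & dco == rel[2])
    found <- FALSE
    for (j in 1:8) {
      kk <- ((k0 - 1L + j) %% 8L) + 1L
      nb <- c(cur[1] + dro[kk], cur[2] + dco[kk])
      if (pad[nb[1], nb[2]]) {
        kprev <- ((k0 - 1L + j - 1L) %% 8L) + 1L
        bx <- c(cur[1] + dro[kprev], cur[2] + dco[kprev])
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (cur[1] == start[1] && cur[2] == start[2] &&
        bx[1] == start_back[1] && bx[2] == start_back[2]) break
    out_r <- c(out_r, cur[1]); out_c <- c(out_c, cur[2])
  }
  cbind(x = out_c - 2L, y = out_r - 2L) # unpad and convert to 0-based (x, y)
}

#' Area centroid of a polygon
#'
#' Shoelace-formula centroid of an ordered polygon. A degenerate polygon
#' (zero signed area, e.g. collinear vertices) falls back to the vertex mean
#' with a warning.
#'
#' @param polygon Two-column matrix of ordered vertices (`x`, `y`).
#' @return Numeric `c(x, y)`.
#' @export
polygon_centroid <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) {
    warning("degenerate (zero-area) polygon; falling back to vertex mean")
    return(c(x = mean(x), y = mean(y)))
  }
  c(x = sum((x + xn) * cross) / (6 * a), y = sum((y + yn) * cross) / (6 * a))
}

#' Calibrated mask area
#'
#' Object size is the foreground pixel count converted to mm^2 with the
#' squared scale factor.
#'
#' @param mask Binary matrix.
#' @param calibration A [calibration()].
#' @return Area in mm^2 (0 for an empty mask).
#' @export
mask_area <- function(mask, calibration) {
  stopifnot(inherits(calibration, "calibration"))
  sum(as_binary_mask(mask)) * calibration$scale^2
}

#' Fit an ellipse to an object contour
#'
#' Direct least-squares conic fit (numerically stable Halir-Flusser variant)
#' to the contour points, reported as centre, full major/minor axis lengths
#' (diameters, not semi-axes) and orientation in degrees within `[0, 180)`
#' (orientation is axial). Axes are swapped if needed so `major >= minor`.
#'
#' @param contour Two-column matrix of contour points (`x`, `y`), at least 5.
#' @return An object of class `ellipse_fit`: list with `center`, `major`,
#'   `minor`, `angle`.
#' @export
fit_object_ellipse <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 5L) {
    stop("unfittable object: ellipse fit needs at least 5 contour points",
         call. = FALSE)
  }
  x <- contour[, 1]; y <- contour[, 2]
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my # centre for conditioning
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, rep(1, length(xs)))
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) stop("unfittable object: singular contour geometry", call. = FALSE)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  va <- Re(ev$vectors)
  cond <- 4 * va[1, ] * va[3, ] - va[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0L) stop("unfittable object: no elliptical solution", call. = FALSE)
  a1 <- va[, idx[1]]
  coef <- c(a1, as.vector(Tm %*% a1)) # A B C D E F in centred coords
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Ff <- coef[6]
  den <- B^2 - 4 * A * C
  xc <- (2 * C * D - B * E) / den
  yc <- (2 * A * E - B * D) / den
  Fc <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + Ff
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  if (-Fc < 0) { Q <- -Q; Fc <- -Fc } # normalise sign so Q is pos. definite
  eq <- eigen(Q, symmetric = TRUE)
  if (any(eq$values <= 0) || -Fc <= 0) {
    stop("unfittable object: degenerate conic", call. = FALSE)
  }
  semi <- sqrt(-Fc / eq$values) # eigenvalues descending -> semi ascending
  major <- 2 * max(semi); minor <- 2 * min(semi)
  vec_major <- eq$vectors[, which.min(eq$values)]
  ang <- atan2(vec_major[2], vec_major[1]) * 180 / pi
  ang <- ang %% 180
  structure(list(center = c(x = xc + mx, y = yc + my),
                 major = major, minor = minor, angle = ang),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> centre (%.2f, %.2f), axes %.2f x %.2f px, %.1f deg\n",
              x$center[1], x$center[2], x$major, x$minor, x$angle))
  invisible(x)
}

#' Major-to-minor axis ratio of a fitted ellipse
#'
#' R = a / b with `a` the major and `b` the minor full axis length; always
#' at least 1. The per-track distribution of R drives posture
#' classification: an elongated crawling larva has large R, a head-casting
#' (bent) one is rounder.
#'
#' @param ellipse An `ellipse_fit`.
#' @return The ratio R >= 1.
#' @export
axis_ratio <- function(ellipse) {
  stopifnot(inherits(ellipse, "ellipse_fit"))
  if (ellipse$minor <= 0) stop("undefined ratio: minor axis is zero", call. = FALSE)
  ellipse$major / ellipse$minor
}

# Full per-object feature row from a single-object mask. Returns a one-row
# tibble; ellipse columns are NA when the contour cannot support a fit.
mask_features <- function(mask, calibration) {
  runs <- cc_runs(mask)
  if (is.null(runs)) stop("Empty object: mask has no foreground pixels.", call. = FALSE)
  k <- which.max(runs$comp_sizes)
  n_comp <- length(runs$comp_sizes)
  comp <- runs_to_mask(runs, k, dim(mask))
  contour <- trace_boundary(comp)
  cen <- if (nrow(contour) >= 3L) {
    suppressWarnings(polygon_centroid(contour))
  } else {
    c(mean(contour[, 1]), mean(contour[, 2]))
  }
  area_px <- sum(comp)
  fit <- tryCatch(fit_object_ellipse(contour), error = function(e) NULL)
  s <- calibration$scale
  tibble::tibble(
    x_px = as.numeric(cen[1]), y_px = as.numeric(cen[2]),
    area_px = as.numeric(area_px), area_mm2 = area_px * s^2,
    ellipse_major_mm = if (is.null(fit)) NA_real_ else fit$major * s,
    ellipse_minor_mm = if (is.null(fit)) NA_real_ else fit$minor * s,
    ratio = if (is.null(fit)) NA_real_ else axis_ratio(fit),
    angle_deg = if (is.null(fit)) NA_real_ else fit$angle,
    n_components = n_comp
  )
}

#' Convert per-frame object masks into a calibrated observation table
#'
#' Takes a segmentation result (see [segment_video()]): a list over frames,
#' each frame a named list mapping object id to a binary mask. Produces one
#' row per (object, frame) with centroid, area, ellipse axes, axis ratio and
#' orientation, in pixels and calibrated units.
#'
#' @param segmentation A `segmentation_result` or a bare list of per-frame
#'   named mask lists.
#' @param calibration A [calibration()].
#' @return A tibble with columns `frame` (0-based), `object_id`, `x_px`,
#'   `y_px`, `area_px`, `area_mm2`, `ellipse_major_mm`, `ellipse_minor_mm`,
#'   `ratio`, `angle_deg`.
#' @export
extract_features <- function(segmentation, calibration) {
  frames <- if (inherits(segmentation, "segmentation_result")) {
    segmentation$masks
  } else {
    segmentation
  }
  rows <- purrr::map(seq_along(frames), function(fi) {
    objs <- frames[[fi]]
    if (length(objs) == 0L) return(NULL)
    ids <- names(objs)
    purrr::map2(objs, ids, function(m, id) {
      ft <- mask_features(m, calibration)
      dplyr::mutate(ft, frame = fi - 1L, object_id = as.integer(id),
                    .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (any(rows$n_components > 1L)) {
    warning(sprintf("%d frames had multi-component masks; largest kept",
                    sum(rows$n_components > 1L)))
  }
  dplyr::select(rows, -"n_components") |>
    dplyr::arrange(.data$object_id, .data$frame)
}
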