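#' Create a spatial/temporal calibration
#'
#' A calibration couples the mm-per-pixel scale factor of the recording with
#' its frame rate. Lengths convert with `scale`, areas with `scale^2`, and
#' per-frame displacements convert to speeds with `fps`.
#'
#' @param scale Millimetres per pixel. Strictly positive.
#' @param fps Frames per second of the analysed video. Strictly positive.
#'
#' @return An object of class `calibration`: a list with elements `scale`
#'   and `fps`.
#' @examples
#' cal <- calibration(scale = 0.1, fps = 10)
#' cal$scale^2 * 100  # area of a 100-pixel mask in mm^2
#' @export
calibration <- function(scale, fps = 10) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number (mm per pixel).", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive number.", call. = FALSE)
  }
  structure(list(scale = as.numeric(scale), fps = as.numeric(fps)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6g mm/px, %.6g fps\n", x$scale, x$fps))
  invisible(x)
}

#' Compute the mm-per-pixel scale factor from two reference points
#'
#' Mirrors the interactive calibration step of arena trackers: the user marks
#' two pixel positions a known physical distance apart (e.g. the ends of a
#' ruler captured in frame) and the scale factor is the known distance divided
#' by the pixel distance.
#'
#' @param p1,p2 Numeric length-2 vectors, pixel coordinates `c(x, y)`.
#' @param known_distance_mm Physical distance between the two points, in mm.
#'
#' @return Scale factor in mm per pixel.
#' @examples
#' compute_scale_factor(c(0, 0), c(100, 0), 10) # 0.1
#' compute_scale_factor(c(0, 0), c(3, 4), 1)    # 0.2
#' @export
compute_scale_factor <- function(p1, p2, known_distance_mm) {
  stopifnot(is.numeric(p1), length(p1) == 2L, is.numeric(p2), length(p2) == 2L)
  if (!is.numeric(known_distance_mm) || length(known_distance_mm) != 1L ||
      !is.finite(known_distance_mm) || known_distance_mm <= 0) {
    stop("`known_distance_mm` must be a single positive number.", call. = FALSE)
  }
  d <- sqrt(sum((as.numeric(p2) - as.numeric(p1))^2))
  if (d == 0) {
    stop("Degenerate calibration: the two reference points coincide.", call. = FALSE)
  }
  known_distance_mm / d
}
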