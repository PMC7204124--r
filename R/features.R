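#' Ordered stack of grayscale frames
#'
#' Light container for a video clip: a list of gray-level matrices (values
#' 0-255, all the same shape) plus the frame rate in frames/second.
#'
#' @param frames List of numeric matrices.
#' @param frame_rate Frames per second (> 0).
#' @return A list of class `frame_stack` with elements `frames` and
#'   `frame_rate`.
#' @export
frame_stack <- function(frames, frame_rate) {
  stopifnot(is.list(frames), length(frames) >= 1, frame_rate > 0,
            all(vapply(frames, is.matrix, logical(1))))
  shape <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), shape), logical(1))
  if (!all(ok)) abort("All frames in a frame_stack must share one shape.")
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255) {
    abort("Frame gray levels must lie in [0, 255].")
  }
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px at %g fps\n",
              length(x$frames), d[1], d[2], x$frame_rate))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Centroid of a detected region
#'
#' The region is treated as a point particle: its position is the unweighted
#' mean of its member pixel coordinates.
#'
#' @param region A tibble (or data frame) of pixel coordinates with columns
#'   `x` and `y` (0-based; `x` = column, `y` = row).
#' @return Named numeric vector `c(x, y)`.
#' @export
region_centroid <- function(region) {
  if (is.null(region) || nrow(region) == 0L) {
    abort("region_centroid() requires a non-empty region.")
  }
  c(x = mean(region$x), y = mean(region$y))
}

#' Euclidean displacement between two positions
#'
#' @param p_a,p_b Numeric vectors `c(x, y)` (names optional).
#' @return The planar distance in pixels.
#' @export
displacement <- function(p_a, p_b) {
  sqrt(sum((as.numeric(p_b)[1:2] - as.numeric(p_a)[1:2])^2))
}

#' Extract the centroid track of the moving target from a video
#'
#' Runs three-frame differencing on every interior frame (the mask is
#' attributed to the central frame of each triple), cleans and selects the
#' largest moving region, and records its centroid. Frames where no region
#' survives produce no row — a gap in the track — rather than a zero.
#'
#' @param video A [frame_stack()].
#' @param cfg A [diff_config()].
#' @return A tibble of class `motion_track` with columns `frame_index`
#'   (0-based), `x`, `y` (pixels, 0-based) and `area` (region size in
#'   pixels); attribute `frame_rate` carries the video's frame rate.
#' @export
extract_track <- function(video, cfg = diff_config()) {
  stopifnot(inherits(video, "frame_stack"))
  n <- length(video$frames)
  if (n < 3L) abort("Three-frame differencing needs at least 3 frames.")
  rows <- vector("list", n - 2L)
  for (k in 2:(n - 1L)) {
    mask <- three_frame_difference(video$frames[[k - 1L]],
                                   video$frames[[k]],
                                   video$frames[[k + 1L]],
                                   cfg, frame_index = k - 1L)
    sel <- clean_and_select(mask, cfg)
    if (!is.null(sel$region)) {
      cen <- region_centroid(sel$region)
      rows[[k - 1L]] <- tibble::tibble(
        frame_index = k - 1L, x = cen[["x"]], y = cen[["y"]],
        area = nrow(sel$region)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(frame_index = integer(), x = numeric(),
                          y = numeric(), area = integer())
  }
  new_motion_track(out, video$frame_rate)
}

new_motion_track <- function(tbl, frame_rate) {
  structure(tbl, frame_rate = frame_rate,
            class = c("motion_track", class(tibble::as_tibble(tbl))))
}

#' Per-frame-pair speed sequence of a track
#'
#' For each pair of consecutively detected centroids the speed is the
#' Euclidean displacement divided by the elapsed time
#' `(difference in frame index) / frame_rate`. Detection gaps therefore use
#' the true frame gap, not one frame blindly, so a missed detection dilutes
#' rather than inflates the speed.
#'
#' @param track A `motion_track` tibble (columns `frame_index`, `x`, `y`)
#'   with at least 2 rows.
#' @param frame_rate Frames per second; defaults to the track's
#'   `frame_rate` attribute.
#' @param source_id Optional identifier of the originating video.
#' @param normalize_height If non-`NULL`, divide every speed by this frame
#'   height (pixels), yielding frame-heights/second. Off by default.
#' @return A tibble of class `velocity_sequence` with columns `pair_index`,
#'   `frame_from`, `frame_to` and `speed` (pixels/second, always >= 0).
#' @export
velocity_sequence <- function(track, frame_rate = attr(track, "frame_rate"),
                              source_id = NULL, normalize_height = NULL) {
  if (is.null(frame_rate) || frame_rate <= 0) {
    abort("velocity_sequence() needs a positive frame_rate.")
  }
  if (nrow(track) < 2L) {
    abort("velocity_sequence() needs a track with at least 2 points.")
  }
  fi <- track$frame_index
  if (any(diff(fi) <= 0)) abort("Track frame indices must strictly increase.")
  dx <- diff(track$x)
  dy <- diff(track$y)
  dt <- diff(fi) / frame_rate
  speed <- sqrt(dx^2 + dy^2) / dt
  if (!is.null(normalize_height)) speed <- speed / normalize_height
  structure(
    tibble::tibble(
      pair_index = seq_along(speed),
      frame_from = fi[-length(fi)],
      frame_to = fi[-1L],
      speed = speed
    ),
    frame_rate = frame_rate, source_id = source_id,
    class = c("velocity_sequence", class(tibble::tibble()))
  )
}

#' Speed sequence directly from centroid coordinates
#'
#' Convenience wrapper building a track from raw coordinates and calling
#' [velocity_sequence()].
#'
#' @param frame_index,x,y Equal-length vectors of detections.
#' @param frame_rate Frames per second.
#' @inheritParams velocity_sequence
#' @return A `velocity_sequence` tibble.
#' @export
speeds_from_points <- function(frame_index, x, y, frame_rate,
                               source_id = NULL) {
  track <- new_motion_track(
    tibble::tibble(frame_index = frame_index, x = x, y = y), frame_rate
  )
  velocity_sequence(track, frame_rate, source_id = source_id)
}

#' @describeIn velocity_sequence Line plot of speed against pair index.
#' @param object A `velocity_sequence`.
#' @param ... Unused.
#' @export
autoplot.velocity_sequence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pair_index,
                                       y = .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame pair", y = "speed (px/s)")
}

#' @importFrom rlang .data
#' @export
autoplot.motion_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame_index, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "frame", y = "centroid y (px)")
}
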