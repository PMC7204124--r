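#' Monitoring pipeline configuration
#'
#' @param diff A [diff_config()] for motion detection.
#' @param window_length Frames per classified segment (>= 3). Continuous
#'   monitoring has no natural "action" boundary, so the stream is cut into
#'   overlapping windows.
#' @param window_stride Frames between successive window starts.
#' @param alert_policy `"k_of_m"` (default) raises an alert only when at
#'   least `k` of the last `m` windows (including the current one) were
#'   classified positive, damping single-window flips; `"any_positive"`
#'   alerts on every positive window, i.e. immediately.
#' @param k,m Integers for the k-of-m policy, `1 <= k <= m`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(diff = diff_config(), window_length = 30,
                            window_stride = 15,
                            alert_policy = c("k_of_m", "any_positive"),
                            k = 2, m = 3) {
  stopifnot(window_length >= 3, window_stride >= 1, k >= 1, k <= m)
  structure(
    list(diff = diff, window_length = as.integer(window_length),
         window_stride = as.integer(window_stride),
         alert_policy = match.arg(alert_policy),
         k = as.integer(k), m = as.integer(m)),
    class = "pipeline_config"
  )
}

#' Run the monitoring pipeline on a video
#'
#' Slides windows of `window_length` frames by `window_stride` over the
#' stack. Each window goes through three-frame differencing, largest-region
#' tracking, velocity extraction and VDS classification; windows in which no
#' motion is detected (fewer than two tracked centroids) are reported as
#' `"no_motion"` rather than classified. Alerts are emitted for positive
#' windows according to the alert policy.
#'
#' @param video A [frame_stack()] (or `synthetic_video`).
#' @param model A trained [vds_train()] model.
#' @param cfg A [pipeline_config()].
#' @return A list of class `monitor_result` with `report` (one tibble row
#'   per window: `window`, `start_frame`, `end_frame` (0-based, inclusive),
#'   `n_detected`, `seq_length`, `decision`, `class`, `status`) and
#'   `alerts` (tibble of `window_start_frame`, `window_end_frame`,
#'   `decision_value`, `time_start_s`, `time_end_s`).
#' @export
run_monitor <- function(video, model, cfg = pipeline_config()) {
  if (inherits(video, "synthetic_video")) video <- video$frames
  stopifnot(inherits(video, "frame_stack"), inherits(model, "vds_model"))
  n <- length(video$frames)
  if (n < cfg$window_length) {
    abort(sprintf(
      "Video has %d frames but one window needs %d.", n, cfg$window_length
    ))
  }
  fw <- video$frame_rate
  starts <- seq(1L, n - cfg$window_length + 1L, by = cfg$window_stride)
  rows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    s <- starts[w]
    e <- s + cfg$window_length - 1L
    sub <- frame_stack(video$frames[s:e], fw)
    track <- extract_track(sub, cfg$diff)
    if (nrow(track) < 2L) {
      rows[[w]] <- tibble::tibble(
        window = w, start_frame = s - 1L, end_frame = e - 1L,
        n_detected = nrow(track), seq_length = 0L,
        decision = NA_real_, class = NA_real_, status = "no_motion"
      )
      next
    }
    vs <- velocity_sequence(track, fw)
    dec <- predict(model, vs$speed, type = "decision")
    rows[[w]] <- tibble::tibble(
      window = w, start_frame = s - 1L, end_frame = e - 1L,
      n_detected = nrow(track), seq_length = nrow(vs),
      decision = dec, class = if (dec >= 0) 1 else -1, status = "classified"
    )
  }
  report <- dplyr::bind_rows(rows)
  positive <- !is.na(report$class) & report$class == 1
  alert_idx <- if (cfg$alert_policy == "any_positive") {
    which(positive)
  } else {
    which(vapply(seq_along(positive), function(w) {
      if (!positive[w]) return(FALSE)
      recent <- positive[max(1L, w - cfg$m + 1L):w]
      sum(recent) >= cfg$k
    }, logical(1)))
  }
  alerts <- tibble::tibble(
    window_start_frame = report$start_frame[alert_idx],
    window_end_frame = report$end_frame[alert_idx],
    decision_value = report$decision[alert_idx],
    time_start_s = report$start_frame[alert_idx] / fw,
    time_end_s = report$end_frame[alert_idx] / fw
  )
  structure(list(report = report, alerts = alerts, config = cfg),
            class = "monitor_result")
}

#' @export
print.monitor_result <- function(x, ...) {
  cat("<monitor_result>\n")
  cat(sprintf("  %d windows, %d classified, %d alerts (%s)\n",
              nrow(x$report), sum(x$report$status == "classified"),
              nrow(x$alerts), x$config$alert_policy))
  invisible(x)
}

#' @export
autoplot.monitor_result <- function(object, ...) {
  r <- object$report[object$report$status == "classified", ]
  ggplot2::ggplot(r, ggplot2::aes(x = .data$start_frame,
                                  y = .data$decision)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "window start frame", y = "decision value")
}
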