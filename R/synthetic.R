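#' Scene configuration for synthetic laryngeal videos
#'
#' Describes the static rendering side of a synthetic clip: a bright
#' elliptical "throat marker" blob on a flat noisy background. The blob
#' emulates the high-contrast sticker placed on the patient's throat;
#' `marker_contrast` is the gray-level difference between blob and
#' background, so low values emulate the harder no-sticker condition.
#'
#' @param frame_count Number of frames (>= 3).
#' @param height,width Frame size in pixels.
#' @param frame_rate Frames per second.
#' @param blob_axes Ellipse semi-axes in pixels, `c(x, y)`.
#' @param marker_contrast Gray-level difference in `[0, 255]` between blob
#'   and background.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (gray levels); frames are clipped to `[0, 255]` and rounded to 8 bits.
#' @param background_level Background gray level.
#' @param seed Integer RNG seed; identical configurations reproduce
#'   bit-identical frames.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(frame_count = 60, height = 160, width = 120,
                         frame_rate = 10, blob_axes = c(10, 7),
                         marker_contrast = 80, noise_sigma = 5,
                         background_level = 60, seed = 1) {
  stopifnot(frame_count >= 3, height > 0, width > 0, frame_rate > 0,
            length(blob_axes) == 2, all(blob_axes > 0),
            marker_contrast >= 0, marker_contrast <= 255,
            noise_sigma >= 0, background_level >= 0, background_level <= 255)
  structure(
    list(frame_count = as.integer(frame_count), height = as.integer(height),
         width = as.integer(width), frame_rate = frame_rate,
         blob_axes = as.numeric(blob_axes),
         marker_contrast = marker_contrast, noise_sigma = noise_sigma,
         background_level = background_level, seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Kinematic profile of one class of laryngeal motion
#'
#' The blob moves vertically as a sinusoid (smooth periodic laryngeal
#' motion), optionally disturbed by per-frame positional jitter and, for the
#' positive class, by sporadic one-frame high-velocity excursions ("bursts")
#' that stand in for the irregular motion of a phlegm-stagnation episode.
#' A burst displaces the blob by `2.5 * base_amplitude` pixels (random sign)
#' for a single frame.
#'
#' The real kinematic signature of phlegm stagnation is not quantitatively
#' characterised; these profiles are tunable stand-ins, not clinically
#' validated motion models.
#'
#' @param class_label `+1` (phlegm stagnation) or `-1` (normal).
#' @param base_amplitude Sinusoid amplitude in pixels.
#' @param base_frequency Sinusoid frequency in cycles/second.
#' @param jitter_sigma Per-frame positional noise, pixels. Raising it blurs
#'   the class separation continuously.
#' @param burst_probability Per-frame probability of a burst; must be 0 for
#'   the normal class.
#' @param drift Constant vertical velocity in pixels/frame (default 0);
#'   useful for constant-speed calibration clips.
#' @return A list of class `motion_profile`.
#' @export
motion_profile <- function(class_label, base_amplitude = 12,
                           base_frequency = 0.5, jitter_sigma = 1.5,
                           burst_probability = 0, drift = 0) {
  stopifnot(class_label %in% c(-1, 1),
            base_amplitude >= 0, base_frequency >= 0, jitter_sigma >= 0,
            burst_probability >= 0, burst_probability <= 1)
  if (class_label == -1 && burst_probability > 0) {
    abort("The normal class (-1) must have burst_probability = 0.")
  }
  structure(
    list(class_label = class_label, base_amplitude = base_amplitude,
         base_frequency = base_frequency, jitter_sigma = jitter_sigma,
         burst_probability = burst_probability, drift = drift),
    class = "motion_profile"
  )
}

#' Paired motion profiles with well-separated speed distributions
#'
#' The positive class moves with large amplitude at a faster rhythm and
#' bursts; the negative class is a slow small sinusoid. Their speed
#' distributions do not overlap, so classifiers should recover the labels
#' essentially perfectly.
#'
#' @return A list with elements `pos` and `neg` ([motion_profile()]s).
#' @export
separable_profiles <- function() {
  list(
    pos = motion_profile(+1, base_amplitude = 20, base_frequency = 0.8,
                         jitter_sigma = 0.5, burst_probability = 0.2),
    neg = motion_profile(-1, base_amplitude = 5, base_frequency = 0.4,
                         jitter_sigma = 0.5)
  )
}

#' Paired motion profiles with moderately overlapping speed distributions
#'
#' Both classes share amplitude, frequency and a substantial jitter; the
#' positive class differs only through sporadic bursts, so clips with few or
#' no bursts are genuinely ambiguous. This is the regime used for comparing
#' classifiers.
#'
#' @return A list with elements `pos` and `neg`.
#' @export
overlapping_profiles <- function() {
  list(
    pos = motion_profile(+1, base_amplitude = 12, base_frequency = 0.5,
                         jitter_sigma = 3, burst_probability = 0.06),
    neg = motion_profile(-1, base_amplitude = 12, base_frequency = 0.5,
                         jitter_sigma = 3)
  )
}

# Evaluate the scripted blob-center trajectory. Uses the current RNG stream
# for jitter and bursts; callers control seeding.
generate_trajectory <- function(scene, profile) {
  n <- scene$frame_count
  k <- 0:(n - 1L)
  t <- k / scene$frame_rate
  cx <- (scene$width - 1) / 2
  cy <- (scene$height - 1) / 2
  y <- cy + profile$drift * (k - (n - 1) / 2) +
    profile$base_amplitude * sin(2 * pi * profile$base_frequency * t)
  if (profile$jitter_sigma > 0) y <- y + rnorm(n, 0, profile$jitter_sigma)
  if (profile$burst_probability > 0) {
    hit <- runif(n) < profile$burst_probability
    sign <- ifelse(runif(n) < 0.5, -1, 1)
    y <- y + hit * sign * 2.5 * profile$base_amplitude
  }
  tibble::tibble(frame_index = k, x = rep(cx, n), y = y)
}

# Anti-aliased filled ellipse coverage in [0, 1] on the pixel grid.
# (x, y) are 0-based with x = column, y = row.
ellipse_coverage <- function(height, width, cx, cy, ax, ay) {
  xs <- matrix(rep(0:(width - 1L), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1L), times = width), nrow = height)
  r <- sqrt(((xs - cx) / ax)^2 + ((ys - cy) / ay)^2)
  w <- 1 / min(ax, ay)  # ~1 px soft edge in normalized radius units
  cov <- 0.5 + (1 - r) / (2 * w)
  pmax(pmin(cov, 1), 0)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic laryngeal-motion video
#'
#' Renders the blob along the profile's trajectory and returns both the
#' frames and the exact generated centers for ground-truth comparison.
#' Identical inputs and seed reproduce bit-identical frames.
#'
#' @param scene A [scene_config()].
#' @param profile A [motion_profile()].
#' @return A list of class `synthetic_video` with `frames` (a
#'   [frame_stack()]), `track` (the true centers as a `motion_track`
#'   tibble), `scene`, and `profile`.
#' @export
generate_video <- function(scene, profile) {
  stopifnot(inherits(scene, "scene_config"), inherits(profile, "motion_profile"))
  with_seed(scene$seed, {
    traj <- generate_trajectory(scene, profile)
    ax <- scene$blob_axes[1]
    ay <- scene$blob_axes[2]
    bad <- traj$x - ax < 0 | traj$x + ax > scene$width - 1 |
      traj$y - ay < 0 | traj$y + ay > scene$height - 1
    if (any(bad)) {
      abort(sprintf(
        "Trajectory leaves the frame at %d of %d frames (first at frame %d); enlarge the frame or shrink the motion.",
        sum(bad), nrow(traj), traj$frame_index[which(bad)[1]]
      ))
    }
    frames <- vector("list", scene$frame_count)
    for (i in seq_len(scene$frame_count)) {
      img <- scene$background_level + scene$marker_contrast *
        ellipse_coverage(scene$height, scene$width,
                         traj$x[i], traj$y[i], ax, ay)
      if (scene$noise_sigma > 0) {
        img <- img + matrix(rnorm(length(img), 0, scene$noise_sigma),
                            nrow = scene$height)
      }
      frames[[i]] <- round(pmax(pmin(img, 255), 0))
    }
    structure(
      list(frames = frame_stack(frames, scene$frame_rate),
           track = new_motion_track(traj, scene$frame_rate),
           scene = scene, profile = profile),
      class = "synthetic_video"
    )
  })
}

#' Generate a balanced labeled set of synthetic videos
#'
#' @param n_per_class Videos per class (>= 1).
#' @param scene A [scene_config()] shared by all videos (its `seed` is
#'   ignored; per-video seeds are derived from `seed`).
#' @param profiles List with elements `pos` (label +1) and `neg` (label -1).
#' @param seed Integer master seed; the whole dataset is deterministic
#'   under it.
#' @return A tibble with columns `id`, `label` (+1/-1), `video`
#'   (list of `synthetic_video`) and `track` (list of `motion_track`).
#' @export
generate_dataset <- function(n_per_class, scene = scene_config(),
                             profiles = overlapping_profiles(), seed = 1) {
  stopifnot(n_per_class >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L * n_per_class))
  labels <- rep(c(1, -1), each = n_per_class)
  videos <- vector("list", 2L * n_per_class)
  for (i in seq_along(labels)) {
    sc <- scene
    sc$seed <- seeds[i]
    prof <- if (labels[i] == 1) profiles$pos else profiles$neg
    videos[[i]] <- generate_video(sc, prof)
  }
  tibble::tibble(
    id = sprintf("video_%03d", seq_along(labels)),
    label = labels,
    video = videos,
    track = lapply(videos, `[[`, "track")
  )
}

#' Generate labeled velocity sequences without rendering
#'
#' Evaluates the kinematic model only: the speed between consecutive true
#' blob centers, skipping rendering and detection. This makes large
#' classifier experiments cheap while exercising exactly the same motion
#' model as [generate_dataset()]. Sequences have `frame_count - 1` values.
#'
#' @inheritParams generate_dataset
#' @param frame_count Frames per clip.
#' @param frame_rate Frames per second.
#' @return A tibble with columns `id`, `label` and `sequence` (list of
#'   numeric speed vectors in pixels/second).
#' @export
generate_sequences <- function(n_per_class,
                               profiles = overlapping_profiles(),
                               frame_count = 60, frame_rate = 10, seed = 1) {
  stopifnot(n_per_class >= 1)
  scene <- scene_config(frame_count = frame_count, frame_rate = frame_rate,
                        noise_sigma = 0)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L * n_per_class))
  labels <- rep(c(1, -1), each = n_per_class)
  seqs <- vector("list", 2L * n_per_class)
  for (i in seq_along(labels)) {
    prof <- if (labels[i] == 1) profiles$pos else profiles$neg
    traj <- with_seed(seeds[i], generate_trajectory(scene, prof))
    d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
    seqs[[i]] <- d * frame_rate
  }
  tibble::tibble(
    id = sprintf("seq_%03d", seq_along(labels)),
    label = labels,
    sequence = seqs
  )
}

#' Write a synthetic video to disk
#'
#' Writes zero-padded 8-bit grayscale PNG frames (`frame_000001.png`, ...)
#' plus a JSON sidecar holding the scene, profile and ground-truth track as
#' per-frame `(frame_index, x, y)` triples.
#'
#' @param video A `synthetic_video` (or a bare [frame_stack()], in which
#'   case the sidecar holds only the frame rate).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- if (inherits(video, "synthetic_video")) video$frames else video
  for (i in seq_along(frames$frames)) {
    png::writePNG(frames$frames[[i]] / 255,
                  target = file.path(dir, sprintf("frame_%06d.png", i)))
  }
  side <- list(frame_rate = frames$frame_rate,
               frame_count = length(frames$frames))
  if (inherits(video, "synthetic_video")) {
    side$scene <- unclass(video$scene)
    side$profile <- unclass(video$profile)
    side$track <- video$track[, c("frame_index", "x", "y")]
  }
  jsonlite::write_json(side, file.path(dir, "video.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a directory of numbered grayscale PNG frames
#'
#' @param dir Directory containing `frame_*.png` files (any other `.png`
#'   files are read in lexicographic order).
#' @param frame_rate Frames per second; if `NULL`, taken from a
#'   `video.json` sidecar in `dir`.
#' @return A [frame_stack()].
#' @export
read_video <- function(dir, frame_rate = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) abort(sprintf("No PNG frames found in '%s'.", dir))
  if (is.null(frame_rate)) {
    side <- file.path(dir, "video.json")
    if (!file.exists(side)) {
      abort("No frame_rate given and no video.json sidecar found.")
    }
    frame_rate <- jsonlite::read_json(side)$frame_rate
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # gray stored as RGB
    round(img * 255)
  })
  frame_stack(frames, frame_rate)
}
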