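test_that("zero contrast and zero noise yield constant frames and empty masks", {
  scene <- scene_config(frame_count = 5, marker_contrast = 0, noise_sigma = 0,
                        seed = 1)
  v <- generate_video(scene, motion_profile(-1, jitter_sigma = 0))
  expect_true(all(vapply(v$frames$frames, function(f) {
    all(f == scene$background_level)
  }, logical(1))))
  m <- three_frame_difference(v$frames$frames[[1]], v$frames$frames[[2]],
                              v$frames$frames[[3]], diff_config())
  expect_equal(sum(m), 0)
})

test_that("a static scene renders identical frames and a constant track", {
  scene <- scene_config(frame_count = 4, noise_sigma = 0, seed = 2)
  prof <- motion_profile(-1, base_amplitude = 0, jitter_sigma = 0)
  v <- generate_video(scene, prof)
  expect_true(all(vapply(v$frames$frames[-1], identical,
                         logical(1), v$frames$frames[[1]])))
  expect_equal(length(unique(v$track$y)), 1L)
})

test_that("the noiseless track equals the scripted sinusoid exactly", {
  scene <- scene_config(frame_count = 40, frame_rate = 10, noise_sigma = 0,
                        seed = 3)
  prof <- motion_profile(-1, base_amplitude = 10, base_frequency = 0.5,
                         jitter_sigma = 0)
  v <- generate_video(scene, prof)
  k <- 0:39
  expected_y <- (scene$height - 1) / 2 +
    10 * sin(2 * pi * 0.5 * k / 10)
  expect_equal(v$track$y, expected_y)
  expect_equal(v$track$x, rep((scene$width - 1) / 2, 40))
})

test_that("generation is bit-reproducible under the seed", {
  scene <- scene_config(frame_count = 6, seed = 99)
  prof <- motion_profile(+1, burst_probability = 0.3)
  v1 <- generate_video(scene, prof)
  v2 <- generate_video(scene, prof)
  expect_identical(v1$frames$frames, v2$frames$frames)
  expect_identical(v1$track, v2$track)

  d1 <- generate_dataset(2, scene_config(frame_count = 5), seed = 5)
  d2 <- generate_dataset(2, scene_config(frame_count = 5), seed = 5)
  expect_identical(d1$label, d2$label)
  expect_identical(lapply(d1$video, function(v) v$frames$frames),
                   lapply(d2$video, function(v) v$frames$frames))
})

test_that("datasets are balanced", {
  d <- generate_dataset(1, scene_config(frame_count = 5), seed = 4)
  expect_equal(sort(d$label), c(-1, 1))
  s <- generate_sequences(25, seed = 6)
  expect_equal(nrow(s), 50L)
  expect_equal(sum(s$label == 1), 25L)
  expect_equal(sum(s$label == -1), 25L)
  expect_equal(lengths(s$sequence), rep(59L, 50))
})

test_that("trajectories that would leave the frame are rejected", {
  scene <- scene_config(frame_count = 10, height = 40, seed = 1)
  prof <- motion_profile(-1, base_amplitude = 30, jitter_sigma = 0)
  expect_error(generate_video(scene, prof), "leaves the frame")
})

test_that("the normal class cannot be given bursts", {
  expect_error(motion_profile(-1, burst_probability = 0.1), "burst")
})

test_that("rendered blob centroid matches the true center within 0.5 px", {
  scene <- scene_config(frame_count = 8, noise_sigma = 0, seed = 12)
  prof <- motion_profile(+1, jitter_sigma = 2, burst_probability = 0.2)
  v <- generate_video(scene, prof)
  for (i in seq_along(v$frames$frames)) {
    f <- v$frames$frames[[i]] - scene$background_level
    xs <- matrix(rep(0:(scene$width - 1), each = scene$height),
                 nrow = scene$height)
    ys <- matrix(rep(0:(scene$height - 1), times = scene$width),
                 nrow = scene$height)
    cx <- sum(xs * f) / sum(f)
    cy <- sum(ys * f) / sum(f)
    expect_lt(abs(cx - v$track$x[i]), 0.5)
    expect_lt(abs(cy - v$track$y[i]), 0.5)
  }
})

test_that("bursts raise the positive class mean speed at equal amplitude", {
  diffs <- vapply(1:100, function(s) {
    d <- generate_sequences(1, overlapping_profiles(), frame_count = 40,
                            seed = s)
    mean(d$sequence[d$label == 1][[1]]) - mean(d$sequence[d$label == -1][[1]])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("growing jitter makes the class speed distributions overlap", {
  sep <- function(jit) {
    profs <- list(
      pos = motion_profile(+1, jitter_sigma = jit, burst_probability = 0.06),
      neg = motion_profile(-1, jitter_sigma = jit)
    )
    d <- generate_sequences(30, profs, frame_count = 40, seed = 31)
    mp <- vapply(d$sequence[d$label == 1], mean, numeric(1))
    mn <- vapply(d$sequence[d$label == -1], mean, numeric(1))
    (mean(mp) - mean(mn)) / sqrt((stats::var(mp) + stats::var(mn)) / 2)
  }
  # between-class effect size shrinks as within-class jitter grows
  expect_gt(sep(0.5), sep(8))
})

test_that("videos round-trip through PNG frames and the JSON sidecar", {
  dir <- withr::local_tempdir()
  scene <- scene_config(frame_count = 5, seed = 8)
  v <- generate_video(scene, motion_profile(-1))
  write_video(v, dir)
  expect_length(list.files(dir, pattern = "frame_\\d{6}\\.png"), 5L)
  back <- read_video(dir)
  expect_equal(back$frame_rate, scene$frame_rate)
  expect_equal(back$frames, v$frames$frames, ignore_attr = TRUE)
})
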