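test_that("interframe difference thresholds the absolute pixel difference", {
  a <- matrix(50, 3, 3)
  b <- a
  b[2, 3] <- 60  # one pixel brighter by 10

  expect_equal(sum(frame_difference(a, a, diff_config(threshold = 1))), 0)

  m <- frame_difference(a, b, diff_config(threshold = 5))
  expect_equal(sum(m), 1L)
  expect_equal(m[2, 3], 1L)

  expect_equal(sum(frame_difference(a, b, diff_config(threshold = 11))), 0)
  # symmetry of the absolute difference
  expect_equal(unclass(frame_difference(a, b, diff_config(5))),
               unclass(frame_difference(b, a, diff_config(5))))
})

test_that("shape mismatches are rejected with both shapes named", {
  expect_error(frame_difference(matrix(0, 2, 3), matrix(0, 3, 3)),
               "2x3.*3x3")
})

test_that("three-frame difference is the AND of the two pairwise masks", {
  cfg <- diff_config(threshold = 20)
  # a block stepping right by 5 columns per frame
  mk <- function(col0) {
    f <- matrix(0, 8, 15)
    f[3:6, (col0 + 1):(col0 + 5)] <- 200
    f
  }
  f1 <- mk(0); f2 <- mk(5); f3 <- mk(10)
  m <- three_frame_difference(f1, f2, f3, cfg)
  manual_and <- (unclass(frame_difference(f1, f2, cfg)) &
                   unclass(frame_difference(f2, f3, cfg))) * 1L
  expect_identical(unclass(m), manual_and)
  # only the middle block position changed in BOTH pairs: the previous
  # position (ghost) changed only in the first, the next only in the second
  expect_equal(sum(m), 20)
  expect_true(all(which(unclass(m) == 1L, arr.ind = TRUE)[, "col"] %in% 6:10))

  expect_equal(sum(three_frame_difference(f1, f1, f1, cfg)), 0)
  # identical first pair forces an all-zero conjunction
  expect_equal(sum(three_frame_difference(f1, f1, f3, cfg)), 0)
})

test_that("AND equivalence holds bit-exactly on random frame triples", {
  set.seed(7)
  for (trial in 1:40) {
    f1 <- random_frame(); f2 <- random_frame(); f3 <- random_frame()
    cfg <- diff_config(threshold = sample(5:80, 1))
    m <- three_frame_difference(f1, f2, f3, cfg)
    manual <- (unclass(frame_difference(f1, f2, cfg)) &
                 unclass(frame_difference(f2, f3, cfg))) * 1L
    expect_identical(unclass(m), manual)
  }
})

test_that("raising the threshold never adds mask pixels", {
  set.seed(8)
  for (trial in 1:20) {
    f1 <- random_frame(); f2 <- random_frame()
    t1 <- sample(5:100, 1)
    t2 <- t1 + sample(1:100, 1)
    m1 <- frame_difference(f1, f2, diff_config(threshold = t1))
    m2 <- frame_difference(f1, f2, diff_config(threshold = t2))
    expect_true(all(m2 <= m1))
  }
})

test_that("cleanup keeps the largest sufficiently large component", {
  m <- matrix(0L, 30, 30)
  m[3:12, 3:12] <- 1L        # 100 px
  m[20:21, 25] <- 1L
  m[22, 26] <- 1L            # 3 px, 8-connected diagonal piece
  expect_equal(sort(flood_areas(m), decreasing = TRUE), c(100, 3))

  sel <- clean_and_select(m, diff_config(threshold = 5, morph_radius = 0,
                                         min_area = 10))
  expect_equal(nrow(sel$region), 100)
  expect_true(all(sel$region$x %in% 2:11))
  expect_true(all(sel$region$y %in% 2:11))
})

test_that("no surviving component yields a none result, not an error", {
  expect_null(clean_and_select(matrix(0L, 5, 5), diff_config())$region)
  speck <- matrix(0L, 9, 9); speck[5, 5] <- 1L
  expect_null(clean_and_select(speck, diff_config(min_area = 2,
                                                  morph_radius = 0))$region)
})

test_that("closing fills interior holes, matching brute-force morphology", {
  m <- matrix(0L, 40, 40)
  m[10:29, 10:29] <- 1L
  m[17, 17] <- 0L  # single interior hole
  sel <- clean_and_select(m, diff_config(morph_radius = 1))
  expect_equal(nrow(sel$region), 400)

  se <- matrix(1L, 3, 3)
  expect_equal(unclass(sel$mask), bf_close(m, se))
})

test_that("optional opening removes thin structures like brute force", {
  m <- matrix(0L, 30, 30)
  m[5:20, 10] <- 1L          # 1-px-wide line
  m[24:28, 20:26] <- 1L      # 5x7 block
  cfg <- diff_config(morph_radius = 0, open_radius = 1, min_area = 1)
  sel <- clean_and_select(m, cfg)
  se <- matrix(1L, 3, 3)
  expect_equal(unclass(sel$mask), bf_dilate(bf_erode(m, se), se))
  # only the block survives the opening
  expect_true(all(sel$region$x %in% 19:25))
})

test_that("largest-component ties break on the top-left bounding box corner", {
  m <- matrix(0L, 20, 20)
  m[12:14, 2:4] <- 1L   # 9 px, lower-left
  m[2:4, 12:14] <- 1L   # 9 px, upper-right (smaller row wins)
  sel <- clean_and_select(m, diff_config(morph_radius = 0, min_area = 1))
  expect_equal(sort(unique(sel$region$y)), 1:3)
  expect_equal(sort(unique(sel$region$x)), 11:13)
})
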