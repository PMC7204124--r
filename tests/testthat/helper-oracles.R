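# Independent oracles used to pin down expected values. These deliberately
# avoid the package's own implementations: exhaustive path enumeration for
# DTW, brute-force structuring-element sweeps for morphology, and queue-based
# flood fill for component areas.

# Exhaustive DTW: enumerate every monotone warping path ending at (M, N)
# backwards. A path may leave the table ("enter" it, viewed forwards) only
# where the boundary rule grants cost zero: at the virtual origin for the
# standard rule, anywhere with i < 1 or j < 1 for the literal rule.
oracle_dtw <- function(a, b, constraint = "standard_a",
                       boundary = "standard", local_cost = "absolute") {
  steps <- if (constraint == "standard_a") {
    list(c(1, 1), c(1, 0), c(0, 1))
  } else {
    list(c(1, 1), c(2, 1), c(1, 2))
  }
  d <- function(i, j) {
    if (local_cost == "absolute") abs(a[i] - b[j]) else (a[i] - b[j])^2
  }
  entry_ok <- function(pi, pj) {
    if (boundary == "standard") pi == 0 && pj == 0 else (pi < 1 || pj < 1)
  }
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + d(i, j)
    for (s in steps) {
      pi <- i - s[1]
      pj <- j - s[2]
      if (pi >= 1 && pj >= 1) {
        rec(pi, pj, acc)
      } else if (entry_ok(pi, pj)) {
        if (acc < best) best <<- acc
      }
    }
  }
  rec(length(a), length(b), 0)
  best
}

# Brute-force binary morphology. Outside the matrix counts as background;
# callers keep shapes at least one structuring-element radius away from the
# border so the padding convention cannot matter.
bf_dilate <- function(m, se) {
  r <- (nrow(se) - 1) / 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      hit <- FALSE
      for (di in -r:r) {
        for (dj in -r:r) {
          if (se[di + r + 1, dj + r + 1] == 0) next
          ii <- i + di
          jj <- j + dj
          if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
              m[ii, jj] != 0) {
            hit <- TRUE
          }
        }
      }
      out[i, j] <- as.integer(hit)
    }
  }
  out
}

bf_erode <- function(m, se) {
  r <- (nrow(se) - 1) / 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      all_in <- TRUE
      for (di in -r:r) {
        for (dj in -r:r) {
          if (se[di + r + 1, dj + r + 1] == 0) next
          ii <- i + di
          jj <- j + dj
          inside <- ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
            m[ii, jj] != 0
          if (!inside) all_in <- FALSE
        }
      }
      out[i, j] <- as.integer(all_in)
    }
  }
  out
}

bf_close <- function(m, se) bf_erode(bf_dilate(m, se), se)

# Component areas by queue-based flood fill (8-connectivity), independent of
# the compiled labeling.
flood_areas <- function(m) {
  seen <- matrix(FALSE, nrow(m), ncol(m))
  areas <- integer(0)
  for (j in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m))) {
      if (m[i, j] == 0 || seen[i, j]) next
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      area <- 0L
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        area <- area + 1L
        for (di in -1:1) {
          for (dj in -1:1) {
            ii <- p[1] + di
            jj <- p[2] + dj
            if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
                m[ii, jj] != 0 && !seen[ii, jj]) {
              seen[ii, jj] <- TRUE
              queue <- c(queue, list(c(ii, jj)))
            }
          }
        }
      }
      areas <- c(areas, area)
    }
  }
  areas
}

random_frame <- function(nr = 12, nc = 12) {
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
}
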