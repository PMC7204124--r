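#' Dynamic time warping configuration
#'
#' Controls the recursion used by [dtw_distance()]: the local step set, how
#' the table is initialised at its borders, and the pointwise cost.
#'
#' @param constraint Step set for a cell's predecessors. `"standard_a"` allows
#'   `(i-1, j)`, `(i, j-1)` and `(i-1, j-1)`; `"extended_b"` is an
#'   Itakura-style set `(i-1, j-1)`, `(i-2, j-1)`, `(i-1, j-2)` that forces
#'   strictly advancing alignments.
#' @param boundary `"standard"` admits alignments only through the virtual
#'   origin, so the first row and column accumulate cost; `"literal"` treats
#'   every cell with `i < 1` or `j < 1` as having cumulative cost zero, which
#'   permits cost-free skipping of a prefix of either sequence. The standard
#'   rule is the default because it makes the self-distance path
#'   non-degenerate.
#' @param local_cost `"absolute"` for `|x - y|`, `"squared"` for `(x - y)^2`.
#'
#' @return A list of class `dtw_config`.
#' @seealso [dtw_distance()]
#' @export
dtw_config <- function(constraint = c("standard_a", "extended_b"),
                       boundary = c("standard", "literal"),
                       local_cost = c("absolute", "squared")) {
  structure(
    list(
      constraint = match.arg(constraint),
      boundary = match.arg(boundary),
      local_cost = match.arg(local_cost)
    ),
    class = "dtw_config"
  )
}

#' Pointwise matching cost between two speeds
#'
#' @param x,y Scalar speeds (or equal-length vectors, compared elementwise).
#' @param cfg A [dtw_config()].
#' @return Non-negative cost(s).
#' @export
dtw_local_cost <- function(x, y, cfg = dtw_config()) {
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("dtw_local_cost() requires finite inputs.")
  }
  if (cfg$local_cost == "absolute") abs(x - y) else (x - y)^2
}

#' DTW distance between two velocity sequences
#'
#' Fills the `M x N` cumulative-cost table with the recursion
#' `D(i, j) = min over allowed predecessors + d(a_i, b_j)` and backtracks one
#' optimal warping path from `(M, N)`. Ties during backtracking prefer the
#' diagonal predecessor, then the vertical, then the horizontal one, so the
#' returned path is deterministic.
#'
#' Under the `"extended_b"` step set some table cells can be unreachable; if
#' `(M, N)` itself is unreachable the distance is `Inf` and the path is empty.
#'
#' @param a,b Numeric speed vectors, or [velocity_sequence()] tibbles (their
#'   `speed` column is used). Both must be non-empty.
#' @param cfg A [dtw_config()].
#' @param keep_table Keep the full cumulative-cost matrix in the result
#'   (useful for diagnostics; off by default).
#' @return An object of class `dtw_alignment`: a list with `distance`,
#'   `normalized` (distance divided by `M + N`), `path` (a tibble of 1-based
#'   index pairs `i`, `j` from entry to `(M, N)`), `lengths`, and `cfg`.
#' @examples
#' dtw_distance(c(0, 2, 4), c(0, 4))
#' @export
dtw_distance <- function(a, b, cfg = dtw_config(), keep_table = FALSE) {
  a <- as_speed_vector(a)
  b <- as_speed_vector(b)
  if (length(a) < 1L || length(b) < 1L) {
    abort("dtw_distance() requires two non-empty sequences.")
  }
  D <- .dtw_table(a, b,
    constraint = match(cfg$constraint, c("standard_a", "extended_b")) - 1L,
    boundary = match(cfg$boundary, c("standard", "literal")) - 1L,
    local_cost = match(cfg$local_cost, c("absolute", "squared")) - 1L
  )
  M <- length(a)
  N <- length(b)
  dist <- D[M, N]
  path <- if (is.finite(dist)) dtw_backtrack(D, a, b, cfg) else
    tibble::tibble(i = integer(), j = integer())
  structure(
    list(
      distance = dist,
      normalized = dist / (M + N),
      path = path,
      lengths = c(M = M, N = N),
      cfg = cfg,
      table = if (keep_table) D else NULL
    ),
    class = "dtw_alignment"
  )
}

# Recover one optimal path from the filled table. Predecessors are probed in
# preference order (diagonal first); entry is reached when the best
# predecessor lies outside the table.
dtw_backtrack <- function(D, a, b, cfg) {
  steps <- if (cfg$constraint == "standard_a") {
    rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L))
  } else {
    rbind(c(1L, 1L), c(2L, 1L), c(1L, 2L))
  }
  pad <- function(i, j) {
    if (i >= 1L && j >= 1L) return(D[i, j])
    if (cfg$boundary == "literal") return(0)
    if (i == 0L && j == 0L) 0 else Inf
  }
  i <- nrow(D)
  j <- ncol(D)
  path <- list(c(i, j))
  repeat {
    d_here <- dtw_local_cost(a[i], b[j], cfg)
    target <- D[i, j] - d_here
    tol <- 1e-9 * max(1, abs(D[i, j]))
    chosen <- NULL
    for (s in seq_len(nrow(steps))) {
      pi <- i - steps[s, 1L]
      pj <- j - steps[s, 2L]
      if (abs(pad(pi, pj) - target) <= tol) {
        chosen <- c(pi, pj)
        break
      }
    }
    if (is.null(chosen) || chosen[1L] < 1L || chosen[2L] < 1L) break
    i <- chosen[1L]
    j <- chosen[2L]
    path <- c(path, list(c(i, j)))
  }
  m <- do.call(rbind, rev(path))
  tibble::tibble(i = m[, 1L], j = m[, 2L])
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat("<dtw_alignment>\n")
  cat(sprintf(
    "  distance: %.6g (normalized %.6g), lengths %d x %d, path %d cells\n",
    x$distance, x$normalized, x$lengths[["M"]], x$lengths[["N"]],
    nrow(x$path)
  ))
  cat(sprintf(
    "  constraint=%s boundary=%s cost=%s\n",
    x$cfg$constraint, x$cfg$boundary, x$cfg$local_cost
  ))
  invisible(x)
}

#' Extract the speed values from a sequence-like object
#'
#' Accepts a bare numeric vector or a [velocity_sequence()] tibble and
#' returns the numeric speeds.
#'
#' @param x Numeric vector or `velocity_sequence`.
#' @return Numeric vector of speeds.
#' @export
as_speed_vector <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x) && "speed" %in% names(x)) return(as.numeric(x$speed))
  abort("Expected a numeric vector or a velocity_sequence with a `speed` column.")
}
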