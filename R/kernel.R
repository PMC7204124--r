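#' Kernel and SVM configuration for the VDS classifier
#'
#' The VDS kernel between two velocity sequences `a`, `b` is
#' `K(a, b) = exp(-(alpha * D + (1 - alpha) * V) / (2 * sigma^2))`
#' where `D` is their DTW distance and `V` the squared difference of their
#' mean speeds. `alpha` interpolates between pure sequence-shape similarity
#' (`alpha = 1`) and pure overall-speed similarity (`alpha = 0`).
#'
#' @param alpha Mixing weight in `[0, 1]` between the DTW term and the
#'   velocity term.
#' @param sigma Kernel bandwidth (> 0), on the scale of the (normalized)
#'   inputs.
#' @param C Soft-margin penalty (> 0).
#' @param normalize_inputs `"zscore_over_training"` (default) centers and
#'   scales all speeds by the pooled mean/sd of the training set before both
#'   kernel terms, so `sigma = 1` is a sensible default; `"none"` uses raw
#'   pixels/second.
#' @param dtw A [dtw_config()] used for the `D` term.
#' @param normalize_dtw Divide `D` by `M + N` (the two sequence lengths) so
#'   the DTW and velocity terms share scale across sequence lengths
#'   (default `TRUE`); set `FALSE` for the raw cumulative cost.
#' @return A list of class `kernel_config`.
#' @export
kernel_config <- function(alpha = 0.5, sigma = 1, C = 10,
                          normalize_inputs = c("zscore_over_training", "none"),
                          dtw = dtw_config(), normalize_dtw = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1, sigma > 0, C > 0)
  structure(
    list(alpha = alpha, sigma = sigma, C = C,
         normalize_inputs = match.arg(normalize_inputs),
         dtw = dtw, normalize_dtw = isTRUE(normalize_dtw)),
    class = "kernel_config"
  )
}

#' Velocity similarity term of the VDS kernel
#'
#' The squared difference of the mean speeds of the two sequences: a scalar
#' summary of "how fast overall", symmetric and zero iff the means agree.
#'
#' @param a,b Non-empty numeric speed vectors or [velocity_sequence()]s.
#' @return A non-negative number.
#' @export
velocity_term <- function(a, b) {
  a <- as_speed_vector(a)
  b <- as_speed_vector(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("velocity_term() requires non-empty sequences.")
  }
  (mean(a) - mean(b))^2
}

# DTW distance value only (no path recovery) -- the hot path for Gram
# matrices.
dtw_dist_value <- function(a, b, cfg, normalize = TRUE) {
  d <- .dtw_table(a, b,
    constraint = match(cfg$constraint, c("standard_a", "extended_b")) - 1L,
    boundary = match(cfg$boundary, c("standard", "literal")) - 1L,
    local_cost = match(cfg$local_cost, c("absolute", "squared")) - 1L
  )[length(a), length(b)]
  if (normalize) d / (length(a) + length(b)) else d
}

#' VDS kernel between two velocity sequences
#'
#' @param a,b Non-empty numeric speed vectors or [velocity_sequence()]s.
#'   They are used as given; any training-set normalization is the caller's
#'   (i.e. the model's) responsibility.
#' @param cfg A [kernel_config()].
#' @return Kernel value in `(0, 1]`; `K(a, a) = 1` under the standard DTW
#'   boundary.
#' @export
vds_kernel <- function(a, b, cfg = kernel_config()) {
  a <- as_speed_vector(a)
  b <- as_speed_vector(b)
  D <- dtw_dist_value(a, b, cfg$dtw, normalize = cfg$normalize_dtw)
  V <- velocity_term(a, b)
  exp(-(cfg$alpha * D + (1 - cfg$alpha) * V) / (2 * cfg$sigma^2))
}

#' Gram matrix of the VDS kernel
#'
#' @param x List of numeric speed vectors.
#' @param y Optional second list; when `NULL` the symmetric `x` vs `x` Gram
#'   matrix is computed (upper triangle mirrored).
#' @param cfg A [kernel_config()].
#' @return A numeric matrix of kernel evaluations, `length(x)` by
#'   `length(y %||% x)`.
#' @export
vds_gram <- function(x, y = NULL, cfg = kernel_config()) {
  x <- lapply(x, as_speed_vector)
  if (is.null(y)) {
    n <- length(x)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      K[i, i] <- vds_kernel(x[[i]], x[[i]], cfg)
      if (i < n) {
        for (j in (i + 1L):n) {
          K[i, j] <- K[j, i] <- vds_kernel(x[[i]], x[[j]], cfg)
        }
      }
    }
    K
  } else {
    y <- lapply(y, as_speed_vector)
    K <- matrix(0, length(x), length(y))
    for (i in seq_along(x)) {
      for (j in seq_along(y)) {
        K[i, j] <- vds_kernel(x[[i]], y[[j]], cfg)
      }
    }
    K
  }
}
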