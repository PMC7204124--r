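#' @title VDS sequence classifier
#' @description Soft-margin SVM over velocity sequences with the mixed
#'   DTW/velocity RBF kernel, trained by solving the dual quadratic program
#'   on the precomputed Gram matrix.
#' @name vds_train
NULL

# Solve the soft-margin SVM dual on a precomputed Gram matrix.
# Returns dual coefficients, bias, and whether the Gram matrix needed a
# positive-semidefinite repair (negative eigenvalues clipped to zero before
# solving; out-of-sample kernel rows are later used unrepaired).
solve_svm_dual <- function(K, y, C) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  repaired <- min(eg$values) < -1e-8 * max(abs(eg$values), 1)
  K_solve <- if (repaired) {
    eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  } else {
    K
  }
  H <- (y %*% t(y)) * K_solve + diag(1e-8, n)
  sol <- kernlab::ipop(
    c = rep(-1, n), H = H,
    A = matrix(y, nrow = 1), b = 0, r = 0,
    l = rep(0, n), u = rep(C, n), sigf = 9
  )
  alpha <- pmin(pmax(kernlab::primal(sol), 0), C)
  tol <- C * 1e-5
  alpha[alpha < tol] <- 0
  # dropping near-zero coefficients perturbs the equality constraint
  # sum(alpha * y) = 0; project the kept coefficients back onto it
  defect <- sum(alpha * y)
  adj <- which(alpha > tol & alpha < C * (1 - 1e-6))
  if (length(adj) == 0L) adj <- which(alpha > tol)
  alpha[adj] <- alpha[adj] - y[adj] * defect / length(adj)
  alpha <- pmin(pmax(alpha, 0), C)
  g <- as.vector(K_solve %*% (alpha * y))
  free <- alpha > tol & alpha < C * (1 - 1e-6)
  if (any(free)) {
    b <- mean(y[free] - g[free])
  } else {
    # all support vectors at bound: take the midpoint of the KKT-feasible
    # interval for the bias
    lower <- c((1 - g)[y == 1 & alpha == 0], (-1 - g)[y == -1 & alpha > 0])
    upper <- c((1 - g)[y == 1 & alpha > 0], (-1 - g)[y == -1 & alpha == 0])
    lo <- if (length(lower)) max(lower) else -Inf
    up <- if (length(upper)) min(upper) else Inf
    b <- if (is.finite(lo) && is.finite(up)) (lo + up) / 2 else 0
  }
  list(alpha = alpha, bias = b, repaired = repaired, gram_solved = K_solve)
}

check_training_frame <- function(data) {
  if (!is.data.frame(data) || !all(c("sequence", "label") %in% names(data))) {
    abort("Training data must be a data frame with `sequence` and `label` columns.")
  }
  if (!all(data$label %in% c(-1, 1))) {
    abort("Labels must be +1 or -1.")
  }
  if (nrow(data) < 2L) abort("Need at least 2 training samples.")
  if (length(unique(data$label)) < 2L) {
    abort("Training data must contain both classes (+1 and -1).")
  }
  seqs <- lapply(data$sequence, as_speed_vector)
  if (any(lengths(seqs) == 0L)) abort("Empty velocity sequences are not allowed.")
  if (length(unique(seqs)) == 1L) {
    abort("Degenerate training set: all velocity sequences are identical.")
  }
  seqs
}

pooled_speed_stats <- function(seqs) {
  v <- unlist(seqs)
  list(mean = mean(v), sd = sd(v))
}

apply_normalization <- function(seqs, stats, mode) {
  if (mode == "none") return(seqs)
  s <- if (is.na(stats$sd) || stats$sd == 0) 1 else stats$sd
  lapply(seqs, function(x) (x - stats$mean) / s)
}

#' Train the VDS classifier
#'
#' Precomputes the full Gram matrix of the mixed DTW/velocity kernel over
#' the training sequences, solves the soft-margin SVM dual with penalty `C`,
#' and keeps the support sequences, dual coefficients and bias. The mixed
#' kernel is not guaranteed positive semidefinite (DTW is not a metric
#' embedding), so when the Gram matrix has meaningfully negative eigenvalues
#' they are clipped to zero before solving and the model records that the
#' repair happened.
#'
#' @param data A data frame with a `sequence` list-column (numeric speed
#'   vectors or [velocity_sequence()]s) and a `label` column of +1/-1.
#' @param kernel A [kernel_config()].
#' @return An object of class `vds_model`.
#' @examples
#' d <- generate_sequences(5, separable_profiles(), seed = 1)
#' m <- vds_train(d)
#' mean(predict(m, d) == d$label)
#' @export
vds_train <- function(data, kernel = kernel_config()) {
  seqs <- check_training_frame(data)
  y <- as.numeric(data$label)
  stats <- pooled_speed_stats(seqs)
  transformed <- apply_normalization(seqs, stats, kernel$normalize_inputs)
  K <- vds_gram(transformed, cfg = kernel)
  fit <- solve_svm_dual(K, y, kernel$C)
  sv <- which(fit$alpha > 0)
  if (length(sv) == 0L) abort("Training produced no support vectors.")
  structure(
    list(
      support = tibble::tibble(
        index = sv,
        label = y[sv],
        dual_coef = fit$alpha[sv],
        coef = fit$alpha[sv] * y[sv]
      ),
      support_sequences = seqs[sv],
      support_transformed = transformed[sv],
      bias = fit$bias,
      kernel = kernel,
      stats = stats,
      gram_repaired = fit$repaired,
      n_train = length(y),
      class_counts = table(factor(y, levels = c(-1, 1)))
    ),
    class = "vds_model"
  )
}

#' Predict phlegm-stagnation status for velocity sequences
#'
#' The decision value is `sum_i coef_i * K(x_i, x) + b` over the support
#' sequences; the class is its sign, with a decision value of exactly zero
#' mapped to +1.
#'
#' @param object A `vds_model`.
#' @param newdata A numeric speed vector, a list of them, a
#'   [velocity_sequence()], or a data frame with a `sequence` column.
#' @param type `"class"` for +1/-1 labels, `"decision"` for raw decision
#'   values.
#' @param ... Unused.
#' @return A numeric vector, one element per input sequence.
#' @export
predict.vds_model <- function(object, newdata,
                              type = c("class", "decision"), ...) {
  type <- match.arg(type)
  seqs <- as_sequence_list(newdata)
  transformed <- apply_normalization(seqs, object$stats,
                                     object$kernel$normalize_inputs)
  K <- vds_gram(transformed, object$support_transformed, cfg = object$kernel)
  dec <- as.vector(K %*% object$support$coef) + object$bias
  if (type == "decision") dec else ifelse(dec >= 0, 1, -1)
}

as_sequence_list <- function(newdata) {
  if (is.data.frame(newdata)) {
    if ("speed" %in% names(newdata)) return(list(as_speed_vector(newdata)))
    if ("sequence" %in% names(newdata)) {
      return(lapply(newdata$sequence, as_speed_vector))
    }
    abort("Data frame input needs a `sequence` (or `speed`) column.")
  }
  if (is.numeric(newdata)) return(list(as.numeric(newdata)))
  lapply(newdata, as_speed_vector)
}

#' @export
print.vds_model <- function(x, ...) {
  cat("<vds_model>\n")
  cat(sprintf("  %d training sequences (%d pos / %d neg), %d support vectors\n",
              x$n_train, x$class_counts[["1"]], x$class_counts[["-1"]],
              nrow(x$support)))
  cat(sprintf("  alpha=%.3g sigma=%.3g C=%.3g bias=%.4g gram_repaired=%s\n",
              x$kernel$alpha, x$kernel$sigma, x$kernel$C, x$bias,
              x$gram_repaired))
  invisible(x)
}

#' @rdname vds_train
#' @param x A `vds_model`.
#' @param ... Unused.
#' @return `tidy()` returns one row per support vector with its training
#'   index, label, dual coefficient and signed coefficient; `glance()` a
#'   one-row model summary.
#' @export
tidy.vds_model <- function(x, ...) x$support

#' @rdname vds_train
#' @export
glance.vds_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_support = nrow(x$support),
    bias = x$bias,
    alpha = x$kernel$alpha,
    sigma = x$kernel$sigma,
    C = x$kernel$C,
    normalize_inputs = x$kernel$normalize_inputs,
    gram_repaired = x$gram_repaired
  )
}

#' DTW nearest-template baseline
#'
#' Labels each query with the label of the training sequence at minimal DTW
#' distance (each training sequence acts as a template); ties keep the first
#' occurrence.
#'
#' @param train A data frame with `sequence` and `label` columns.
#' @param query A sequence or list of sequences.
#' @param dtw A [dtw_config()].
#' @param normalize_dtw Length-normalize distances by `M + N` (does not
#'   change the nearest neighbor for equal-length sequences).
#' @return Numeric vector of +1/-1 labels.
#' @export
baseline_dtw_1nn <- function(train, query, dtw = dtw_config(),
                             normalize_dtw = TRUE) {
  templates <- lapply(train$sequence, as_speed_vector)
  if (length(templates) == 0L) abort("Empty training set.")
  queries <- as_sequence_list(query)
  vapply(queries, function(q) {
    d <- vapply(templates, function(tmpl) {
      dtw_dist_value(q, tmpl, dtw, normalize = normalize_dtw)
    }, numeric(1))
    as.numeric(train$label[which.min(d)])
  }, numeric(1))
}

#' Linearly resample a sequence to a fixed length
#'
#' @param x Numeric vector.
#' @param length_out Target length (>= 1).
#' @return Numeric vector of length `length_out`.
#' @export
resample_sequence <- function(x, length_out) {
  x <- as_speed_vector(x)
  stopifnot(length_out >= 1)
  if (length(x) == 1L) return(rep(x, length_out))
  if (length(x) == length_out) return(x)
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = length_out))$y
}

#' Fixed-length-vector SVM baseline
#'
#' A plain RBF SVM cannot consume variable-length sequences, so each
#' sequence is linearly resampled to a common length first. Training reuses
#' the same dual solver as [vds_train()] with the Gaussian kernel
#' `exp(-||u - v||^2 / (2 sigma^2))` on the resampled vectors.
#'
#' @param data A data frame with `sequence` and `label` columns.
#' @param length_out Common length; defaults to the rounded median training
#'   length.
#' @param sigma RBF bandwidth; defaults to `sqrt(length_out)` on z-scored
#'   inputs (so per-coordinate differences of order 1 give kernel values of
#'   order `exp(-1/2)`).
#' @param C Soft-margin penalty.
#' @param normalize_inputs As in [kernel_config()].
#' @return An object of class `fixedvec_svm` with a `predict()` method.
#' @export
train_svm_fixedvec <- function(data, length_out = NULL, sigma = NULL, C = 10,
                               normalize_inputs = c("zscore_over_training",
                                                    "none")) {
  normalize_inputs <- match.arg(normalize_inputs)
  seqs <- check_training_frame(data)
  y <- as.numeric(data$label)
  if (is.null(length_out)) {
    length_out <- max(1L, round(stats::median(lengths(seqs))))
  }
  if (is.null(sigma)) sigma <- sqrt(length_out)
  stats <- pooled_speed_stats(seqs)
  transformed <- apply_normalization(seqs, stats, normalize_inputs)
  X <- t(vapply(transformed, resample_sequence, numeric(length_out),
                length_out = length_out))
  K <- rbf_gram(X, X, sigma)
  fit <- solve_svm_dual(K, y, C)
  sv <- which(fit$alpha > 0)
  structure(
    list(
      support_vectors = X[sv, , drop = FALSE],
      coef = fit$alpha[sv] * y[sv],
      bias = fit$bias,
      sigma = sigma, C = C, length_out = length_out,
      stats = stats, normalize_inputs = normalize_inputs,
      gram_repaired = fit$repaired
    ),
    class = "fixedvec_svm"
  )
}

rbf_gram <- function(A, B, sigma) {
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-pmax(sq, 0) / (2 * sigma^2))
}

#' @export
predict.fixedvec_svm <- function(object, newdata,
                                 type = c("class", "decision"), ...) {
  type <- match.arg(type)
  seqs <- as_sequence_list(newdata)
  transformed <- apply_normalization(seqs, object$stats,
                                     object$normalize_inputs)
  X <- t(vapply(transformed, resample_sequence, numeric(object$length_out),
                length_out = object$length_out))
  dec <- as.vector(rbf_gram(X, object$support_vectors, object$sigma) %*%
                     object$coef) + object$bias
  if (type == "decision") dec else ifelse(dec >= 0, 1, -1)
}
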