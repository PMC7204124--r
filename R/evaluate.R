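#' Compare classifiers by per-class detection rate
#'
#' Splits the labeled sequences into a stratified training and test set (or
#' stratified folds), trains each requested method on the training portion,
#' and reports the detection rate — the fraction of each class's test
#' samples assigned their true label — per method and class.
#'
#' @param data A data frame with `sequence` and `label` columns.
#' @param methods Any of `"vds"`, `"dtw_1nn"`, `"svm_fixedvec"`.
#' @param holdout Fraction of each class held out for testing (used when
#'   `n_folds` and `test_data` are `NULL`).
#' @param n_folds If given, stratified `n_folds`-fold cross-validation
#'   instead of a single holdout split; must not exceed the size of either
#'   class.
#' @param test_data If given, no splitting happens: every method trains on
#'   all of `data` and is scored on `test_data` (same columns).
#' @param kernel [kernel_config()] for the VDS method.
#' @param dtw [dtw_config()] for the DTW-1NN baseline.
#' @param C Penalty for the fixed-vector SVM baseline.
#' @param seed Integer seed controlling the split only.
#' @return A tibble of class `vds_evaluation` with columns `method`, `class`
#'   (+1/-1), `n_test`, `n_correct` and `detection_rate` (a fraction in
#'   `[0, 1]`), aggregated over folds when cross-validating.
#' @export
evaluate_methods <- function(data,
                             methods = c("vds", "dtw_1nn", "svm_fixedvec"),
                             holdout = 0.4, n_folds = NULL, test_data = NULL,
                             kernel = kernel_config(), dtw = dtw_config(),
                             C = 10, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(data$label %in% c(-1, 1)))
  if (!is.null(test_data)) {
    return(evaluate_split(data, test_data, methods, kernel, dtw, C))
  }
  idx_pos <- which(data$label == 1)
  idx_neg <- which(data$label == -1)
  if (length(idx_pos) < 2L || length(idx_neg) < 2L) {
    abort("Need at least 2 samples of each class to evaluate.")
  }
  folds <- if (is.null(n_folds)) {
    n_test_pos <- max(1L, round(holdout * length(idx_pos)))
    n_test_neg <- max(1L, round(holdout * length(idx_neg)))
    test <- with_seed(seed, c(sample(idx_pos, n_test_pos),
                              sample(idx_neg, n_test_neg)))
    list(test)
  } else {
    if (n_folds > length(idx_pos) || n_folds > length(idx_neg)) {
      abort(sprintf("n_folds = %d exceeds the size of a class.", n_folds))
    }
    with_seed(seed, {
      fp <- split(sample(idx_pos), rep_len(seq_len(n_folds), length(idx_pos)))
      fn <- split(sample(idx_neg), rep_len(seq_len(n_folds), length(idx_neg)))
      lapply(seq_len(n_folds), function(k) c(fp[[k]], fn[[k]]))
    })
  }
  tally <- list()
  for (test in folds) {
    tally <- score_split(data[-test, , drop = FALSE],
                         data[test, , drop = FALSE],
                         methods, kernel, dtw, C, tally)
  }
  tally_to_tibble(tally, methods)
}

score_split <- function(train, testd, methods, kernel, dtw, C,
                        tally = list()) {
  for (m in methods) {
    pred <- switch(m,
      vds = predict(vds_train(train, kernel = kernel), testd),
      dtw_1nn = baseline_dtw_1nn(train, testd, dtw = dtw),
      svm_fixedvec = predict(train_svm_fixedvec(train, C = C), testd)
    )
    for (cl in c(1, -1)) {
      sel <- testd$label == cl
      key <- paste(m, cl)
      prev <- tally[[key]] %||% c(0, 0)
      tally[[key]] <- prev + c(sum(pred[sel] == cl), sum(sel))
    }
  }
  tally
}

tally_to_tibble <- function(tally, methods) {
  rows <- list()
  for (m in methods) {
    for (cl in c(1, -1)) {
      v <- tally[[paste(m, cl)]]
      rows[[paste(m, cl)]] <- tibble::tibble(
        method = m, class = cl, n_test = v[2], n_correct = v[1],
        detection_rate = v[1] / v[2]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vds_evaluation", class(out))
  out
}

evaluate_split <- function(train, test, methods, kernel, dtw, C) {
  tally_to_tibble(score_split(train, test, methods, kernel, dtw, C), methods)
}

#' Detection rates over replicated synthetic datasets
#'
#' Learning-curve comparison across classifiers: per replicate, a fresh
#' test set of `test_per_class` sequences per class is generated and shared
#' by every training size and method, so all methods are scored on
#' identical test samples; per training size, a fresh training set is
#' generated and all methods train on it. Per-class detection rates are
#' stacked over replicates.
#'
#' @param n_per_class Vector of per-class training-set sizes to sweep.
#' @param n_replicates Replicates per size (fresh data each time).
#' @param test_per_class Test sequences per class per replicate.
#' @param profiles Motion profile pair, as in [generate_sequences()].
#' @param frame_count,frame_rate Clip geometry for the generator.
#' @inheritParams evaluate_methods
#' @return A `vds_evaluation` tibble with additional `n_per_class` and
#'   `replicate` columns.
#' @export
replicate_evaluation <- function(n_per_class = c(25, 50, 75),
                                 n_replicates = 10, test_per_class = 50,
                                 profiles = overlapping_profiles(),
                                 frame_count = 60, frame_rate = 10,
                                 methods = c("vds", "dtw_1nn", "svm_fixedvec"),
                                 kernel = kernel_config(), dtw = dtw_config(),
                                 C = 10, seed = 1) {
  out <- list()
  for (r in seq_len(n_replicates)) {
    test_seed <- (seed * 1009L + r * 7919L) %% .Machine$integer.max
    test <- generate_sequences(test_per_class, profiles,
                               frame_count = frame_count,
                               frame_rate = frame_rate, seed = test_seed)
    for (n in n_per_class) {
      train_seed <- (test_seed + n * 131L + 1L) %% .Machine$integer.max
      train <- generate_sequences(n, profiles, frame_count = frame_count,
                                  frame_rate = frame_rate, seed = train_seed)
      ev <- evaluate_methods(train, methods = methods, test_data = test,
                             kernel = kernel, dtw = dtw, C = C)
      ev$n_per_class <- n
      ev$replicate <- r
      out[[length(out) + 1L]] <- ev
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("vds_evaluation", class(res))
  res
}

#' Summarise an evaluation as mean detection rate per method
#'
#' @param ev A `vds_evaluation`, typically from [replicate_evaluation()].
#' @return A tibble with one row per method (and `n_per_class` when
#'   present) giving the mean detection rate across classes and replicates.
#' @export
summarise_evaluation <- function(ev) {
  keys <- intersect(c("method", "n_per_class"), names(ev))
  dplyr::summarise(
    dplyr::group_by(ev, dplyr::across(dplyr::all_of(keys))),
    mean_detection_rate = mean(.data$detection_rate),
    .groups = "drop"
  )
}

#' @export
autoplot.vds_evaluation <- function(object, ...) {
  s <- summarise_evaluation(object)
  if ("n_per_class" %in% names(s)) {
    ggplot2::ggplot(s, ggplot2::aes(x = .data$n_per_class,
                                    y = 100 * .data$mean_detection_rate,
                                    colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "training samples per class",
                    y = "mean detection rate (%)")
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$method,
                                 y = 100 * .data$detection_rate,
                                 fill = factor(.data$class))) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "detection rate (%)", fill = "class")
  }
}
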