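#' Serialize a trained VDS model to JSON
#'
#' The file holds the support sequences inline (original, untransformed
#' speeds), dual coefficients, bias, kernel configuration, normalization
#' statistics and the Gram-repair flag, so [read_model()] reconstructs a
#' model whose predictions match the original exactly.
#'
#' @param model A `vds_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "vds_model"))
  obj <- list(
    format = "vds_model",
    support = list(
      index = model$support$index,
      label = model$support$label,
      dual_coef = model$support$dual_coef,
      sequences = model$support_sequences
    ),
    bias = model$bias,
    kernel = list(
      alpha = model$kernel$alpha, sigma = model$kernel$sigma,
      C = model$kernel$C, normalize_inputs = model$kernel$normalize_inputs,
      normalize_dtw = model$kernel$normalize_dtw,
      dtw = unclass(model$kernel$dtw)
    ),
    stats = model$stats,
    gram_repaired = model$gram_repaired,
    n_train = model$n_train,
    class_counts = as.list(model$class_counts)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a VDS model written by [write_model()]
#'
#' @param path Path to the JSON file.
#' @return A `vds_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vds_model")) {
    abort(sprintf("'%s' is not a serialized vds_model.", path))
  }
  kcfg <- kernel_config(
    alpha = obj$kernel$alpha, sigma = obj$kernel$sigma, C = obj$kernel$C,
    normalize_inputs = obj$kernel$normalize_inputs,
    dtw = dtw_config(obj$kernel$dtw$constraint, obj$kernel$dtw$boundary,
                     obj$kernel$dtw$local_cost),
    normalize_dtw = obj$kernel$normalize_dtw
  )
  seqs <- obj$support$sequences
  if (!is.list(seqs)) seqs <- apply(seqs, 1, identity, simplify = FALSE)
  seqs <- lapply(seqs, as.numeric)
  stats <- list(mean = obj$stats$mean, sd = obj$stats$sd)
  structure(
    list(
      support = tibble::tibble(
        index = obj$support$index,
        label = obj$support$label,
        dual_coef = obj$support$dual_coef,
        coef = obj$support$dual_coef * obj$support$label
      ),
      support_sequences = seqs,
      support_transformed = apply_normalization(seqs, stats,
                                                kcfg$normalize_inputs),
      bias = obj$bias,
      kernel = kcfg,
      stats = stats,
      gram_repaired = obj$gram_repaired,
      n_train = obj$n_train,
      class_counts = obj$class_counts
    ),
    class = "vds_model"
  )
}

#' Write a motion track or velocity sequence as CSV
#'
#' Tracks use columns `frame_index,x,y[,area]`; velocity sequences
#' `pair_index,frame_from,frame_to,speed`. Coordinates are 0-based with
#' `x` = column and `y` = row.
#'
#' @param x A `motion_track` or `velocity_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a labeled sequence manifest
#'
#' Two-column CSV (`path,label`) pointing at per-sequence CSV files, the
#' on-disk format for training sets.
#'
#' @param data A data frame with `sequence` and `label` columns.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_sequence_manifest <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    p <- file.path(dir, sprintf("seq_%04d.csv", i))
    v <- as_speed_vector(data$sequence[[i]])
    utils::write.csv(
      data.frame(pair_index = seq_along(v), speed = v), p, row.names = FALSE
    )
    paths[i] <- basename(p)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(path = paths, label = data$label), manifest,
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a labeled sequence manifest written by [write_sequence_manifest()]
#'
#' @param manifest Path to `manifest.csv`; sequence paths are resolved
#'   relative to its directory.
#' @return A tibble with `sequence` and `label` columns.
#' @export
read_sequence_manifest <- function(manifest) {
  m <- utils::read.csv(manifest)
  base <- dirname(manifest)
  seqs <- lapply(m$path, function(p) {
    f <- if (file.exists(p)) p else file.path(base, p)
    utils::read.csv(f)$speed
  })
  tibble::tibble(sequence = seqs, label = m$label)
}
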