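#' Motion-detection configuration
#'
#' @param threshold Gray-level threshold `T` applied to the absolute frame
#'   difference (8-bit scale). Too large a threshold fragments or misses the
#'   target; too small floods the mask with noise. Set `threshold = "otsu"`
#'   to pick it per frame pair from the difference histogram.
#' @param morph_radius Radius in pixels of the disc structuring element used
#'   for morphological closing in [clean_and_select()] (fills interior
#'   holes and bridges small gaps).
#' @param min_area Smallest connected component (in pixels) kept as a
#'   candidate moving region.
#' @param open_radius Radius of the disc used for a morphological opening
#'   after the closing. Off (0) by default: the conjunction mask of a
#'   uniformly colored moving target is legitimately thin — interior pixels
#'   barely change between frames, so mostly the advancing and receding
#'   edges survive — and an opening erases exactly those; isolated noise
#'   specks are rejected by `min_area` instead.
#' @return A list of class `diff_config`.
#' @export
diff_config <- function(threshold = 25, morph_radius = 1, min_area = 9,
                        open_radius = 0) {
  if (!identical(threshold, "otsu")) {
    stopifnot(is.numeric(threshold), threshold > 0)
  }
  stopifnot(morph_radius >= 0, min_area >= 1, open_radius >= 0)
  structure(
    list(threshold = threshold, morph_radius = morph_radius,
         min_area = min_area, open_radius = open_radius),
    class = "diff_config"
  )
}

check_same_shape <- function(a, b, what = c("prev", "curr")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf(
      "Frame shape mismatch: %s is %dx%d but %s is %dx%d.",
      what[1], nrow(a), ncol(a), what[2], nrow(b), ncol(b)
    ))
  }
}

resolve_threshold <- function(D, cfg) {
  if (identical(cfg$threshold, "otsu")) {
    # Otsu on the 8-bit difference histogram; guard the no-contrast case.
    if (max(D) <= 0) return(Inf)
    EBImage::otsu(EBImage::Image(D / 255), range = c(0, 1), levels = 256) * 255
  } else {
    cfg$threshold
  }
}

#' Interframe difference mask
#'
#' Binarizes the absolute gray-level difference of two consecutive frames:
#' the mask is 1 where `|curr - prev| >= threshold`. This is the raw mask,
#' before any morphology.
#'
#' @param prev,curr Gray-level matrices of identical shape (values 0-255).
#' @param cfg A [diff_config()].
#' @param frame_index Optional index of the frame the mask describes,
#'   attached as the `frame_index` attribute.
#' @return An integer 0/1 matrix of class `motion_mask`.
#' @export
frame_difference <- function(prev, curr, cfg = diff_config(),
                             frame_index = NULL) {
  check_same_shape(prev, curr)
  D <- abs(curr - prev)
  thr <- resolve_threshold(D, cfg)
  new_motion_mask((D >= thr) * 1L, frame_index)
}

#' Three-frame difference mask
#'
#' Computes the two interframe masks of the triple `(prev, curr, nxt)` and
#' returns their pixelwise AND. The conjunction removes the "image tail" (the
#' ghost of the target's previous position) that a single pairwise difference
#' leaves behind, at the cost of occasional interior holes; those are filled
#' downstream by [clean_and_select()]. The result is attributed to the
#' central frame.
#'
#' @param prev,curr,nxt Gray-level matrices of identical shape.
#' @param cfg A [diff_config()].
#' @param frame_index Optional index of the central frame.
#' @return An integer 0/1 matrix of class `motion_mask`.
#' @export
three_frame_difference <- function(prev, curr, nxt, cfg = diff_config(),
                                   frame_index = NULL) {
  check_same_shape(prev, curr)
  check_same_shape(curr, nxt, what = c("curr", "next"))
  r1 <- frame_difference(prev, curr, cfg)
  r2 <- frame_difference(curr, nxt, cfg)
  new_motion_mask((unclass(r1) & unclass(r2)) * 1L, frame_index)
}

new_motion_mask <- function(mask, frame_index = NULL) {
  storage.mode(mask) <- "integer"
  structure(mask, frame_index = frame_index, class = c("motion_mask", "matrix"))
}

#' Morphological cleanup and largest-region selection
#'
#' Applies a morphological closing with a disc of radius `morph_radius`
#' (fills interior holes), optionally followed by an opening with a disc of
#' radius `open_radius` (removes thin structures and specks; off by
#' default, see [diff_config()]), labels the surviving 8-connected
#' components, drops components smaller than `min_area`, and returns the
#' largest one. Ties on area are broken by the smallest bounding-box
#' top-left corner (row first, then column).
#'
#' @param mask A binary matrix (typically from [three_frame_difference()]).
#' @param cfg A [diff_config()].
#' @return A list with `mask` (the cleaned binary `motion_mask`) and `region`
#'   (a tibble of member pixel coordinates `x`, `y`, 0-based with
#'   `x` = column and `y` = row, or `NULL` when no component survives).
#' @export
clean_and_select <- function(mask, cfg = diff_config()) {
  m <- unclass(mask) * 1
  if (cfg$morph_radius >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(cfg$morph_radius) + 1L, "disc")
    m <- round(as.matrix(EBImage::imageData(EBImage::closing(m, brush))))
  }
  if (cfg$open_radius >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(cfg$open_radius) + 1L, "disc")
    m <- round(as.matrix(EBImage::imageData(EBImage::opening(m, brush))))
  }
  cleaned <- new_motion_mask(m, attr(mask, "frame_index"))
  lab <- .label_components8(unclass(cleaned))
  n_comp <- max(lab)
  if (n_comp == 0L) {
    return(list(mask = cleaned, region = NULL))
  }
  areas <- tabulate(lab[lab > 0L], nbins = n_comp)
  keep <- which(areas >= cfg$min_area)
  if (length(keep) == 0L) {
    return(list(mask = cleaned, region = NULL))
  }
  best_area <- max(areas[keep])
  cand <- keep[areas[keep] == best_area]
  if (length(cand) > 1L) {
    # tie-break: smallest top-left bounding-box corner, row then column
    corners <- vapply(cand, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      c(min(idx[, 1L]), min(idx[, 2L]))
    }, numeric(2))
    ord <- order(corners[1L, ], corners[2L, ])
    cand <- cand[ord]
  }
  idx <- which(lab == cand[1L], arr.ind = TRUE)
  region <- tibble::tibble(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
  list(mask = cleaned, region = region[order(region$x, region$y), ])
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask A `motion_mask` or binary matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(unclass(mask) * 1, target = path)
  invisible(path)
}
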