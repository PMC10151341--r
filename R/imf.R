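#' Inframammary-fold detector configuration
#'
#' The IMF detector slides a square window upward from the bottom of the
#' standardized image, binarizes each window at a global threshold, and stops
#' at the first position where foreground occupies more than `stop_fraction`
#' of the window.
#'
#' @param roi_size Window side in pixels (256 at full resolution; use 64 for
#'   quarter-scale phantoms).
#' @param threshold Global binarization threshold on normalized intensity,
#'   strict comparison (`intensity/255 > threshold`).
#' @param stop_fraction Foreground fraction that must be exceeded (strictly)
#'   for the scan to stop; 0.25 is "more than a quarter of the window".
#' @param scan_stride Upward step in pixels between candidate positions.
#' @param col_anchor Horizontal placement of the window: `"chest_wall"`
#'   (flush against the right edge, where the fold lies under the canonical
#'   orientation) or `"center"`.
#' @return A list of class `imf_config`.
#' @export
imf_config <- function(roi_size = 256L, threshold = 0.8, stop_fraction = 0.25,
                       scan_stride = 16L, col_anchor = c("chest_wall", "center")) {
  col_anchor <- match.arg(col_anchor)
  if (!is_count(roi_size)) abort("roi_size must be a positive integer", class = "mammoqc_config_error")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly in (0, 1)", class = "mammoqc_config_error")
  }
  if (!is.numeric(stop_fraction) || stop_fraction <= 0 || stop_fraction >= 1) {
    abort("stop_fraction must lie strictly in (0, 1)", class = "mammoqc_config_error")
  }
  if (!is_count(scan_stride) || scan_stride > roi_size) {
    abort("scan_stride must be an integer in [1, roi_size]", class = "mammoqc_config_error")
  }
  structure(
    list(roi_size = as.integer(roi_size), threshold = threshold,
         stop_fraction = stop_fraction, scan_stride = as.integer(scan_stride),
         col_anchor = col_anchor),
    class = "imf_config"
  )
}

#' Binarize a region at a global normalized threshold
#'
#' @param region Numeric matrix with intensities in `[0, 255]`.
#' @param threshold Normalized threshold in `[0, 1]`; a pixel is foreground
#'   iff `intensity/255 > threshold` (strict).
#' @return A logical matrix of the same shape.
#' @export
binarize_global <- function(region, threshold) {
  if (!is.matrix(region) || length(region) == 0L) {
    abort("`region` must be a non-empty matrix", class = "mammoqc_input_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    abort("threshold must be a single value in [0, 1]", class = "mammoqc_config_error")
  }
  region / 255 > threshold
}

#' Count foreground pixels in a binary mask
#'
#' @param mask Logical matrix.
#' @return Integer count of `TRUE` entries.
#' @export
count_foreground <- function(mask) {
  if (length(mask) == 0L) abort("empty mask", class = "mammoqc_input_error")
  sum(mask)
}

roi_box <- function(row0, col0, size) {
  list(row0 = as.integer(row0), col0 = as.integer(col0),
       height = as.integer(size), width = as.integer(size))
}

crop_box <- function(img, box) {
  img[box$row0:(box$row0 + box$height - 1L),
      box$col0:(box$col0 + box$width - 1L), drop = FALSE]
}

new_roi_detection <- function(part, box, patch, foreground_fraction, converged,
                              extremum = NULL, n_steps = NA_integer_) {
  structure(
    list(part = part, box = box, patch = patch,
         foreground_fraction = foreground_fraction, converged = converged,
         extremum = extremum, n_steps = as.integer(n_steps)),
    class = "roi_detection"
  )
}

#' @export
print.roi_detection <- function(x, ...) {
  cat(sprintf("<roi_detection:%s> box [%d..%d] x [%d..%d], fg=%.3f, converged=%s\n",
              x$part, x$box$row0, x$box$row0 + x$box$height - 1L,
              x$box$col0, x$box$col0 + x$box$width - 1L,
              x$foreground_fraction, x$converged))
  if (!is.null(x$extremum)) {
    cat(sprintf("  extremum (row=%d, col=%d)\n", x$extremum$row, x$extremum$col))
  }
  invisible(x)
}

#' Detect the inframammary-fold region
#'
#' Places a `roi_size` square window with its bottom edge on the image's
#' bottom edge at the configured column anchor, then repeatedly moves it up
#' by `scan_stride` while the strict-threshold foreground fraction is at most
#' `stop_fraction`. The first window exceeding the stop fraction is cropped
#' and returned with `converged = TRUE`. If the window reaches the top of
#' the image without meeting the criterion, the topmost window is returned
#' with `converged = FALSE` and a warning.
#'
#' @param img Standardized image matrix (values in `[0, 255]`).
#' @param cfg An [imf_config()].
#' @return A `roi_detection` object with fields `box`, `patch`,
#'   `foreground_fraction`, `converged`, `n_steps`.
#' @export
detect_imf <- function(img, cfg = imf_config()) {
  assert_image_matrix(img)
  k <- cfg$roi_size
  if (nrow(img) < k || ncol(img) < k) {
    abort(sprintf("image (%d x %d) smaller than roi_size %d", nrow(img), ncol(img), k),
          class = "mammoqc_size_error")
  }
  col0 <- switch(cfg$col_anchor,
                 chest_wall = ncol(img) - k + 1L,
                 center = (ncol(img) - k) %/% 2L + 1L)
  start <- nrow(img) - k + 1L
  positions <- unique(c(seq.int(start, 1L, by = -cfg$scan_stride), 1L))
  area <- k * k
  for (i in seq_along(positions)) {
    box <- roi_box(positions[i], col0, k)
    patch <- crop_box(img, box)
    frac <- count_foreground(binarize_global(patch, cfg$threshold)) / area
    if (frac > cfg$stop_fraction) {
      return(new_roi_detection("imf", box, patch, frac, TRUE, n_steps = i - 1L))
    }
  }
  warn(sprintf("IMF scan did not converge (top window foreground %.3f <= %.2f)",
               frac, cfg$stop_fraction), class = "mammoqc_nonconvergence")
  new_roi_detection("imf", box, patch, frac, FALSE, n_steps = length(positions) - 1L)
}
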