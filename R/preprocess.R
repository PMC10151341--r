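#' Preprocessing configuration
#'
#' Controls standardization of raw mammograms: target size, interpolation,
#' and the fixed orientation convention. The canonical geometry used by all
#' downstream detectors is: chest wall along the RIGHT image edge, nipple
#' pointing toward the left-bottom. Left-laterality images are mirrored into
#' this frame.
#'
#' @param resize_cols,resize_rows Target image size in pixels. The defaults
#'   (2730 wide, 4096 tall) are the standard full-resolution working size;
#'   tests and phantom work typically run at 1/4 scale (682 x 1024).
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(resize_cols = 2730L, resize_rows = 4096L,
                              interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!is_count(resize_cols) || !is_count(resize_rows)) {
    abort("resize dimensions must be positive integers", class = "mammoqc_config_error")
  }
  structure(
    list(resize_cols = as.integer(resize_cols),
         resize_rows = as.integer(resize_rows),
         interpolation = interpolation,
         orientation = "chest_wall_right"),
    class = "preprocess_config"
  )
}

#' Construct a raw mammogram object
#'
#' @param pixels Numeric matrix of non-negative intensities (rows x cols).
#' @param laterality `"left"`, `"right"` or `"unknown"`.
#' @param bit_depth Positive integer (8 or 16 for PNG sources).
#' @param source_id Opaque identifier (usually the file name).
#' @return A list of class `mammogram` with fields `pixels`, `laterality`,
#'   `bit_depth`, `source_id`.
#' @export
mammogram <- function(pixels, laterality = c("unknown", "left", "right"),
                      bit_depth = 8L, source_id = "") {
  laterality <- match.arg(laterality)
  assert_image_matrix(pixels, "pixels")
  if (any(pixels < 0)) {
    abort("mammogram intensities must be non-negative", class = "mammoqc_input_error")
  }
  if (!is_count(bit_depth)) {
    abort("bit_depth must be a positive integer", class = "mammoqc_input_error")
  }
  structure(
    list(pixels = pixels, laterality = laterality,
         bit_depth = as.integer(bit_depth), source_id = as.character(source_id)),
    class = "mammogram"
  )
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram> %d x %d, %d-bit, laterality=%s, source=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$laterality,
              if (nzchar(x$source_id)) x$source_id else "<none>"))
  invisible(x)
}

# PNG IHDR layout: 8-byte signature, 4-byte length, "IHDR", width(4), height(4),
# bit depth(1), colour type(1). We only need the two metadata bytes that
# png::readPNG discards.
png_header_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 26L)
  if (length(hdr) < 26L) abort("not a PNG file (truncated header)", class = "mammoqc_io_error")
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

laterality_from_filename <- function(path) {
  tokens <- toupper(strsplit(basename(path), "[^[:alnum:]]+")[[1]])
  left <- c("L", "LEFT", "LMLO", "LCC")
  right <- c("R", "RIGHT", "RMLO", "RCC")
  if (any(tokens %in% left) && !any(tokens %in% right)) return("left")
  if (any(tokens %in% right) && !any(tokens %in% left)) return("right")
  "unknown"
}

#' Read a grayscale mammogram from disk
#'
#' Reads an 8- or 16-bit grayscale PNG, preserving the source integer
#' intensities, and parses laterality from the file name when possible
#' (tokens such as `LEFT`, `L`, `RMLO` delimited by non-alphanumerics).
#'
#' @param path Path to the image file.
#' @param format `"png"`. (`"dicom"` is recognised but not supported; convert
#'   DICOM exports to 16-bit PNG first.)
#' @param laterality Optional override; if `NULL`, parsed from the file name,
#'   defaulting to `"unknown"`.
#' @return A [mammogram()] object.
#' @export
read_mammogram <- function(path, format = c("png", "dicom"), laterality = NULL) {
  format <- match.arg(format)
  if (format == "dicom") {
    abort("DICOM input is not supported; export to 16-bit grayscale PNG first",
          class = "mammoqc_io_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mammoqc_io_error")
  }
  info <- png_header_info(path)
  if (!info$color_type %in% c(0L, 4L)) {
    abort(sprintf("expected a grayscale PNG, got colour type %d: %s",
                  info$color_type, path), class = "mammoqc_format_error")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # drop alpha plane
  scale <- 2^info$bit_depth - 1
  px <- round(px * scale)
  lat <- laterality %||% laterality_from_filename(path)
  mammogram(px, laterality = lat, bit_depth = info$bit_depth,
            source_id = basename(path))
}

#' Write a standardized image or patch as 8-bit PNG
#'
#' @param img Numeric matrix with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  assert_image_matrix(img, "img")
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
  invisible(path)
}

#' Infer laterality from image content
#'
#' Fallback when neither metadata nor the file name carries laterality: the
#' breast is much brighter than background, so the image half with the larger
#' summed intensity is the chest-wall side.
#'
#' @param img A [mammogram()] or a numeric matrix.
#' @return `"left"` or `"right"`.
#' @export
infer_laterality <- function(img) {
  px <- if (inherits(img, "mammogram")) img$pixels else img
  assert_image_matrix(px, "img")
  nc <- ncol(px)
  half <- nc %/% 2L
  left_sum <- sum(px[, seq_len(half)])
  right_sum <- sum(px[, (nc - half + 1L):nc])
  if (left_sum == right_sum) {
    abort("cannot infer laterality: image halves have identical mass",
          class = "mammoqc_detection_error")
  }
  if (left_sum > right_sum) "left" else "right"
}

resize_matrix <- function(m, rows, cols, interpolation) {
  if (nrow(m) == rows && ncol(m) == cols) return(m)
  filt <- if (interpolation == "nearest") "none" else "bilinear"
  # EBImage's first array dimension is our row dimension
  out <- EBImage::resize(m, w = rows, h = cols, filter = filt)
  matrix(as.numeric(out), rows, cols)
}

#' Standardize a mammogram into the canonical working frame
#'
#' Mirrors left-laterality images about the vertical axis so the chest wall
#' lies along the right image edge, stretches to the configured size, and
#' min-max normalizes intensities onto the integer range 0..255. Unknown
#' laterality is resolved with [infer_laterality()].
#'
#' @param img A [mammogram()] object or a plain numeric matrix (treated as
#'   right laterality).
#' @param cfg A [preprocess_config()].
#' @return An integer-valued numeric matrix of size
#'   `resize_rows x resize_cols` with `min == 0` and `max == 255`.
#' @export
standardize <- function(img, cfg = preprocess_config()) {
  if (is.matrix(img)) img <- mammogram(img, laterality = "right")
  if (!inherits(img, "mammogram")) {
    abort("`img` must be a mammogram or a numeric matrix", class = "mammoqc_input_error")
  }
  px <- img$pixels
  lat <- img$laterality
  if (lat == "unknown") lat <- infer_laterality(px)
  if (lat == "left") px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  px <- resize_matrix(px, cfg$resize_rows, cfg$resize_cols, cfg$interpolation)
  rng <- range(px)
  if (rng[1] == rng[2]) {
    abort("constant image: no dynamic range to normalize",
          class = "mammoqc_normalization_error")
  }
  round((px - rng[1]) / (rng[2] - rng[1]) * 255)
}
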