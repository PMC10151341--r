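label_names <- c("poor", "average", "excellent")

#' Convert a positioning label to its integer code
#'
#' The three-level positioning-quality scale is coded 1 = poor, 2 = average,
#' 3 = excellent.
#'
#' @param x Integer codes in `{1,2,3}` or names in
#'   `{"poor","average","excellent"}` (vectorized).
#' @return Integer vector of codes.
#' @export
label_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(!x %in% 1:3)) abort("label codes must be 1, 2 or 3", class = "mammoqc_input_error")
    return(x)
  }
  m <- match(tolower(as.character(x)), label_names)
  if (any(is.na(m))) abort("labels must be poor/average/excellent or 1/2/3",
                           class = "mammoqc_input_error")
  m
}

#' @rdname label_code
#' @return For `label_name()`, a character vector of names.
#' @export
label_name <- function(x) label_names[label_code(x)]

#' Phantom specification
#'
#' Describes one synthetic MLO-like mammogram: a bright half-elliptical
#' breast against the chest-wall (right) edge on a dark background, a
#' pectoral wedge in the upper chest-wall corner, an optional nipple bump on
#' the breast contour, an optional bright inframammary-fold band near the
#' bottom, an optional radiopaque label block and border shading bands, plus
#' additive Gaussian noise. The rendered structure encodes the requested
#' positioning labels: an excellent fold label produces a thick bright band
#' that the IMF scan criterion detects, an average label a thin dimmer band,
#' a poor label none; an excellent nipple label produces a large in-profile
#' bump, average a small one, poor a smooth (off-profile) contour.
#'
#' @param seed Integer; the phantom is byte-reproducible given the seed.
#' @param image_shape `c(rows, cols)`; the default 1024 x 682 is 1/4 of the
#'   full-resolution working size, matching an ROI side of 64.
#' @param label_imf,label_nipple Positioning labels (codes or names).
#' @param nipple_in_profile If `NULL`, derived from `label_nipple`
#'   (poor means off-profile).
#' @param imf_band_intensity Normalized band intensity; if `NULL`, 0.95 for
#'   excellent and 0.85 for average.
#' @param add_artifacts Add a bright radiopaque label block away from the
#'   breast.
#' @param add_border_shading Add bright shading strips along image borders.
#' @param laterality `"right"` (rendered as-is, chest wall right) or
#'   `"left"` (mirrored, as acquired images of the left breast are).
#' @param noise_sd Additive Gaussian noise standard deviation on the
#'   normalized 0..1 scale.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed, image_shape = c(1024L, 682L),
                         label_imf = "excellent", label_nipple = "excellent",
                         nipple_in_profile = NULL, imf_band_intensity = NULL,
                         add_artifacts = TRUE, add_border_shading = TRUE,
                         laterality = c("right", "left"), noise_sd = 0.02) {
  laterality <- match.arg(laterality)
  if (!is_count(seed, min = 0L)) abort("seed must be a non-negative integer",
                                       class = "mammoqc_config_error")
  if (length(image_shape) != 2L || any(image_shape < 128L)) {
    abort("image_shape must be c(rows, cols) with both >= 128",
          class = "mammoqc_config_error")
  }
  li <- label_code(label_imf); ln <- label_code(label_nipple)
  structure(
    list(seed = as.integer(seed), image_shape = as.integer(image_shape),
         label_imf = li, label_nipple = ln,
         nipple_in_profile = nipple_in_profile %||% (ln != 1L),
         imf_band_intensity = imf_band_intensity,
         add_artifacts = isTRUE(add_artifacts),
         add_border_shading = isTRUE(add_border_shading),
         laterality = laterality, noise_sd = noise_sd),
    class = "phantom_spec"
  )
}

disk_mask <- function(rr, cc, r0, c0, radius) {
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

#' Generate one ground-truthed phantom mammogram
#'
#' Renders the phantom described by `spec` and returns both the image and
#' the exact ground truth. Truth coordinates always refer to the canonical
#' orientation (chest wall right); for a left-laterality phantom the pixel
#' array is mirrored but the truth matches the image after [standardize()].
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (a [mammogram()]) and `truth`: `nipple_rc`
#'   (row, col), `imf_rows` (first, last rows of the fold band, or `NULL`),
#'   `breast_bottom_row`, `breast_mask` (noise-free silhouette, canonical
#'   orientation), `labels` (`c(imf, nipple)`), `nipple_in_profile`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec",
                                             class = "mammoqc_input_error")
  R <- spec$image_shape[1]; C <- spec$image_shape[2]
  with_seed(spec$seed, {
    j <- runif(4, -0.02, 0.02)
    r0 <- (0.52 + j[1]) * R          # breast centre row
    a  <- (0.58 + j[2]) * C          # horizontal semi-axis
    b  <- (0.33 + j[3]) * R          # vertical semi-axis
    hp <- (0.42 + j[4]) * R          # pectoral wedge height
    wp <- 0.33 * C                   # pectoral wedge width
    ca <- C - a                      # breast apex column

    rr <- matrix(seq_len(R), R, C)
    cc <- matrix(seq_len(C), R, C, byrow = TRUE)

    img <- matrix(0.05, R, C)
    d2 <- ((cc - C) / a)^2 + ((rr - r0) / b)^2
    breast <- d2 <= 1
    img[breast] <- 0.5 + 0.1 * (1 - d2[breast])

    wedge <- (rr / hp + (C - cc) / wp) <= 1
    img[wedge] <- pmax(img[wedge], 0.72)

    # nipple bump on the contour apex; size encodes the nipple label
    if (spec$nipple_in_profile) {
      rn <- round((if (spec$label_nipple >= 3L) 0.013 else 0.008) * R)
      bump <- disk_mask(rr, cc, r0, ca, rn)
      img[bump] <- pmax(img[bump], 0.52)
      breast <- breast | bump
      # exact left-bottom extremum of the rendered bump: the point the
      # nipple detector is supposed to recover
      bi <- which(bump)
      br <- ((bi - 1L) %% R) + 1L
      bc <- ((bi - 1L) %/% R) + 1L
      cmin <- min(bc)
      nipple_rc <- c(max(br[bc == cmin]), cmin)
    } else {
      nipple_rc <- c(round(r0), round(ca + 15))
    }

    # inframammary fold band near the bottom of the breast
    rbot <- round(r0 + b)
    imf_rows <- NULL
    if (spec$label_imf >= 2L) {
      h <- if (spec$label_imf == 3L) round(0.024 * R) else round(0.010 * R)
      inten <- spec$imf_band_intensity %||% (if (spec$label_imf == 3L) 0.95 else 0.85)
      rows <- (rbot - h + 1L):rbot
      cols <- round(C - 0.45 * a):C
      img[rows, cols] <- pmax(img[rows, cols], inten)
      imf_rows <- c(rows[1], rows[length(rows)])
    }

    if (spec$add_artifacts) {
      ar <- round(0.06 * R):(round(0.06 * R) + round(0.03 * R))
      ac <- round(0.08 * C):(round(0.08 * C) + round(0.06 * C))
      img[ar, ac] <- 0.95
    }
    if (spec$add_border_shading) {
      sw <- 6L
      img[, seq_len(sw)] <- pmax(img[, seq_len(sw)], 0.38)
      img[(R - sw + 1L):R, ] <- pmax(img[(R - sw + 1L):R, ], 0.38)
    }

    img <- clamp(img + rnorm(R * C, 0, spec$noise_sd), 0, 1)
    px <- round(img * 255)
    if (spec$laterality == "left") px <- px[, rev(seq_len(C)), drop = FALSE]

    list(
      image = mammogram(px, laterality = spec$laterality, bit_depth = 8L,
                        source_id = sprintf("phantom-%d", spec$seed)),
      truth = list(nipple_rc = nipple_rc, imf_rows = imf_rows,
                   breast_bottom_row = rbot, breast_mask = breast,
                   labels = c(imf = spec$label_imf, nipple = spec$label_nipple),
                   nipple_in_profile = spec$nipple_in_profile)
    )
  })
}

#' Generate a labeled phantom dataset
#'
#' Draws per-image positioning labels from `class_mix` and renders one
#' phantom per row. The default mix mirrors the strong class imbalance of
#' screening programmes, where most images fail at least one criterion.
#'
#' @param n Number of phantoms.
#' @param class_mix Length-3 fractions (poor, average, excellent) summing
#'   to 1.
#' @param seed Master seed; per-image seeds and label draws derive from it.
#' @param ... Further arguments passed to [phantom_spec()] (e.g.
#'   `image_shape`, `noise_sd`).
#' @return A tibble with columns `id`, `seed`, `label_imf`, `label_nipple`,
#'   `nipple_row`, `nipple_col`, `imf_first`, `imf_last`,
#'   `breast_bottom_row`, and a list-column `image` of [mammogram()]s.
#' @export
generate_dataset <- function(n, class_mix = c(0.75, 0.16, 0.09), seed = 1L, ...) {
  if (!is_count(n, min = 0L)) abort("n must be a non-negative integer",
                                    class = "mammoqc_config_error")
  if (length(class_mix) != 3L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-9) {
    abort("class_mix must be 3 non-negative fractions summing to 1",
          class = "mammoqc_config_error")
  }
  cols <- c("id", "seed", "label_imf", "label_nipple", "nipple_row",
            "nipple_col", "imf_first", "imf_last", "breast_bottom_row")
  if (n == 0L) {
    out <- tibble::as_tibble(stats::setNames(rep(list(integer(0)), length(cols)), cols))
    out$image <- list()
    return(out)
  }
  draws <- with_seed(seed, {
    list(imf = sample.int(3L, n, replace = TRUE, prob = class_mix),
         nip = sample.int(3L, n, replace = TRUE, prob = class_mix),
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  rows <- purrr::map(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_spec(seed = draws$seeds[i],
                                        label_imf = draws$imf[i],
                                        label_nipple = draws$nip[i], ...))
    tr <- ph$truth
    tibble::tibble(
      id = sprintf("phantom-%04d", i), seed = draws$seeds[i],
      label_imf = draws$imf[i], label_nipple = draws$nip[i],
      nipple_row = tr$nipple_rc[1], nipple_col = tr$nipple_rc[2],
      imf_first = if (is.null(tr$imf_rows)) NA_integer_ else tr$imf_rows[1],
      imf_last = if (is.null(tr$imf_rows)) NA_integer_ else tr$imf_rows[2],
      breast_bottom_row = tr$breast_bottom_row,
      image = list(ph$image)
    )
  })
  dplyr::bind_rows(rows)
}

#' Crop a patch at the ground-truth location of a positioning part
#'
#' Truth-located crops give class-separable patches independent of detector
#' behaviour, which is what controlled classifier experiments need. For the
#' fold part the window sits flush against the chest wall with its bottom
#' edge just below the breast's bottom row; for the nipple part it is
#' centred on the true nipple coordinate (clamped to the image).
#'
#' @param img Standardized image matrix.
#' @param truth Truth list from [generate_phantom()] (or a dataset row's
#'   truth columns assembled into a list with `nipple_rc` and
#'   `breast_bottom_row`).
#' @param part `"imf"` or `"nipple"`.
#' @param roi_size Patch side in pixels.
#' @return A `roi_size` square matrix.
#' @export
extract_truth_patch <- function(img, truth, part = c("imf", "nipple"),
                                roi_size = 64L) {
  part <- match.arg(part)
  assert_image_matrix(img)
  k <- as.integer(roi_size)
  if (part == "imf") {
    wb <- clamp(truth$breast_bottom_row + 8L, k, nrow(img))
    box <- roi_box(wb - k + 1L, ncol(img) - k + 1L, k)
  } else {
    half <- k %/% 2L
    box <- roi_box(clamp(truth$nipple_rc[1] - half, 1L, nrow(img) - k + 1L),
                   clamp(truth$nipple_rc[2] - half, 1L, ncol(img) - k + 1L), k)
  }
  crop_box(img, box)
}
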