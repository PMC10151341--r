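#' Nipple-in-profile detector configuration
#'
#' The nipple detector segments the breast (median denoise, binarize,
#' morphological cleaning, border masking, largest 8-connected component)
#' and places the ROI on the component's left-bottom extremum, which under
#' the canonical orientation (chest wall right, nipple pointing left-down)
#' indexes the nipple when it is imaged in profile.
#'
#' @param median_size Odd median-filter window side (pixels).
#' @param binarize_method `"otsu"` (data-driven threshold, default) or
#'   `"fixed"` (use `fixed_threshold`).
#' @param fixed_threshold Normalized threshold used when `binarize_method`
#'   is `"fixed"`.
#' @param border_margin_frac Fraction of each dimension zeroed at every
#'   border to suppress scanner shading bands.
#' @param struct_radius Disk radius (pixels) of the structuring element used
#'   for opening-then-closing.
#' @param roi_size ROI side in pixels (256 full scale, 64 quarter scale).
#' @return A list of class `nipple_config`.
#' @export
nipple_config <- function(median_size = 3L, binarize_method = c("otsu", "fixed"),
                          fixed_threshold = 0.8, border_margin_frac = 0.02,
                          struct_radius = 5L, roi_size = 256L) {
  binarize_method <- match.arg(binarize_method)
  if (!is_count(median_size, min = 3L) || median_size %% 2L == 0L) {
    abort("median_size must be an odd integer >= 3", class = "mammoqc_config_error")
  }
  if (!is.numeric(border_margin_frac) || border_margin_frac < 0 || border_margin_frac >= 0.5) {
    abort("border_margin_frac must lie in [0, 0.5)", class = "mammoqc_config_error")
  }
  if (!is_count(struct_radius, min = 0L)) {
    abort("struct_radius must be a non-negative integer", class = "mammoqc_config_error")
  }
  if (!is_count(roi_size)) abort("roi_size must be a positive integer", class = "mammoqc_config_error")
  structure(
    list(median_size = as.integer(median_size), binarize_method = binarize_method,
         fixed_threshold = fixed_threshold, border_margin_frac = border_margin_frac,
         struct_radius = as.integer(struct_radius), roi_size = as.integer(roi_size)),
    class = "nipple_config"
  )
}

# pairwise sort step of the median-of-9 selection network: min into a, max
# into b. Arithmetic form (finite inputs only) — markedly faster than
# pmin/pmax on large vectors.
sort2 <- function(v, a, b) {
  s <- v[[a]] + v[[b]]
  d <- abs(v[[a]] - v[[b]])
  v[[a]] <- (s - d) / 2
  v[[b]] <- (s + d) / 2
  v
}

median9 <- function(v) {
  # Paeth's 19-exchange median-of-9 network; indices 1..9
  steps <- list(c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
                c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
                c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5), c(5, 3))
  for (s in steps) v <- sort2(v, s[1], s[2])
  v[[5]]
}

#' Median filter with reflect padding
#'
#' Each output pixel is the exact median of its `size x size` neighbourhood;
#' image borders are handled by reflect padding. The default 3 x 3 window
#' uses a vectorized selection network; larger windows fall back to a direct
#' per-pixel median.
#'
#' @param img Numeric matrix.
#' @param size Odd window side in pixels.
#' @return Matrix of the same shape.
#' @export
median_denoise <- function(img, size = 3L) {
  assert_image_matrix(img)
  if (!is_count(size, min = 1L) || size %% 2L == 0L) {
    abort("median window size must be odd", class = "mammoqc_config_error")
  }
  if (size == 1L) return(img)
  p <- (size - 1L) %/% 2L
  padded <- reflect_pad(img, p, p)
  nr <- nrow(img); nc <- ncol(img)
  if (size == 3L) {
    shifts <- vector("list", 9L)
    k <- 0L
    for (dc in 0:2) for (dr in 0:2) {
      k <- k + 1L
      # bare vectors: pmin/pmax skip attribute bookkeeping
      shifts[[k]] <- as.numeric(padded[dr + seq_len(nr), dc + seq_len(nc)])
    }
    out <- median9(shifts)
    dim(out) <- c(nr, nc)
    return(out)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- median(padded[i:(i + size - 1L), j:(j + size - 1L)])
    }
  }
  out
}

#' Zero out a margin along every image border
#'
#' Suppresses the bright shading bands that scanned mammograms often carry
#' on their edges before component labeling.
#'
#' @param mask Logical matrix.
#' @param margin_frac Fraction of each dimension zeroed at each border;
#'   `floor(margin_frac * n)` rows/columns are cleared per side.
#' @return Logical matrix of the same shape.
#' @export
apply_border_mask <- function(mask, margin_frac) {
  if (length(mask) == 0L) abort("empty mask", class = "mammoqc_input_error")
  if (!is.numeric(margin_frac) || margin_frac < 0 || margin_frac >= 0.5) {
    abort("margin_frac must lie in [0, 0.5)", class = "mammoqc_config_error")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  mr <- floor(margin_frac * nr); mc <- floor(margin_frac * nc)
  if (mr > 0) {
    mask[seq_len(mr), ] <- FALSE
    mask[(nr - mr + 1L):nr, ] <- FALSE
  }
  if (mc > 0) {
    mask[, seq_len(mc)] <- FALSE
    mask[, (nc - mc + 1L):nc] <- FALSE
  }
  mask
}

#' Morphological cleaning: opening then closing with a disk
#'
#' Opening removes structures thinner than the disk (radiopaque labels,
#' noise specks); the subsequent closing fills holes smaller than the disk.
#'
#' @param mask Logical matrix.
#' @param struct_radius Disk radius in pixels; `0` is the identity.
#' @return Logical matrix of the same shape.
#' @export
morph_clean <- function(mask, struct_radius = 5L) {
  if (length(mask) == 0L) abort("empty mask", class = "mammoqc_input_error")
  if (struct_radius == 0L) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(struct_radius) + 1L, shape = "disc")
  m <- EBImage::closing(EBImage::opening(mask * 1, brush), brush)
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

# 8-connected labeling: 4-connected pass (EBImage::bwlabel, compiled), then a
# union-find over the label ids merging pairs that touch diagonally. Returns
# an integer matrix (0 = background) with components numbered by first
# appearance in row-major scan order.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) {
    abort("mask has no foreground pixels", class = "mammoqc_detection_error")
  }
  lab4 <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nr, nc)
  k <- max(lab4)
  parent <- seq_len(k)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  pairs <- rbind(
    cbind(as.vector(lab4[-nr, -nc]), as.vector(lab4[-1L, -1L])),  # down-right
    cbind(as.vector(lab4[-1L, -nc]), as.vector(lab4[-nr, -1L]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      a <- find_root(pairs[i, 1]); b <- find_root(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(k), find_root, integer(1))
  comp_px <- root[lab4[idx]]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  rm_rank <- (rows - 1L) * nc + cols               # row-major scan order
  first_rm <- tapply(rm_rank, comp_px, min)
  ord <- as.integer(names(first_rm))[order(first_rm)]
  relabel_map <- integer(k)
  relabel_map[ord] <- seq_along(ord)
  labels <- matrix(0L, nr, nc)
  labels[idx] <- relabel_map[comp_px]
  list(labels = labels, n_components = length(ord))
}

#' Select the largest connected component of a mask
#'
#' Labels the mask under 8-connectivity and keeps only the component with
#' the most pixels (the breast); ties are broken toward the component first
#' encountered in row-major scan order.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return A list with `labels` (integer matrix, 0 = background),
#'   `n_components`, `largest` (logical mask of the winning component),
#'   `label` (its id) and `size` (its pixel count).
#' @export
largest_component <- function(mask) {
  lab <- label_components8(mask)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n_components)
  win <- which.max(sizes)
  list(labels = lab$labels, n_components = lab$n_components,
       largest = lab$labels == win, label = win, size = sizes[win])
}

#' Left-bottom extremum of a connected region
#'
#' Among the pixels attaining the region's minimal column index, returns the
#' one with the maximal row index: the lower of the two leftmost boundary
#' points in the 8-point compass-extrema convention.
#'
#' @param component Logical matrix with at least one `TRUE` pixel.
#' @return A list of class `extrema_point` with `row`, `col`, `kind`.
#' @export
left_bottom_extremum <- function(component) {
  idx <- which(component)
  if (length(idx) == 0L) {
    abort("empty component", class = "mammoqc_detection_error")
  }
  nr <- nrow(component)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  cmin <- min(cols)
  r <- max(rows[cols == cmin])
  structure(list(row = r, col = cmin, kind = "left-bottom"), class = "extrema_point")
}

nipple_threshold <- function(img, cfg) {
  if (cfg$binarize_method == "fixed") return(cfg$fixed_threshold)
  EBImage::otsu(img / 255, range = c(0, 1))
}

#' Detect the nipple-in-profile region
#'
#' Runs the full segmentation chain — median denoise, binarize (Otsu by
#' default), morphological opening/closing, border masking, largest
#' 8-connected component — then centres a `roi_size` square on the breast
#' component's left-bottom extremum, clamped to the image bounds.
#'
#' @param img Standardized image matrix (values in `[0, 255]`).
#' @param cfg A [nipple_config()].
#' @return A `roi_detection` object; `extremum` holds the located point and
#'   `foreground_fraction` the breast-component area fraction of the image.
#' @export
detect_nipple <- function(img, cfg = nipple_config()) {
  assert_image_matrix(img)
  k <- cfg$roi_size
  if (nrow(img) < k || ncol(img) < k) {
    abort(sprintf("image (%d x %d) smaller than roi_size %d", nrow(img), ncol(img), k),
          class = "mammoqc_size_error")
  }
  den <- median_denoise(img, cfg$median_size)
  mask <- binarize_global(den, nipple_threshold(den, cfg))
  mask <- morph_clean(mask, cfg$struct_radius)
  mask <- apply_border_mask(mask, cfg$border_margin_frac)
  if (!any(mask)) {
    abort("no foreground left after cleaning; cannot locate the breast",
          class = "mammoqc_detection_error")
  }
  comp <- largest_component(mask)
  ext <- left_bottom_extremum(comp$largest)
  half <- k %/% 2L
  row0 <- clamp(ext$row - half, 1L, nrow(img) - k + 1L)
  col0 <- clamp(ext$col - half, 1L, ncol(img) - k + 1L)
  box <- roi_box(row0, col0, k)
  new_roi_detection("nipple", box, crop_box(img, box),
                    foreground_fraction = comp$size / length(img),
                    converged = TRUE, extremum = ext)
}
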