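#' CLAHE configuration
#'
#' @param clip_limit Normalized histogram clip limit (fraction of a tile's
#'   pixel count at which each histogram bin is clipped before
#'   equalization). 0.01 is common practice for radiographs.
#' @param tile_grid Number of tiles per axis (the image is divided into
#'   `tile_grid x tile_grid` contextual regions).
#' @return A list of class `clahe_config`.
#' @export
clahe_config <- function(clip_limit = 0.01, tile_grid = 8L) {
  if (!is.numeric(clip_limit) || clip_limit <= 0) {
    abort("clip_limit must be > 0", class = "mammoqc_config_error")
  }
  if (!is_count(tile_grid)) {
    abort("tile_grid must be a positive integer", class = "mammoqc_config_error")
  }
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 bins = 256L),
            class = "clahe_config")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit and bilinear blending
#' between neighbouring tile mappings, applied to a detected patch before
#' classification. Input and output are on the 0..255 scale. Constant
#' patches are returned unchanged (there is no contrast to redistribute).
#'
#' @param patch Numeric matrix with values in `[0, 255]`.
#' @param cfg A [clahe_config()].
#' @return Matrix of the same shape with values in `[0, 255]`.
#' @export
enhance_clahe <- function(patch, cfg = clahe_config()) {
  assert_image_matrix(patch, "patch")
  rng <- range(patch)
  if (rng[1] == rng[2]) return(patch)
  nt <- cfg$tile_grid
  # EBImage requires dimensions divisible by the tile grid; reflect-pad up
  pr <- (nt - nrow(patch) %% nt) %% nt
  pc <- (nt - ncol(patch) %% nt) %% nt
  x <- patch / 255
  if (pr > 0L) x <- rbind(x, x[nrow(x) - seq_len(pr) + 1L, , drop = FALSE])
  if (pc > 0L) x <- cbind(x, x[, ncol(x) - seq_len(pc) + 1L, drop = FALSE])
  # EBImage's limit is relative to (tile pixels / bins); ours to tile pixels
  out <- EBImage::clahe(x, nx = nt, ny = nt, bins = cfg$bins,
                        limit = cfg$clip_limit * cfg$bins)
  out <- matrix(as.numeric(out), nrow(x), ncol(x))
  out <- out[seq_len(nrow(patch)), seq_len(ncol(patch)), drop = FALSE]
  clamp(out * 255, 0, 255)
}
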