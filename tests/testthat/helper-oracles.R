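# quarter-scale configs matching the default phantom geometry
quarter_pre <- function(...) preprocess_config(resize_cols = 682L, resize_rows = 1024L, ...)
quarter_imf <- function(...) imf_config(roi_size = 64L, ...)
quarter_nipple <- function(...) nipple_config(roi_size = 64L, ...)

std_phantom <- function(seed, ...) {
  ph <- generate_phantom(phantom_spec(seed = seed, ...))
  list(img = standardize(ph$image, quarter_pre()), truth = ph$truth)
}

# ---- independent brute-force oracles -------------------------------------

oracle_median <- function(img, size) {
  p <- (size - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rev(seq_len(p) + 1L), seq_len(nr), nr - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(nc), nc - seq_len(p))
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- median(pad[i:(i + size - 1L), j:(j + size - 1L)])
    }
  }
  out
}

# flood-fill 8-connected labeling, components numbered in row-major
# first-encounter order
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  comp <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] && labels[i, j] == 0L) {
        comp <- comp + 1L
        stack <- list(c(i, j))
        labels[i, j] <- comp
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (dr in -1:1) for (dc in -1:1) {
            r <- p[1] + dr; cl <- p[2] + dc
            if (r >= 1 && r <= nr && cl >= 1 && cl <= nc &&
                mask[r, cl] && labels[r, cl] == 0L) {
              labels[r, cl] <- comp
              stack[[length(stack) + 1L]] <- c(r, cl)
            }
          }
        }
      }
    }
  }
  labels
}

oracle_extremum <- function(mask) {
  best <- NULL
  for (j in seq_len(ncol(mask))) {
    rows <- which(mask[, j])
    if (length(rows)) { best <- c(max(rows), j); break }
  }
  best
}

oracle_metrics <- function(cm) {
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  rec <- pre <- f1 <- numeric(3)
  for (k in 1:3) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp; fp <- sum(cm[, k]) - tp
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[k] <- if (pre[k] + rec[k] > 0) 2 * pre[k] * rec[k] / (pre[k] + rec[k]) else 0
  }
  c(accuracy = acc, recall = mean(rec), precision = mean(pre), f1 = mean(f1))
}

# exhaustive bottom-up window scan, any stride
oracle_imf_scan <- function(img, roi = 64L, threshold = 0.8, stop_frac = 0.25,
                            stride = 1L, col_anchor = "chest_wall") {
  col0 <- if (col_anchor == "chest_wall") ncol(img) - roi + 1L else
    (ncol(img) - roi) %/% 2L + 1L
  start <- nrow(img) - roi + 1L
  positions <- unique(c(seq.int(start, 1L, by = -stride), 1L))
  for (r0 in positions) {
    win <- img[r0:(r0 + roi - 1L), col0:(col0 + roi - 1L)]
    if (sum(win / 255 > threshold) / (roi * roi) > stop_frac) {
      return(list(row0 = r0, converged = TRUE))
    }
  }
  list(row0 = 1L, converged = FALSE)
}

hist_entropy <- function(img) {
  p <- tabulate(floor(img) + 1L, nbins = 256L)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# ---- minimal 16-bit grayscale PNG writer (for the read path) -------------
# zlib stream with stored (uncompressed) deflate blocks; CRC32 and Adler32
# computed in R. Only used to build tiny fixtures at test time.

.crc_table <- local({
  tab <- integer(256)
  poly <- -306674912L # 0xEDB88320
  for (n in 0:255) {
    cr <- n
    for (k in 1:8) {
      cr <- if (bitwAnd(cr, 1L)) bitwXor(poly, bitwShiftR(cr, 1L)) else bitwShiftR(cr, 1L)
    }
    tab[n + 1L] <- cr
  }
  tab
})

crc32_raw <- function(bytes) {
  cr <- -1L
  for (b in as.integer(bytes)) {
    cr <- bitwXor(.crc_table[bitwAnd(bitwXor(cr, b), 255L) + 1L], bitwShiftR(cr, 8L))
  }
  bitwXor(cr, -1L)
}

u32_be <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(u32_be(length(data)), td, u32_be(crc32_raw(td)))
}

zlib_stored <- function(data) {
  n <- length(data)
  out <- as.raw(c(0x78, 0x01))
  pos <- 1L
  repeat {
    len <- min(65535L, n - pos + 1L)
    final <- if (pos + len - 1L >= n) 0x01 else 0x00
    out <- c(out, as.raw(final),
             writeBin(len, raw(), size = 2L, endian = "little"),
             writeBin(bitwAnd(bitwXor(len, -1L), 65535L), raw(), size = 2L, endian = "little"),
             data[pos:(pos + len - 1L)])
    pos <- pos + len
    if (pos > n) break
  }
  s1 <- 1L; s2 <- 0L
  for (b in as.integer(data)) {
    s1 <- (s1 + b) %% 65521L
    s2 <- (s2 + s1) %% 65521L
  }
  c(out, u32_be(s2 * 65536 + s1))
}

write_png16 <- function(img, path) {
  w <- ncol(img); h <- nrow(img)
  ihdr <- c(u32_be(w), u32_be(h), as.raw(c(16, 0, 0, 0, 0)))
  scan <- do.call(c, lapply(seq_len(h), function(i) {
    v <- as.integer(img[i, ])
    c(as.raw(0), as.raw(as.vector(rbind(v %/% 256L, v %% 256L))))
  }))
  bytes <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
             png_chunk("IHDR", ihdr),
             png_chunk("IDAT", zlib_stored(scan)),
             png_chunk("IEND", raw(0)))
  writeBin(bytes, path)
  invisible(path)
}

# ---- reference classifiers injectable into cross_validate ----------------
# registered with .S3method so dispatch works from inside the package

.S3method("predict", "mean_rule_clf", function(object, newdata, ...) {
  tibble::tibble(label = vapply(newdata, function(p) as.integer(round(mean(p) / 10)), 1L))
})

.S3method("predict", "always_average_clf", function(object, newdata, ...) {
  tibble::tibble(label = rep(2L, length(newdata)))
})

# write n phantoms as PNGs plus a labels CSV; returns the directory
write_phantom_corpus <- function(dir, labels_imf, labels_nipple, seeds) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("ph%03d", seq_along(seeds))
  for (i in seq_along(seeds)) {
    ph <- generate_phantom(phantom_spec(seed = seeds[i],
                                        label_imf = labels_imf[i],
                                        label_nipple = labels_nipple[i]))
    write_image_png(ph$image$pixels, file.path(dir, paste0(ids[i], ".png")))
  }
  labfile <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(image_id = ids, imf_label = labels_imf,
                              nipple_label = labels_nipple),
                   labfile, row.names = FALSE)
  list(dir = dir, labels = labfile, ids = ids)
}

# truth-located fold patches for classifier experiments
phantom_patch_set <- function(labels, seed_base) {
  patches <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- std_phantom(seed_base + i, label_imf = labels[i], label_nipple = labels[i])
    patches[[i]] <- extract_truth_patch(sp$img, sp$truth, "imf", 64)
  }
  tibble::tibble(patch = patches, label = labels)
}
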