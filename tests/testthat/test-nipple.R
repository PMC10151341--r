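test_that("median filtering removes speckle and leaves constants alone", {
  expect_equal(median_denoise(matrix(42, 10, 10), 3), matrix(42, 10, 10))
  m <- matrix(0, 9, 9); m[5, 5] <- 255
  expect_true(all(median_denoise(m, 3) == 0))
  expect_error(median_denoise(m, 4), class = "mammoqc_config_error")
})

test_that("median filter equals the brute-force neighbourhood median", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
    expect_equal(median_denoise(x, 3), oracle_median(x, 3))
  }
  set.seed(99)
  x <- matrix(sample(0:255, 15 * 15, TRUE), 15, 15)
  expect_equal(median_denoise(x, 5), oracle_median(x, 5))
})

test_that("border masking clears exactly the configured margin", {
  m <- matrix(TRUE, 100, 100)
  out <- apply_border_mask(m, 0.02)
  expect_true(all(out[3:98, 3:98]))
  expect_false(any(out[1:2, ])); expect_false(any(out[99:100, ]))
  expect_false(any(out[, 1:2])); expect_false(any(out[, 99:100]))
  expect_identical(apply_border_mask(m, 0), m)
  expect_error(apply_border_mask(m, 0.5), class = "mammoqc_config_error")
})

test_that("opening removes sub-disk specks and closing fills small holes", {
  m <- matrix(FALSE, 60, 60)
  m[20:50, 20:50] <- TRUE  # large block
  m[5, 5] <- TRUE          # isolated speck
  m[35, 35] <- FALSE       # pinhole
  out <- morph_clean(m, 5L)
  expect_false(out[5, 5])
  expect_true(out[35, 35])
  expect_true(out[30, 30])
})

test_that("largest-component selection matches flood-fill labeling", {
  m <- matrix(FALSE, 30, 30)
  m[2:11, 2:11] <- TRUE    # 100 px
  m[20:22, 20:22] <- TRUE  # 9 px
  sel <- largest_component(m)
  expect_identical(sel$size, 100L)
  expect_true(all(sel$largest == (row(m) %in% 2:11 & col(m) %in% 2:11)))

  single <- matrix(FALSE, 10, 10); single[3:6, 3:6] <- TRUE
  expect_identical(largest_component(single)$largest, single)

  for (seed in 1:8) {
    set.seed(seed)
    msk <- matrix(runif(32 * 32) > 0.55, 32, 32)
    if (!any(msk)) next
    got <- largest_component(msk)
    want <- oracle_components(msk)
    expect_identical(max(want), got$n_components)
    expect_identical(tabulate(got$labels[got$labels > 0]),
                     tabulate(want[want > 0]))
    # identical partition, not just identical size distribution
    expect_true(all(got$labels == want))
  }
  expect_error(largest_component(matrix(FALSE, 4, 4)),
               class = "mammoqc_detection_error")
})

test_that("equal-size components tie toward the first in row-major scan order", {
  m <- matrix(FALSE, 10, 10)
  m[1:2, 5:6] <- TRUE  # first reached scanning row 1
  m[4:5, 1:2] <- TRUE
  sel <- largest_component(m)
  expect_true(sel$largest[1, 5])
  expect_false(sel$largest[4, 1])
})

test_that("left-bottom extremum is the lowest of the leftmost pixels", {
  rect <- matrix(FALSE, 20, 20); rect[5:12, 6:15] <- TRUE
  e <- left_bottom_extremum(rect)
  expect_identical(c(e$row, e$col), c(12L, 6L))

  tri <- matrix(FALSE, 20, 20)
  for (i in 1:10) tri[i + 4, 5:(4 + i)] <- TRUE  # vertical left edge at col 5
  e2 <- left_bottom_extremum(tri)
  expect_identical(c(e2$row, e2$col), c(14L, 5L))

  for (seed in 1:10) {
    set.seed(seed)
    blob <- matrix(runif(40 * 40) > 0.7, 40, 40)
    if (!any(blob)) next
    e3 <- left_bottom_extremum(blob)
    expect_identical(c(e3$row, e3$col), oracle_extremum(blob))
  }
  expect_error(left_bottom_extremum(matrix(FALSE, 3, 3)),
               class = "mammoqc_detection_error")
})

test_that("a quarter-disk against the chest wall yields its leftmost-lowest contour point", {
  n <- 300L
  rr <- matrix(seq_len(n), n, n); cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- ifelse((rr - 150)^2 + (cc - n)^2 <= 100^2, 200, 0)
  d <- detect_nipple(img, quarter_nipple())
  # the leftmost surviving column of the disk is a short vertical chord; the
  # left-bottom rule picks its lowest pixel, a few rows below the apex
  expect_true(d$extremum$col >= 200 && d$extremum$col <= 205)
  expect_true(d$extremum$row >= 150 && d$extremum$row <= 170)
  b <- d$box
  expect_true(b$row0 <= 150 && 150 <= b$row0 + b$height - 1)
  expect_true(b$col0 <= 200 && 200 <= b$col0 + b$width - 1)
})

test_that("the detected box contains the true phantom nipple", {
  for (seed in 81:86) {
    sp <- std_phantom(seed, label_nipple = "excellent")
    d <- detect_nipple(sp$img, quarter_nipple())
    tr <- sp$truth$nipple_rc
    b <- d$box
    expect_true(b$row0 <= tr[1] && tr[1] <= b$row0 + b$height - 1)
    expect_true(b$col0 <= tr[2] && tr[2] <= b$col0 + b$width - 1)
  }
})

test_that("a radiopaque label away from the breast does not move the box", {
  with_art <- std_phantom(91, add_artifacts = TRUE)
  without <- std_phantom(91, add_artifacts = FALSE)
  d1 <- detect_nipple(with_art$img, quarter_nipple())
  d2 <- detect_nipple(without$img, quarter_nipple())
  expect_identical(d1$box, d2$box)
})

test_that("boxes near the image edge are clamped fully inside", {
  img <- matrix(0, 200, 200)
  rr <- matrix(seq_len(200), 200, 200); cc <- matrix(seq_len(200), 200, 200, byrow = TRUE)
  img[(rr - 190)^2 + (cc - 10)^2 <= 15^2] <- 220
  d <- detect_nipple(img, quarter_nipple(struct_radius = 2L, border_margin_frac = 0))
  b <- d$box
  expect_gte(b$row0, 1L); expect_gte(b$col0, 1L)
  expect_lte(b$row0 + b$height - 1L, 200L)
  expect_lte(b$col0 + b$width - 1L, 200L)
})

test_that("an image with no usable foreground raises a detection error", {
  expect_error(detect_nipple(matrix(0, 100, 100), quarter_nipple(binarize_method = "fixed")),
               class = "mammoqc_detection_error")
})
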