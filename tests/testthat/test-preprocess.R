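test_that("min-max normalization maps a 2x2 grid onto the full 0..255 range", {
  cfg <- preprocess_config(resize_cols = 2L, resize_rows = 2L)
  m <- matrix(c(0, 10, 5, 15), 2, 2) # [[0,5],[10,15]]
  out <- standardize(mammogram(m, laterality = "right"), cfg)
  expect_equal(out, matrix(c(0, 170, 85, 255), 2, 2))
})

test_that("standardized images span exactly 0..255 for non-constant input", {
  for (seed in c(3, 11)) {
    sp <- std_phantom(seed)
    expect_equal(min(sp$img), 0)
    expect_equal(max(sp$img), 255)
    expect_true(all(sp$img == round(sp$img)))
  }
})

test_that("a left-labeled mirror image standardizes identically to its right twin", {
  set.seed(5)
  base <- matrix(sample(0:255, 80 * 60, TRUE), 80, 60)
  cfg <- preprocess_config(resize_cols = 60L, resize_rows = 80L)
  right <- standardize(mammogram(base, laterality = "right"), cfg)
  mirrored <- base[, rev(seq_len(ncol(base)))]
  left <- standardize(mammogram(mirrored, laterality = "left"), cfg)
  expect_identical(left, right)
})

test_that("standardize is idempotent under nearest-neighbour interpolation", {
  cfg <- quarter_pre(interpolation = "nearest")
  once <- standardize(generate_phantom(phantom_spec(seed = 8))$image, cfg)
  twice <- standardize(mammogram(once, laterality = "right"), cfg)
  expect_identical(dim(twice), dim(once))
  expect_identical(twice, once)
})

test_that("constant images are rejected as degenerate", {
  cfg <- preprocess_config(resize_cols = 10L, resize_rows = 10L)
  expect_error(standardize(mammogram(matrix(7, 10, 10), laterality = "right"), cfg),
               class = "mammoqc_normalization_error")
})

test_that("laterality inference finds the heavier half and errors on ties", {
  m <- matrix(0, 40, 40); m[, 1:12] <- 200
  expect_identical(infer_laterality(m), "left")
  expect_identical(infer_laterality(m[, rev(1:40)]), "right")
  expect_error(infer_laterality(matrix(1, 10, 10)), class = "mammoqc_detection_error")
})

test_that("laterality inference agrees with the generated phantom side", {
  for (seed in 1:25) {
    side <- if (seed %% 2 == 0) "left" else "right"
    ph <- generate_phantom(phantom_spec(seed = 300 + seed, laterality = side))
    expect_identical(infer_laterality(ph$image), side)
  }
})

test_that("8-bit PNG round trip preserves pixels and parses filename laterality", {
  dir <- withr::local_tempdir()
  set.seed(2)
  px <- matrix(sample(0:255, 50 * 40, TRUE), 50, 40)
  path <- file.path(dir, "case7_LEFT_MLO.png")
  write_image_png(px, path)
  img <- read_mammogram(path)
  expect_equal(img$pixels, px)
  expect_identical(img$laterality, "left")
  expect_identical(img$bit_depth, 8L)
})

test_that("16-bit PNG reads losslessly with the correct bit depth", {
  dir <- withr::local_tempdir()
  set.seed(4)
  px <- matrix(sample(0:65535, 8 * 6, TRUE), 8, 6)
  px[1, 1] <- 65535L
  path <- file.path(dir, "deep16_R_CC.png")
  write_png16(px, path)
  img <- read_mammogram(path)
  expect_identical(img$bit_depth, 16L)
  expect_equal(img$pixels, px)
  expect_identical(img$laterality, "right")
})

test_that("all-zero PNG decodes to an all-zero mammogram of the right shape", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "blank.png")
  write_image_png(matrix(0, 100, 80), path)
  img <- read_mammogram(path)
  expect_identical(dim(img$pixels), c(100L, 80L))
  expect_true(all(img$pixels == 0))
  expect_identical(img$laterality, "unknown")
})

test_that("colour PNGs are rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rgb.png")
  png::writePNG(array(runif(20 * 20 * 3), c(20, 20, 3)), path)
  expect_error(read_mammogram(path), class = "mammoqc_format_error")
})

test_that("DICOM input is refused with a clear message", {
  expect_error(read_mammogram("x.dcm", format = "dicom"), class = "mammoqc_io_error")
})
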