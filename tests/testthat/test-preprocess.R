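test_that("greyscale conversion applies luminance weights and rescale", {
  white <- array(1, c(4, 5, 3))
  # the standard luminance weights sum to 0.9999
  expect_equal(to_greyscale(white), matrix(1, 4, 5), tolerance = 1e-3)
  red <- array(0, c(4, 5, 3)); red[, , 1] <- 1
  expect_equal(to_greyscale(red), matrix(0.2989, 4, 5))
  expect_error(to_greyscale(array(1, c(4, 5, 2))), "channels")

  # greyscale input: min-max rescale (constant-plus-one-pixel oracle)
  g <- matrix(5, 3, 3); g[2, 2] <- 6
  expected <- matrix(0, 3, 3); expected[2, 2] <- 1
  expect_equal(to_greyscale(g), expected)
  # a constant image cannot be rescaled and passes through
  expect_equal(to_greyscale(matrix(0.5, 3, 3)), matrix(0.5, 3, 3))
})

test_that("CLAHE keeps range, spreads levels, and degrades gracefully", {
  # constant image stays constant
  out <- enhance_contrast(matrix(0.5, 64, 64))
  expect_equal(max(out) - min(out), 0)
  # two-level image: output levels at least as separated as input levels
  set.seed(42)
  img <- matrix(sample(c(0.4, 0.6), 64 * 64, replace = TRUE), 64, 64)
  out2 <- enhance_contrast(img, clip_limit = 4, tile_grid = c(2, 2))
  expect_gt(max(out2) - min(out2), 0.2)
  # range contract on arbitrary input, non-divisible dimensions
  img3 <- matrix(runif(97 * 61), 97, 61)
  out3 <- enhance_contrast(img3)
  expect_true(all(out3 >= 0 & out3 <= 1))
  expect_identical(dim(out3), dim(img3))
  # image smaller than one tile: global equalization fallback, with warning
  expect_warning(small <- enhance_contrast(matrix(runif(36), 6, 6)),
                 "falling back")
  expect_identical(dim(small), c(6L, 6L))
})

test_that("mean blur equals the direct windowed mean, borders included", {
  set.seed(7)
  img <- matrix(runif(32 * 32), 32, 32)
  for (w in c(1L, 3L, 7L)) {
    expect_equal(mean_blur(img, w), oracle_mean_blur(img, w),
                 tolerance = 1e-12)
  }
  # constant image is a fixed point
  expect_equal(mean_blur(matrix(0.3, 10, 12), 2), matrix(0.3, 10, 12))
  # single bright pixel spreads to 1/9 over its 3x3 neighbourhood
  img1 <- matrix(0, 9, 9); img1[5, 5] <- 1
  bl <- mean_blur(img1, 1)
  expect_equal(bl[4:6, 4:6], matrix(1 / 9, 3, 3))
  expect_equal(sum(bl), 1)
  expect_error(mean_blur(matrix(0, 5, 8), 5), "smaller")
})

test_that("mean blur is shift-equivariant away from borders", {
  set.seed(8)
  img <- matrix(runif(24 * 24), 24, 24)
  w <- 2L
  shifted <- img[c(2:24, 24), ]              # shift up one row
  b1 <- mean_blur(img, w)
  b2 <- mean_blur(shifted, w)
  interior_rows <- (w + 2):(24 - w - 1)
  interior_cols <- (w + 1):(24 - w)
  expect_equal(b2[interior_rows - 1, interior_cols],
               b1[interior_rows, interior_cols], tolerance = 1e-12)
})

test_that("Otsu threshold matches the exhaustive-search oracle exactly", {
  set.seed(11)
  for (i in 1:25) {
    img <- matrix(runif(16 * 16), 16, 16)
    t <- otsu_threshold(img)
    expect_identical(attr(t, "bin"), oracle_otsu_bin(img))
  }
  # bimodal 0/1 image: the threshold separates the classes exactly
  img <- matrix(rep(c(0, 1), each = 32), 8, 8)
  mask <- binarize(img)
  expect_identical(mask != 0, img == 1)
})

test_that("binarization honours overrides and flags degenerate input", {
  img <- matrix(rep(c(0.4, 0.6), 18), 6, 6)
  mask <- binarize(img, threshold_override = 0.5)
  expect_identical(unname(which(mask)), which(img == 0.6))
  expect_equal(attr(mask, "threshold"), 0.5)

  flat <- binarize(matrix(0.7, 8, 8))
  expect_true(attr(flat, "flagged"))
  expect_false(any(flat))
})

test_that("foreground orientation is an involution", {
  set.seed(3)
  mask <- matrix(runif(64) > 0.5, 8, 8)
  expect_identical(
    unclass(orient_foreground(orient_foreground(mask, TRUE), TRUE))[, ],
    mask)
  empty <- matrix(FALSE, 4, 4)
  expect_true(all(orient_foreground(empty, TRUE)))
  expect_identical(orient_foreground(mask, FALSE)[, ], mask)
})

test_that("preprocessing preserves dimensions at every stage", {
  set.seed(5)
  img <- array(runif(40 * 56 * 3), c(40, 56, 3))
  g <- to_greyscale(img)
  e <- enhance_contrast(g, tile_grid = c(4, 4))
  b <- mean_blur(e, 3)
  m <- orient_foreground(binarize(b))
  for (x in list(g, e, b, m)) expect_identical(dim(x), c(40L, 56L))
  expect_true(all(m %in% c(TRUE, FALSE)))
})
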