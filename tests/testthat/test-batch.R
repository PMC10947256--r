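# batch fixtures are built once per file; images are small to keep the
# suite fast
make_batch_dir <- function(n = 4L, seed0 = 1L) {
  dir <- file.path(tempfile("batch"))
  # vary the geometry so ground-truth densities differ across the batch
  specs <- lapply(seq_len(n), function(s) {
    small_spec(seed = seed0 + s,
               n_primaries = 2L + (s %% 3L),
               rail_spacing_px = 60 + 8 * s,
               commissural_spacing_px = 80 + 10 * s)
  })
  write_synthetic_set(specs, dir)
  list(dir = dir, specs = specs)
}

batch_config <- function(input, output, ...) {
  test_config(input_path = input, output_dir = output,
              pixel_length_um = 0.65, x_pixels = 256, y_pixels = 256,
              trim_factor = 8, blur_w = 8, ...)
}

test_that("a batch processes every image and writes results + overlays", {
  fx <- make_batch_dir(4L)
  out <- tempfile("out")
  report <- run_batch(batch_config(fx$dir, out), verbose = FALSE)
  expect_identical(report$n_images, 4L)
  expect_identical(report$n_processed, 4L)
  expect_identical(nrow(report$results), 4L)
  expect_length(list.files(report$overlay_dir, pattern = "\\.png$"), 4L)
  expect_true(file.exists(report$results_path))
  expect_true(file.exists(file.path(out, "run_metadata.json")))
  # estimates agree with the generator's ground truth
  gt <- read.csv(file.path(fx$dir, "ground_truth.csv"))
  agg <- compare_estimates(gt, report$results,
                           value_col_a = "density_um_per_mm2")
  expect_gt(agg$pearson_r, 0.95)
  expect_lt(agg$mean_abs_rel_diff, 0.12)
})

test_that("reruns with identical inputs give bit-identical CSVs", {
  fx <- make_batch_dir(3L, seed0 = 20L)
  out1 <- tempfile("out"); out2 <- tempfile("out")
  r1 <- run_batch(batch_config(fx$dir, out1), verbose = FALSE)
  r2 <- run_batch(batch_config(fx$dir, out2), verbose = FALSE)
  expect_identical(readLines(r1$results_path), readLines(r2$results_path))
  expect_identical(unname(tools::md5sum(r1$results_path)),
                   unname(tools::md5sum(r2$results_path)))
})

test_that("corrupt, constant, blank and inverted images never abort a batch", {
  fx <- make_batch_dir(2L, seed0 = 40L)
  # corrupt file
  writeLines("not an image", file.path(fx$dir, "corrupt.png"))
  # constant (unstained) frame
  EBImage::writeImage(EBImage::Image(matrix(0.5, 256, 256)),
                      file.path(fx$dir, "constant.png"))
  # blank noise-only frame
  set.seed(1)
  EBImage::writeImage(
    EBImage::Image(matrix(pmin(pmax(rnorm(256^2, 0.85, 0.03), 0), 1),
                          256, 256)),
    file.path(fx$dir, "blank.png"))
  # inverted-polarity frame
  inv <- generate_veins(small_spec(seed = 43L), invert_polarity = TRUE)
  EBImage::writeImage(EBImage::Image(t(inv$image)),
                      file.path(fx$dir, "inverted.png"))
  out <- tempfile("out")
  report <- run_batch(batch_config(fx$dir, out), verbose = FALSE)
  expect_identical(report$n_images, 6L)
  expect_identical(report$n_processed, 5L)
  expect_identical(report$read_failures, "corrupt.png")
  res <- report$results
  expect_true(res$flagged[res$image_id == "constant.png"])
  # the batch report balances: processed + failures = inputs
  expect_identical(report$n_processed + length(report$read_failures),
                   report$n_images)
})

test_that("an empty directory or unwritable output fails fast", {
  empty <- tempfile("empty"); dir.create(empty)
  expect_error(run_batch(batch_config(empty, tempfile())), "no readable")
  expect_error(run_batch(batch_config(tempfile("absent"), tempfile())),
               "does not exist")
})

test_that("deferred review marks rejections without dropping rows", {
  fx <- make_batch_dir(3L, seed0 = 60L)
  out <- tempfile("out")
  report <- run_batch(batch_config(fx$dir, out), verbose = FALSE)
  ids <- report$results$image_id
  reviewed <- apply_review(report, rejections = ids[1:2])
  expect_identical(nrow(reviewed$results), 3L)
  expect_identical(sum(reviewed$results$excluded), 2L)
  expect_true(file.exists(reviewed$results_path_reviewed))
  back <- read_results_table(reviewed$results_path_reviewed)
  expect_identical(back$excluded, c(TRUE, TRUE, FALSE))
  # no-op review keeps every row included
  noop <- apply_review(report, character())
  expect_false(any(noop$results$excluded))
  expect_true("review_time" %in% names(noop$results))
  # unknown ids are named; rejecting everything warns
  expect_error(apply_review(report, "nope.png"), "nope.png")
  expect_warning(apply_review(report, ids), "every image")
})

test_that("agreement summaries behave on reference cases", {
  tab <- data.frame(image_id = sprintf("i%02d", 1:6),
                    vein_density_um_per_mm2 = c(900, 1200, 1500, 800, 1100,
                                                1300))
  self <- compare_estimates(tab, tab)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$slope, 1)
  expect_equal(self$mean_abs_rel_diff, 0)
  doubled <- tab
  doubled$vein_density_um_per_mm2 <- tab$vein_density_um_per_mm2 * 2
  up <- compare_estimates(tab, doubled)
  expect_equal(up$pearson_r, 1)
  expect_equal(up$slope, 2)
  anti <- tab
  anti$vein_density_um_per_mm2 <- 3000 - tab$vein_density_um_per_mm2
  expect_equal(compare_estimates(tab, anti)$pearson_r, -1)
  expect_error(compare_estimates(tab[1:2, ], tab), "fewer than 3")
})
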