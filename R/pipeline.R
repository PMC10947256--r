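# End-to-end pipeline and batch driver: process every image in a directory
# unattended, write results + overlays, then support a deferred manual check.

#' Process a single image through the full pipeline
#'
#' Runs greyscale conversion, CLAHE, mean blur, Otsu binarization, foreground
#' orientation, skeletonization, automatic/manual spur trimming and — in
#' monocot mode with a positive `monocot_branch_length_to_keep` — commissural
#' vein removal, then measures vein density.
#'
#' @param raster Image matrix/array as returned by [read_image()].
#' @param config A `pipeline_config`.
#' @param image_id Identifier for the result row.
#' @return A list: `result` (one-row data frame, see [measure_density()]),
#'   `skeleton` (final trimmed mask) and `grey` (the greyscale input, for
#'   overlays).
#' @export
process_image <- function(raster, config, image_id = "image") {
  stopifnot(inherits(config, "pipeline_config"))
  grey <- to_greyscale(raster)
  dim_mismatch <- nrow(grey) != config$y_pixels ||
    ncol(grey) != config$x_pixels
  if (dim_mismatch) {
    warning("image '", image_id, "' is ", ncol(grey), "x", nrow(grey),
            " but the configuration expects ", config$x_pixels, "x",
            config$y_pixels, "; continuing with actual dimensions",
            call. = FALSE)
  }
  enh <- enhance_contrast(grey, config$clahe_clip_limit,
                          config$clahe_tile_grid)
  blurred <- mean_blur(enh, config$blur_w)
  bin <- binarize(blurred, config$threshold_override)
  degenerate <- isTRUE(attr(bin, "flagged"))
  mask <- if (degenerate) {
    # zero-variance image: no stain signal; complementing the empty mask
    # would declare the whole frame vein
    matrix(FALSE, nrow(grey), ncol(grey))
  } else {
    orient_foreground(bin, config$invert_foreground)
  }
  skel <- skeletonize(mask)
  g <- build_graph(skel)
  eff <- auto_trim_factor(g, config$trim_factor,
                          config$auto_trim_trigger_fraction)
  trimmed <- trim_spurs(g, eff)
  if (config$mode == "monocot" && config$monocot_branch_length_to_keep > 0) {
    trimmed <- remove_commissural(build_graph(trimmed),
                                  config$monocot_branch_length_to_keep)
  }
  res <- measure_density(
    trimmed, config, image_id = image_id,
    auto_trim_used = eff != config$trim_factor,
    effective_trim_factor = eff,
    flagged = dim_mismatch || degenerate
  )
  list(result = res, skeleton = trimmed, grey = grey)
}

.image_extensions <- "\\.(tiff?|png|jpe?g)$"

#' Run the vein-density pipeline over a directory of images
#'
#' Processes every raster image under `config$input_path` (or a single file)
#' unattended: each image runs through [process_image()], an overlay of the
#' final trace over the greyscale original is written to
#' `<output_dir>/overlays/`, and all rows are collected into
#' `<output_dir>/results.csv` together with a machine-readable
#' `run_metadata.json` (configuration echo, timestamps, failures). A
#' corrupt or unreadable image is logged and skipped; it never aborts the
#' batch. The pipeline has no random state, so identical inputs and
#' configuration yield a bit-identical results CSV.
#'
#' @param config A `pipeline_config`.
#' @param verbose Log per-image progress and stage timing via `message()`.
#' @return A `batch_report`: list with `n_images`, `n_processed`,
#'   `n_flagged`, `results` (data frame), `read_failures`, `rejected_ids`,
#'   `results_path`, `overlay_dir`.
#' @export
run_batch <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  input <- config$input_path
  files <- if (dir.exists(input)) {
    sort(list.files(input, pattern = .image_extensions, ignore.case = TRUE,
                    full.names = TRUE))
  } else if (file.exists(input)) {
    input
  } else {
    stop("input_path does not exist: ", input, call. = FALSE)
  }
  if (length(files) == 0L) {
    stop("no readable images found in ", input, call. = FALSE)
  }
  out_dir <- config$output_dir
  overlay_dir <- file.path(out_dir, "overlays")
  dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(overlay_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }

  started <- Sys.time()
  rows <- list()
  failures <- character()
  for (f in files) {
    id <- basename(f)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      raster <- read_image(f)
      pr <- suppressWarnings(process_image(raster, config, image_id = id))
      write_overlay(pr$grey, pr$skeleton,
                    file.path(overlay_dir,
                              paste0(tools::file_path_sans_ext(id), ".png")))
      rows[[length(rows) + 1L]] <- pr$result
      TRUE
    }, error = function(e) {
      if (verbose) message("  [skip] ", id, ": ", conditionMessage(e))
      failures <<- c(failures, id)
      FALSE
    })
    if (ok && verbose) {
      message(sprintf("  [done] %s (%.1f s, density %.1f um/mm2)", id,
                      proc.time()[["elapsed"]] - t0,
                      rows[[length(rows)]]$vein_density_um_per_mm2))
    }
  }
  if (length(rows) == 0L) {
    stop("no image in ", input, " could be processed", call. = FALSE)
  }
  results <- do.call(rbind, rows)
  results_path <- file.path(out_dir, "results.csv")
  write_results_table(results, results_path)

  meta <- list(
    package = "kranzvein",
    version = as.character(packageVersion("kranzvein")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = .config_as_list(config),
    n_images = length(files),
    n_processed = nrow(results),
    read_failures = as.list(failures)
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  report <- list(
    n_images = length(files),
    n_processed = nrow(results),
    n_flagged = sum(results$flagged),
    results = results,
    read_failures = failures,
    rejected_ids = character(),
    results_path = results_path,
    overlay_dir = overlay_dir
  )
  class(report) <- "batch_report"
  report
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$clahe_tile_grid <- paste(out$clahe_tile_grid, collapse = ",")
  out$threshold_override <- out$threshold_override %||% NA
  out
}

#' @export
print.batch_report <- function(x, ...) {
  cat("<batch_report> ", x$n_processed, "/", x$n_images, " image(s) processed, ",
      x$n_flagged, " flagged, ", length(x$read_failures), " read failure(s)\n",
      sep = "")
  if (length(x$rejected_ids)) {
    cat("  rejected on review: ", paste(x$rejected_ids, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Apply a deferred manual review to a batch report
#'
#' The original workflow inspects each overlay only after the whole batch has
#' finished. This function records that review: rejected images (poor staining
#' or image quality) stay in the table but are marked in an `excluded` column,
#' and a `review_time` column is stamped. A revised CSV is written next to the
#' original results.
#'
#' @param report A `batch_report` from [run_batch()].
#' @param rejections Character vector of image ids to exclude (may be empty).
#' @return The revised `batch_report`, with `results_path_reviewed` added.
#' @export
apply_review <- function(report, rejections = character()) {
  stopifnot(inherits(report, "batch_report"))
  rejections <- as.character(rejections)
  unknown <- setdiff(rejections, report$results$image_id)
  if (length(unknown)) {
    stop("unknown image id(s) in rejection list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  res <- report$results
  res$excluded <- res$image_id %in% rejections
  res$review_time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (all(res$excluded)) {
    warning("review rejected every image in the batch")
  }
  report$results <- res
  report$rejected_ids <- rejections
  if (!is.null(report$results_path)) {
    reviewed <- sub("\\.csv$", "_reviewed.csv", report$results_path)
    write_results_table(res, reviewed)
    report$results_path_reviewed <- reviewed
  }
  report
}

#' Agreement between two vein-density tables
#'
#' Compares two density tables (e.g. automated estimates against manual
#' tracings, or against synthetic ground truth) over their shared image ids:
#' Pearson's correlation coefficient, the least-squares fit of `b` on `a`, and
#' the mean absolute relative difference (relative to table `a`, the reference;
#' ids where `a` is zero are dropped from that summary). No inferential
#' testing is performed.
#'
#' @param table_a,table_b Data frames (or CSV paths) with an id column and a
#'   density column.
#' @param id_col Shared id column name (default `"image_id"`).
#' @param value_col_a,value_col_b Density column names; default
#'   `"vein_density_um_per_mm2"`, falling back to `"density_um_per_mm2"` (the
#'   ground-truth table schema) when absent.
#' @return A `density_agreement` list: `n_shared`, `pearson_r`, `slope`,
#'   `intercept`, `mean_abs_rel_diff`.
#' @export
compare_estimates <- function(table_a, table_b, id_col = "image_id",
                              value_col_a = NULL, value_col_b = NULL) {
  ta <- if (is.character(table_a)) read_results_table(table_a) else table_a
  tb <- if (is.character(table_b)) read_results_table(table_b) else table_b
  pick_col <- function(tab, requested) {
    if (!is.null(requested)) return(requested)
    for (cand in c("vein_density_um_per_mm2", "density_um_per_mm2")) {
      if (cand %in% names(tab)) return(cand)
    }
    stop("no density column found; supply value_col", call. = FALSE)
  }
  ca <- pick_col(ta, value_col_a)
  cb <- pick_col(tb, value_col_b)
  shared <- intersect(ta[[id_col]], tb[[id_col]])
  if (length(shared) < 3L) {
    stop("tables share fewer than 3 image ids", call. = FALSE)
  }
  va <- ta[[ca]][match(shared, ta[[id_col]])]
  vb <- tb[[cb]][match(shared, tb[[id_col]])]
  fit <- lm(vb ~ va)
  nz <- va != 0
  out <- list(
    n_shared = length(shared),
    pearson_r = suppressWarnings(cor(va, vb)),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    mean_abs_rel_diff = if (any(nz)) mean(abs(vb[nz] - va[nz]) / abs(va[nz]))
                        else NA_real_
  )
  class(out) <- "density_agreement"
  out
}

#' @export
print.density_agreement <- function(x, ...) {
  cat(sprintf(
    "<density_agreement> n = %d; r = %.4f; fit b = %.4f a + %.4g; mean |rel diff| = %.4f\n",
    x$n_shared, x$pearson_r, x$slope, x$intercept, x$mean_abs_rel_diff))
  invisible(x)
}
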