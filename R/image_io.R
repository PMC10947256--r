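#' Read a micrograph raster image
#'
#' Reads TIFF, PNG or JPEG images (8- or 16-bit greyscale, or 8-bit RGB) into
#' the package's working representation: greyscale images become a numeric
#' `height x width` matrix with intensities in \[0, 1\]; RGB images become a
#' `height x width x 3` array. Intensities that fall outside \[0, 1\] (e.g.
#' raw sensor counts) are min-max rescaled into range.
#'
#' @param path Path to the image file.
#' @return A numeric matrix (greyscale) or 3-channel array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      stop("cannot read image '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  dat <- EBImage::imageData(img)
  nd <- length(dim(dat))
  if (nd == 2L) {
    out <- t(dat)
  } else if (nd == 3L && dim(dat)[3] >= 3L) {
    out <- aperm(dat[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
  } else if (nd == 3L && dim(dat)[3] == 1L) {
    out <- t(dat[, , 1L])
  } else {
    stop("unsupported channel layout in '", path, "'", call. = FALSE)
  }
  if (any(dim(out)[1:2] == 0L)) {
    stop("zero-size image: ", path, call. = FALSE)
  }
  rng <- range(out)
  if (rng[1] < 0 || rng[2] > 1) {
    out <- if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else out * 0
  }
  out
}

# fixed, documented column order of the results table
.result_columns <- c(
  "image_id", "skeleton_pixel_count", "vein_length_um", "area_mm2",
  "vein_density_um_per_mm2", "auto_trim_used", "effective_trim_factor",
  "flagged"
)

#' Write vein-density results to CSV
#'
#' One row per image, in the fixed column order `image_id`,
#' `skeleton_pixel_count`, `vein_length_um`, `area_mm2`,
#' `vein_density_um_per_mm2`, `auto_trim_used`, `effective_trim_factor`,
#' `flagged`, followed by any review columns (`excluded`, `review_time`) when
#' present. Numeric values are written with 17 significant digits so the table
#' round-trips to full precision. Without `append` the file is replaced
#' atomically (written to a temporary file, then renamed).
#'
#' @param results Data frame of density results (see [measure_density()]).
#' @param path Output CSV path.
#' @param append Append rows to an existing table (e.g. a resumed run) instead
#'   of replacing it.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, append = FALSE) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  extra <- setdiff(names(results), .result_columns)
  cols <- c(intersect(.result_columns, names(results)), extra)
  out <- results[, cols, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  if (append && file.exists(path)) {
    suppressWarnings(write.table(out, path, sep = ",", row.names = FALSE,
                                 col.names = FALSE, append = TRUE, qmethod = "double"))
  } else {
    tmp <- tempfile("results_", tmpdir = dirname(path), fileext = ".csv")
    write.table(out, tmp, sep = ",", row.names = FALSE, col.names = TRUE,
                qmethod = "double")
    if (!file.rename(tmp, path)) {         # e.g. across filesystems
      file.copy(tmp, path, overwrite = TRUE)
      unlink(tmp)
    }
  }
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return Data frame with typed columns.
#' @export
read_results_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  num <- c("skeleton_pixel_count", "vein_length_um", "area_mm2",
           "vein_density_um_per_mm2", "effective_trim_factor")
  for (k in intersect(num, names(df))) df[[k]] <- as.numeric(df[[k]])
  for (k in intersect(c("auto_trim_used", "flagged", "excluded"), names(df))) {
    df[[k]] <- as.logical(df[[k]])
  }
  df
}

#' Write a skeleton overlay for the deferred manual check
#'
#' Renders the final vein trace, morphologically dilated for visibility, in
#' red over the greyscale original and writes it as an image file. These
#' overlays are what the user inspects after a batch has finished.
#'
#' @param original Greyscale image matrix (intensities in \[0, 1\]).
#' @param skeleton Binary skeleton mask of identical dimensions.
#' @param path Output image path (format from the extension, e.g. `.png`).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(original, skeleton, path) {
  stopifnot(is.matrix(original))
  if (!all(dim(original) == dim(skeleton))) {
    stop("skeleton dimensions do not match the original image", call. = FALSE)
  }
  g <- clamp01(original)
  sk <- skeleton != 0
  if (any(sk)) {
    brush <- EBImage::makeBrush(3L, shape = "disc")
    dil <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(t(sk * 1)), brush)
    ) > 0
    dil <- t(dil)
  } else {
    dil <- sk
  }
  r <- g; gch <- g; b <- g
  r[dil] <- 1
  gch[dil] <- 0
  b[dil] <- 0
  rgb <- EBImage::rgbImage(EBImage::Image(t(r)), EBImage::Image(t(gch)),
                           EBImage::Image(t(b)))
  EBImage::writeImage(rgb, path)
  invisible(path)
}
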