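#' Convert a trimmed skeleton into a vein-density measurement
#'
#' At the end of the pipeline every bundle-sheath strand is a line one pixel
#' wide, so the foreground pixel count estimates total vein length:
#' `vein_length_um = count * pixel_length_um`. The image area is
#' `height * width * pixel_length_um^2 / 1e6` square millimetres and vein
#' density is their ratio, in micrometres per square millimetre. The skeleton
#' matrix's own dimensions are used for the area so the denominator always
#' describes the raster actually measured; a mismatch with the configured
#' dimensions is flagged upstream.
#'
#' @param skeleton Logical/binary 1-pixel-wide skeleton mask.
#' @param config A `pipeline_config` (only `pixel_length_um` is used here).
#' @param image_id Identifier recorded in the result row.
#' @param auto_trim_used Whether the trim factor was derived automatically.
#' @param effective_trim_factor The trim factor actually applied.
#' @param flagged Force the flag (e.g. dimension mismatch or degenerate
#'   binarization); an empty skeleton is always flagged.
#' @return One-row data frame with columns `image_id`,
#'   `skeleton_pixel_count`, `vein_length_um`, `area_mm2`,
#'   `vein_density_um_per_mm2`, `auto_trim_used`, `effective_trim_factor`,
#'   `flagged`.
#' @examples
#' cfg <- load_config(list(
#'   input_path = ".", trim_factor = 0,
#'   pixel_length_um = 1, x_pixels = 100, y_pixels = 100
#' ))
#' sk <- matrix(FALSE, 100, 100)
#' sk[50, 1:100] <- TRUE
#' measure_density(sk, cfg)$vein_density_um_per_mm2  # 10000
#' @export
measure_density <- function(skeleton, config, image_id = "image",
                            auto_trim_used = FALSE,
                            effective_trim_factor = config$trim_factor,
                            flagged = FALSE) {
  stopifnot(is.matrix(skeleton), inherits(config, "pipeline_config"))
  pl <- config$pixel_length_um
  count <- sum(skeleton != 0)
  h <- nrow(skeleton); w <- ncol(skeleton)
  vein_length_um <- count * pl
  area_mm2 <- h * w * pl^2 / 1e6
  data.frame(
    image_id = as.character(image_id),
    skeleton_pixel_count = as.integer(count),
    vein_length_um = vein_length_um,
    area_mm2 = area_mm2,
    vein_density_um_per_mm2 = vein_length_um / area_mm2,
    auto_trim_used = isTRUE(auto_trim_used),
    effective_trim_factor = as.integer(effective_trim_factor),
    flagged = isTRUE(flagged) || count == 0L,
    stringsAsFactors = FALSE
  )
}
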