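# Preprocessing: raw micrograph -> veins-as-foreground binary mask.
# Chain: greyscale -> CLAHE -> mean blur -> Otsu binarization -> complement.

#' Convert a raster to greyscale
#'
#' RGB input is reduced with the standard luminance weights
#' `0.2989 R + 0.5870 G + 0.1140 B`; greyscale input passes through, min-max
#' rescaled to \[0, 1\] (a constant image is returned unchanged).
#'
#' @param raster Numeric matrix (greyscale) or `height x width x 3` array.
#' @return Numeric matrix with intensities in \[0, 1\].
#' @export
to_greyscale <- function(raster) {
  if (is.matrix(raster)) {
    g <- raster
  } else if (is.array(raster) && length(dim(raster)) == 3L &&
             dim(raster)[3] == 3L) {
    g <- 0.2989 * raster[, , 1] + 0.5870 * raster[, , 2] +
      0.1140 * raster[, , 3]
  } else if (is.array(raster) && length(dim(raster)) == 3L &&
             dim(raster)[3] == 1L) {
    g <- raster[, , 1]
  } else {
    stop("raster must have 1 or 3 channels", call. = FALSE)
  }
  rng <- range(g)
  if (is.matrix(raster) && rng[2] > rng[1]) {
    g <- (g - rng[1]) / (rng[2] - rng[1])
  }
  clamp01(g)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement that evens out staining and illumination
#' differences before blurring and thresholding. The image is divided into
#' `tile_grid` tiles (rows, cols); each tile's histogram is clipped at
#' `clip_limit` times the uniform level before equalization, and tile mappings
#' are bilinearly interpolated. Images too small to tile fall back to global
#' histogram equalization with a warning.
#'
#' @param img Greyscale matrix, intensities in \[0, 1\].
#' @param clip_limit Positive clip limit (1 = no enhancement beyond clipping).
#' @param tile_grid Integer pair `c(rows, cols)` (a single integer is used for
#'   both).
#' @return Enhanced greyscale matrix in \[0, 1\].
#' @export
enhance_contrast <- function(img, clip_limit = 2, tile_grid = c(8L, 8L)) {
  stopifnot(is.matrix(img), clip_limit > 0)
  tile_grid <- .parse_tile_grid(tile_grid)
  h <- nrow(img); w <- ncol(img)
  ny <- tile_grid[1]; nx <- tile_grid[2]
  if (h %/% ny < 2L || w %/% nx < 2L) {
    warning("image too small for a ", ny, "x", nx,
            " tile grid; falling back to global histogram equalization")
    out <- t(EBImage::imageData(EBImage::equalize(EBImage::Image(t(img)))))
    return(clamp01(out))
  }
  # EBImage's CLAHE needs dimensions divisible by the tile counts:
  # replicate-pad to the next multiple, enhance, crop back
  hp <- as.integer(ceiling(h / ny) * ny)
  wp <- as.integer(ceiling(w / nx) * nx)
  ri <- pmin(seq_len(hp), h)
  ci <- pmin(seq_len(wp), w)
  padded <- img[ri, ci, drop = FALSE]
  out <- EBImage::imageData(
    EBImage::clahe(EBImage::Image(t(padded)), nx = nx, ny = ny,
                   limit = clip_limit)
  )
  clamp01(t(out)[seq_len(h), seq_len(w), drop = FALSE])
}

#' Mean blur with replicate border padding
#'
#' Replaces every pixel by the arithmetic mean of the `(2w+1) x (2w+1)` window
#' centred on it; outside the image the nearest border pixel is replicated, so
#' margins are not darkened. This smoothing step merges punctate starch grains
#' within a bundle-sheath strand into a strand of near-uniform intensity.
#' Implemented exactly (not approximately) with a summed-area table.
#'
#' @param img Greyscale matrix.
#' @param w Positive integer half-width; the paper-default window uses
#'   `w = 20`, i.e. a 41 x 41 kernel.
#' @return Blurred matrix of identical dimensions.
#' @export
mean_blur <- function(img, w) {
  stopifnot(is.matrix(img))
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("w must be a positive integer", call. = FALSE)
  h <- nrow(img); wd <- ncol(img)
  if (w >= min(h, wd)) {
    stop("blur half-width w must be smaller than the image's smallest side",
         call. = FALSE)
  }
  k <- 2L * w + 1L
  ri <- pmin(pmax(seq.int(1L - w, h + w), 1L), h)
  ci <- pmin(pmax(seq.int(1L - w, wd + w), 1L), wd)
  p <- img[ri, ci, drop = FALSE]
  # summed-area table with a zero guard row/column
  s <- apply(p, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  s <- rbind(0, cbind(0, s))
  i1 <- seq_len(h); j1 <- seq_len(wd)
  sums <- s[i1 + k, j1 + k, drop = FALSE] - s[i1, j1 + k, drop = FALSE] -
    s[i1 + k, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
  sums / (k * k)
}

#' Otsu threshold over 256 histogram bins
#'
#' Maximizes the between-class intensity variance over the 255 possible cuts
#' of a 256-bin histogram on \[0, 1\]; ties are broken toward the lower
#' threshold. The returned value is the upper edge of the last background bin,
#' so `pixels > threshold` is the foreground class.
#'
#' @param img Greyscale matrix with intensities in \[0, 1\].
#' @param nbins Number of histogram bins (default 256).
#' @return The threshold in \[0, 1\], with attributes `bin` (0-based index of
#'   the last background bin) and `flagged` (`TRUE` for a degenerate,
#'   zero-variance histogram).
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  stopifnot(is.matrix(img) || is.numeric(img))
  v <- as.numeric(img)
  b <- pmin(as.integer(floor(v * nbins)), nbins - 1L)
  counts <- tabulate(b + 1L, nbins)
  p <- counts / sum(counts)
  lev <- seq.int(0L, nbins - 1L)
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[nbins]
  w0 <- omega[seq_len(nbins - 1L)]
  m0 <- mu[seq_len(nbins - 1L)]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  flagged <- all(sigma_b == -Inf)
  kstar <- if (flagged) 0L else which.max(sigma_b) - 1L
  t <- (kstar + 1) / nbins
  attr(t, "bin") <- kstar
  attr(t, "flagged") <- flagged
  t
}

#' Binarize a greyscale image
#'
#' Thresholds at [otsu_threshold()] unless `threshold_override` is supplied;
#' pixels strictly above the threshold become foreground (1). After this step
#' the bright background is foreground and dark-stained veins are background;
#' [orient_foreground()] flips that. A constant (zero-variance) image yields
#' an all-zero mask with attribute `flagged = TRUE`.
#'
#' @param img Greyscale matrix with intensities in \[0, 1\].
#' @param threshold_override Optional fixed threshold in \[0, 1\].
#' @return Logical mask with attributes `threshold` and `flagged`.
#' @export
binarize <- function(img, threshold_override = NULL) {
  stopifnot(is.matrix(img))
  if (!is.null(threshold_override)) {
    stopifnot(threshold_override >= 0, threshold_override <= 1)
    mask <- img > threshold_override
    attr(mask, "threshold") <- as.numeric(threshold_override)
    attr(mask, "flagged") <- FALSE
    return(mask)
  }
  t <- otsu_threshold(img)
  if (isTRUE(attr(t, "flagged"))) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "flagged") <- TRUE
    return(mask)
  }
  mask <- img > as.numeric(t)
  attr(mask, "threshold") <- as.numeric(t)
  attr(mask, "flagged") <- FALSE
  mask
}

#' Orient the mask so veins are foreground
#'
#' Starch-stained veins are dark, so after thresholding they form the
#' background class; complementing the mask (the default) makes them
#' foreground. Set `invert_foreground = FALSE` for images of inverted polarity
#' (bright veins on a dark background).
#'
#' @param mask Logical/binary mask.
#' @param invert_foreground Complement the mask (default `TRUE`).
#' @return Logical mask with veins as `TRUE`.
#' @export
orient_foreground <- function(mask, invert_foreground = TRUE) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  out <- if (invert_foreground) !m else m
  attr(out, "threshold") <- attr(mask, "threshold")
  attr(out, "flagged") <- attr(mask, "flagged")
  out
}
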