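# Synthetic vein-image generator: stained-leaf look-alikes with exact
# analytic ground-truth length, for validating every pipeline stage without
# real micrographs.

#' Specify a synthetic venation image
#'
#' Describes a venation network and its rendering. Two topologies are
#' available: `"parallel"` emulates a grass leaf — near-vertical longitudinal
#' veins ("rails") joined by short horizontal commissural rungs — and
#' `"reticulate"` emulates a dicot network of wavy primaries joined by oblique
#' secondaries that close areoles. Vein centrelines are deterministic
#' functions of the geometric parameters only; the seed drives nothing but the
#' noise field. Strands are rendered dark on a bright background, matching
#' iodine-stained starch, with Gaussian pixel noise and a linear horizontal
#' illumination ramp.
#'
#' Defaults emulate the acquisition conditions of a 100x brightfield
#' starch-stain image: a 1392 x 1040 px frame at 0.65 um per pixel, vein
#' spacing of roughly 100 um, stroke width 5 px, background intensity 0.85
#' against vein intensity 0.25, noise sd 0.03 and an 8% illumination ramp.
#'
#' @param topology `"parallel"` or `"reticulate"`.
#' @param image_height,image_width Frame size in pixels.
#' @param pixel_length_um Scale, micrometres per pixel side.
#' @param n_primaries Number of longitudinal veins (0 gives a blank image).
#' @param rail_spacing_px Horizontal spacing between primaries, pixels.
#' @param waviness_amplitude_px Lateral sinusoidal amplitude of primaries.
#' @param commissural_spacing_px Vertical spacing of commissural rungs along
#'   each rail pair (parallel topology only).
#' @param stroke_width_px Rendered stroke diameter, pixels (odd; an even value
#'   is widened by one pixel).
#' @param background_level,vein_level Background and vein intensities in
#'   \[0, 1\]; `vein_level` must be darker.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param illumination_gradient Total relative intensity change across the
#'   image width (0 disables the ramp).
#' @param seed Integer seed for the noise field.
#' @return A `vein_spec` object.
#' @seealso [generate_veins()], [ground_truth_density()]
#' @export
vein_spec <- function(topology = c("parallel", "reticulate"),
                      image_height = 1040L, image_width = 1392L,
                      pixel_length_um = 0.65,
                      n_primaries = 8L, rail_spacing_px = 150,
                      waviness_amplitude_px = 8,
                      commissural_spacing_px = 260,
                      stroke_width_px = 5L,
                      background_level = 0.85, vein_level = 0.25,
                      noise_sd = 0.03, illumination_gradient = 0.08,
                      seed = 1L) {
  topology <- match.arg(topology)
  spec <- list(
    topology = topology,
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_length_um = as.numeric(pixel_length_um),
    n_primaries = as.integer(n_primaries),
    rail_spacing_px = as.numeric(rail_spacing_px),
    waviness_amplitude_px = as.numeric(waviness_amplitude_px),
    commissural_spacing_px = as.numeric(commissural_spacing_px),
    stroke_width_px = as.integer(stroke_width_px),
    background_level = as.numeric(background_level),
    vein_level = as.numeric(vein_level),
    noise_sd = as.numeric(noise_sd),
    illumination_gradient = as.numeric(illumination_gradient),
    seed = as.integer(seed)
  )
  stopifnot(
    spec$image_height >= 16L, spec$image_width >= 16L,
    spec$pixel_length_um > 0,
    spec$n_primaries >= 0L,
    spec$rail_spacing_px > 0, spec$waviness_amplitude_px >= 0,
    spec$commissural_spacing_px > 0,
    spec$stroke_width_px >= 1L,
    spec$background_level >= 0, spec$background_level <= 1,
    spec$vein_level >= 0, spec$vein_level <= 1,
    spec$noise_sd >= 0
  )
  if (spec$vein_level >= spec$background_level) {
    stop("vein_level must be darker than background_level", call. = FALSE)
  }
  if (spec$n_primaries > 0L) {
    half <- (spec$stroke_width_px + 1) / 2
    span <- (spec$n_primaries - 1L) * spec$rail_spacing_px
    margin <- (spec$image_width - span) / 2 -
      spec$waviness_amplitude_px - half
    if (margin < 1) {
      stop("vein strokes exceed the image bounds; reduce n_primaries, ",
           "rail_spacing_px or waviness_amplitude_px", call. = FALSE)
    }
  }
  class(spec) <- "vein_spec"
  spec
}

# centreline geometry: polylines as (row, col) real-valued matrices, split
# into primaries (rails) and connectors (rungs / secondaries)
.vein_geometry <- function(spec) {
  h <- spec$image_height; w <- spec$image_width
  n <- spec$n_primaries
  rails <- list(); connectors <- list()
  if (n > 0L) {
    amp <- spec$waviness_amplitude_px
    sp <- spec$rail_spacing_px
    period <- 520
    x0 <- (w - (n - 1L) * sp) / 2
    railx <- function(i, y) {
      x0 + (i - 1L) * sp + amp * sin(2 * pi * y / period +
                                       2 * pi * (i - 1L) / max(n, 1L))
    }
    ys <- seq_len(h)
    for (i in seq_len(n)) {
      rails[[i]] <- cbind(row = ys, col = railx(i, ys))
    }
    conn_spacing <- if (spec$topology == "parallel") {
      spec$commissural_spacing_px
    } else {
      1.6 * sp
    }
    golden <- 0.6180339887498949
    for (i in seq_len(max(0L, n - 1L))) {
      # parallel rungs are aligned across rail pairs so that the span of a
      # rail segment between junctions stays at the full commissural
      # spacing; reticulate secondaries are staggered to vary the areoles
      stagger <- if (spec$topology == "parallel") {
        conn_spacing * 0.4
      } else {
        conn_spacing * (0.3 + 0.5 * ((i * golden) %% 1))
      }
      y_at <- if (stagger > h - 6) numeric(0) else
        seq(stagger, h - 6, by = conn_spacing)
      y_at <- y_at[y_at >= 6]
      j <- 0L
      for (y in y_at) {
        j <- j + 1L
        if (spec$topology == "parallel") {
          xa <- railx(i, y); xb <- railx(i + 1L, y)
          steps <- max(2L, ceiling(abs(xb - xa)) + 1L)
          connectors[[length(connectors) + 1L]] <-
            cbind(row = rep(y, steps), col = seq(xa, xb, length.out = steps))
        } else {
          dy <- (if ((i + j) %% 2L == 0L) 1 else -1) * 0.2 * conn_spacing
          y2 <- min(max(y + dy, 6), h - 6)
          xa <- railx(i, y); xb <- railx(i + 1L, y2)
          steps <- max(2L, ceiling(max(abs(xb - xa), abs(y2 - y))) + 1L)
          connectors[[length(connectors) + 1L]] <-
            cbind(row = seq(y, y2, length.out = steps),
                  col = seq(xa, xb, length.out = steps))
        }
      }
    }
  }
  list(rails = rails, connectors = connectors)
}

# pixel-covering length of a centreline polyline: arc length plus one pixel,
# so a strand of N collinear pixels measures N (the convention of the
# pixel-count length estimator)
.polyline_len <- function(p) {
  if (nrow(p) == 0L) return(0)
  if (nrow(p) == 1L) return(1)
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)) + 1
}

# rasterize polylines into a centreline mask (dense resampling + rounding)
.rasterize_polylines <- function(polys, h, w) {
  mask <- matrix(FALSE, h, w)
  for (p in polys) {
    if (nrow(p) < 2L) next
    seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
    if (total == 0) next
    tt <- seq(0, total, by = 0.35)
    rr <- round(approx(cum, p[, 1], xout = tt)$y)
    cc <- round(approx(cum, p[, 2], xout = tt)$y)
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Generate a synthetic stained-leaf image with exact ground truth
#'
#' Renders the centreline network of a [vein_spec()] with the given stroke
#' width (disc stamping via morphological dilation), applies the illumination
#' ramp and adds seeded Gaussian noise. The ground-truth vein length is the
#' analytic arc length of the centreline polylines (pixel-covering
#' convention: a straight strand of N collinear pixels measures N) —
#' independent of rasterization — so end-to-end recovery tests also bound
#' the bias of the pixel-count length estimator. For the parallel topology,
#' `rails_only_length_um` excludes the commissural rungs, which is the
#' quantity a monocot-mode run should recover.
#'
#' @param spec A `vein_spec`.
#' @param invert_polarity Render bright veins on a dark background instead
#'   (exercises `invert_foreground = FALSE`).
#' @return A list: `image` (numeric matrix in \[0, 1\]), `centreline`
#'   (logical mask), `ground_truth_length_um`, `rails_only_length_um`,
#'   `ground_truth_density_um_per_mm2`, and the `spec`.
#' @examples
#' gen <- generate_veins(vein_spec(
#'   "parallel", image_height = 256, image_width = 256,
#'   n_primaries = 2, rail_spacing_px = 120,
#'   waviness_amplitude_px = 0, seed = 7
#' ))
#' gen$ground_truth_density_um_per_mm2
#' @export
generate_veins <- function(spec, invert_polarity = FALSE) {
  stopifnot(inherits(spec, "vein_spec"))
  h <- spec$image_height; w <- spec$image_width
  geom <- .vein_geometry(spec)
  rails_arc <- sum(vapply(geom$rails, .polyline_len, numeric(1)))
  conn_arc <- sum(vapply(geom$connectors, .polyline_len, numeric(1)))
  centre <- .rasterize_polylines(c(geom$rails, geom$connectors), h, w)

  b <- spec$stroke_width_px
  if (b %% 2L == 0L) b <- b + 1L
  vein_mask <- if (b > 1L && any(centre)) {
    t(EBImage::imageData(EBImage::dilate(
      EBImage::Image(t(centre * 1)), EBImage::makeBrush(b, shape = "disc")
    )) > 0)
  } else {
    centre
  }

  base <- matrix(spec$background_level, h, w)
  base[vein_mask] <- spec$vein_level
  xnorm <- matrix(rep((seq_len(w) - 0.5) / w - 0.5, each = h), h, w)
  img <- base * (1 + spec$illumination_gradient * xnorm)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(rnorm(h * w, 0, spec$noise_sd), h, w))
  }
  img <- clamp01(img)
  if (invert_polarity) img <- 1 - img

  pl <- spec$pixel_length_um
  total_um <- (rails_arc + conn_arc) * pl
  area_mm2 <- h * w * pl^2 / 1e6
  list(
    image = img,
    centreline = centre,
    ground_truth_length_um = total_um,
    rails_only_length_um = rails_arc * pl,
    ground_truth_density_um_per_mm2 = total_um / area_mm2,
    spec = spec
  )
}

#' Analytic ground-truth vein density of a spec
#'
#' Total centreline arc length divided by the image area, in the same units as
#' [measure_density()] (um per square mm); no rendering takes place.
#'
#' @param spec A `vein_spec`.
#' @return Density in um per square mm.
#' @export
ground_truth_density <- function(spec) {
  stopifnot(inherits(spec, "vein_spec"))
  geom <- .vein_geometry(spec)
  arc <- sum(vapply(c(geom$rails, geom$connectors), .polyline_len,
                    numeric(1)))
  pl <- spec$pixel_length_um
  area_mm2 <- spec$image_height * spec$image_width * pl^2 / 1e6
  arc * pl / area_mm2
}

#' Write a directory of synthetic images plus their ground truth
#'
#' Emits one image file per spec and a `ground_truth.csv` (columns
#' `image_id`, `length_um`, `rails_only_length_um`, `density_um_per_mm2`)
#' consumable by [run_batch()] and [compare_estimates()] for self-tests.
#'
#' @param specs List of `vein_spec` objects.
#' @param dir Output directory (created if needed).
#' @param format Image file extension (default `"png"`).
#' @return Path of the ground-truth CSV, invisibly.
#' @export
write_synthetic_set <- function(specs, dir, format = "png") {
  if (inherits(specs, "vein_spec")) specs <- list(specs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    gen <- generate_veins(specs[[i]])
    id <- sprintf("synthetic_%s_%03d", specs[[i]]$topology, i)
    EBImage::writeImage(EBImage::Image(t(gen$image)),
                        file.path(dir, paste0(id, ".", format)))
    rows[[i]] <- data.frame(
      image_id = paste0(id, ".", format),
      length_um = gen$ground_truth_length_um,
      rails_only_length_um = gen$rails_only_length_um,
      density_um_per_mm2 = gen$ground_truth_density_um_per_mm2,
      stringsAsFactors = FALSE
    )
  }
  gt <- do.call(rbind, rows)
  path <- file.path(dir, "ground_truth.csv")
  write.table(gt, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}
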