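# Recognised configuration surface: 14 keys, 5 of them mandatory.
.config_keys <- c(
  # mandatory
  "input_path", "trim_factor", "pixel_length_um", "x_pixels", "y_pixels",
  # optional, with defaults
  "mode", "monocot_branch_length_to_keep", "blur_w", "clahe_clip_limit",
  "clahe_tile_grid", "threshold_override", "invert_foreground",
  "auto_trim_trigger_fraction", "output_dir"
)
.config_mandatory <- .config_keys[1:5]

.config_defaults <- function() {
  list(
    mode = "auto",
    monocot_branch_length_to_keep = 0,
    blur_w = 20L,
    clahe_clip_limit = 2,
    clahe_tile_grid = c(8L, 8L),
    threshold_override = NULL,
    invert_foreground = TRUE,
    auto_trim_trigger_fraction = 0.15,
    output_dir = "kranzvein_output"
  )
}

#' Load and validate a pipeline configuration
#'
#' Builds the configuration that drives the vein-density pipeline. Fourteen
#' keys are recognised; five are mandatory: `input_path` (image file or
#' directory), `trim_factor` (pixel length below which spur branches are
#' deleted), `pixel_length_um` (image scale, micrometres per pixel side),
#' `x_pixels` and `y_pixels` (expected image width and height). The nine
#' optional keys tune individual stages and default to: `mode = "auto"`
#' (`"monocot"` additionally removes commissural veins),
#' `monocot_branch_length_to_keep = 0` (Euclidean branch-point span, in
#' pixels, below which a commissural vein is removed; 0 disables removal),
#' `blur_w = 20` (mean-filter half-width, kernel is `(2w+1) x (2w+1)`),
#' `clahe_clip_limit = 2` and `clahe_tile_grid = "8,8"` (contrast
#' enhancement), `threshold_override` (unset: Otsu's method),
#' `invert_foreground = TRUE` (complement after binarization so dark-stained
#' veins become foreground), `auto_trim_trigger_fraction = 0.15` (spur-pixel
#' fraction above which the trim factor is computed automatically) and
#' `output_dir`.
#'
#' @param source Path to a flat `key = value` configuration file, or a named
#'   list of values.
#' @param overrides Named list merged over `source` (e.g. command-line flags).
#' @return A validated `pipeline_config` object (a named list).
#' @examples
#' cfg <- load_config(list(
#'   input_path = ".", trim_factor = 10,
#'   pixel_length_um = 0.65, x_pixels = 1392, y_pixels = 1040
#' ))
#' cfg$blur_w
#' @seealso [serialize_config()], [run_batch()]
#' @export
load_config <- function(source, overrides = list()) {
  vals <- if (is.character(source) && length(source) == 1L) {
    .parse_config_file(source)
  } else if (is.list(source)) {
    source
  } else {
    stop("`source` must be a file path or a named list", call. = FALSE)
  }
  if (length(overrides)) vals <- modifyList(vals, overrides)
  vals <- vals[!vapply(vals, is.null, logical(1))]

  unknown <- setdiff(names(vals), .config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.config_mandatory, names(vals))
  if (length(missing)) {
    stop(paste0(missing[1], " required"), call. = FALSE)
  }

  cfg <- .config_defaults()
  for (k in names(vals)) cfg[[k]] <- vals[[k]]

  cfg$input_path <- as.character(cfg$input_path)
  cfg$trim_factor <- .as_count(cfg$trim_factor, "trim_factor")
  cfg$pixel_length_um <- as.numeric(cfg$pixel_length_um)
  if (!is.finite(cfg$pixel_length_um) || cfg$pixel_length_um <= 0) {
    stop("pixel_length_um must be a positive number", call. = FALSE)
  }
  cfg$x_pixels <- .as_count(cfg$x_pixels, "x_pixels")
  cfg$y_pixels <- .as_count(cfg$y_pixels, "y_pixels")
  if (cfg$x_pixels < 16L || cfg$y_pixels < 16L) {
    stop("x_pixels and y_pixels must be at least 16", call. = FALSE)
  }
  cfg$mode <- match.arg(cfg$mode, c("auto", "monocot"))
  cfg$monocot_branch_length_to_keep <-
    as.numeric(cfg$monocot_branch_length_to_keep)
  if (!is.finite(cfg$monocot_branch_length_to_keep) ||
      cfg$monocot_branch_length_to_keep < 0) {
    stop("monocot_branch_length_to_keep must be non-negative", call. = FALSE)
  }
  cfg$blur_w <- .as_count(cfg$blur_w, "blur_w")
  if (cfg$blur_w < 1L) stop("blur_w must be a positive integer", call. = FALSE)
  cfg$clahe_clip_limit <- as.numeric(cfg$clahe_clip_limit)
  if (!is.finite(cfg$clahe_clip_limit) || cfg$clahe_clip_limit <= 0) {
    stop("clahe_clip_limit must be positive", call. = FALSE)
  }
  cfg$clahe_tile_grid <- .parse_tile_grid(cfg$clahe_tile_grid)
  if (!is.null(cfg$threshold_override)) {
    if (length(cfg$threshold_override) == 1L &&
        (is.na(cfg$threshold_override) ||
         identical(cfg$threshold_override, ""))) {
      cfg["threshold_override"] <- list(NULL)  # unset, keep the slot
    } else {
      cfg$threshold_override <- as.numeric(cfg$threshold_override)
      if (!is.finite(cfg$threshold_override) ||
          cfg$threshold_override < 0 || cfg$threshold_override > 1) {
        stop("threshold_override must lie in [0, 1]", call. = FALSE)
      }
    }
  }
  cfg$invert_foreground <- .as_flag(cfg$invert_foreground, "invert_foreground")
  cfg$auto_trim_trigger_fraction <- as.numeric(cfg$auto_trim_trigger_fraction)
  if (!is.finite(cfg$auto_trim_trigger_fraction) ||
      cfg$auto_trim_trigger_fraction < 0 ||
      cfg$auto_trim_trigger_fraction > 1) {
    stop("auto_trim_trigger_fraction must lie in [0, 1]", call. = FALSE)
  }
  cfg$output_dir <- as.character(cfg$output_dir)

  cfg <- cfg[.config_keys]
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a configuration back to a flat key = value file
#'
#' The written file round-trips through [load_config()] to an identical
#' configuration.
#'
#' @param config A `pipeline_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fmt <- function(k) {
    v <- config[[k]]
    if (is.null(v)) return(NULL)
    if (k == "clahe_tile_grid") v <- paste(v, collapse = ",")
    if (is.logical(v)) v <- ifelse(v, "true", "false")
    if (is.numeric(v)) v <- format(v, digits = 17)
    paste0(k, " = ", v)
  }
  lines <- unlist(lapply(.config_keys, fmt))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in .config_keys) {
    v <- x[[k]]
    cat(sprintf("  %-30s %s\n", k,
                if (is.null(v)) "(unset)" else paste(format(v), collapse = ",")))
  }
  invisible(x)
}

.parse_config_file <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop("cannot parse configuration line: ", ln, call. = FALSE)
    }
    vals[[m[2]]] <- trimws(m[3])
  }
  vals
}

.parse_tile_grid <- function(x) {
  if (is.character(x)) {
    x <- as.numeric(strsplit(x, "[,x ]+")[[1]])
  }
  x <- as.integer(round(as.numeric(x)))
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)) || any(x < 1L)) {
    stop("clahe_tile_grid must be one or two positive integers", call. = FALSE)
  }
  x
}

.as_count <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
    stop(name, " must be a non-negative integer", call. = FALSE)
  }
  as.integer(v)
}

.as_flag <- function(x, name) {
  if (is.logical(x) && length(x) == 1L && !is.na(x)) return(x)
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    if (lx %in% c("true", "t", "yes", "1")) return(TRUE)
    if (lx %in% c("false", "f", "no", "0")) return(FALSE)
  }
  if (is.numeric(x) && x %in% c(0, 1)) return(x == 1)
  stop(name, " must be a logical value", call. = FALSE)
}
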