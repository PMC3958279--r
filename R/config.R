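#' System configuration for the fall-detection pipeline
#'
#' Bundles every tunable parameter of the processing chain.  Defaults match
#' the reference operating point: a sensor mounted on the ceiling 3 m above
#' the floor (`max_height`), 320x240 depth frames at 30 fps, and the
#' empirically calibrated thresholds for foreground extraction, edge carving,
#' person identification and fall detection.
#'
#' @param max_height Sensor-to-floor distance in mm.  Pixels at this depth
#'   are floor.
#' @param floor_band Pixels within this many mm of `max_height` are clamped
#'   to the floor (absorbs carpet/sensor jitter and a lying person's feet).
#' @param th_person Foreground threshold in mm: a pixel whose current depth
#'   differs from the reference frame by more than this is treated as a new
#'   element in the scene.
#' @param gap_coeff Depth-level slicing constant in mm added to foreground
#'   pixels so a fixed Sobel threshold always separates new elements from
#'   static ones, regardless of their raw depth similarity.
#' @param th_sobel Sobel gradient-magnitude threshold (gradient units over
#'   mm values) above which a pixel is treated as an object boundary and
#'   carved to floor depth.
#' @param fall_threshold A tracked person whose central-point height above
#'   the floor drops strictly below this many mm triggers a fall event.
#' @param head_drop_range Two mm values: the cumulative head-to-shoulder
#'   depth drop that marks a human head (head height above shoulders).
#' @param head_diag_range Two mm values: admissible head extent measured
#'   through the four principal axes.
#' @param min_drop_directions Number of scan directions (out of 8) in which
#'   the head-shoulder drop must be observed.
#' @param head_comparability_ratio Maximum allowed ratio between the largest
#'   and smallest of the four head extents.
#' @param fov_half_x,fov_half_y Half field-of-view angles in degrees along
#'   the 320-pixel and 240-pixel axes.
#' @param frame_width,frame_height Frame size in pixels.
#' @param block_w,block_h Super-pixel block size in pixels (8x6 blocks give
#'   the 40x40 super-pixel grid).
#' @param fps Frame rate in Hz.
#' @param fusion_split_radius Chebyshev radius, in super-pixels, used to
#'   carve each participant out of a fused blob.
#' @param peak_radius Planar radius in mm of the neighbourhood averaged
#'   around the depth minimum when locating the head peak point.
#' @param peak_depth_window Depth window in mm around the minimum used for
#'   the same averaging.
#' @param track_grace Number of consecutive unmatched frames after which a
#'   tracked person (or object) is retired.
#'
#' @return An object of class `system_config` (a validated named list).
#' @examples
#' cfg <- system_config()
#' cfg$fall_threshold
#' @export
system_config <- function(max_height = 3000,
                          floor_band = 200,
                          th_person = 50,
                          gap_coeff = 6000,
                          th_sobel = 2000,
                          fall_threshold = 400,
                          head_drop_range = c(200, 300),
                          head_diag_range = c(200, 400),
                          min_drop_directions = 2,
                          head_comparability_ratio = 1.5,
                          fov_half_x = 28.5,
                          fov_half_y = 21.5,
                          frame_width = 320,
                          frame_height = 240,
                          block_w = 8,
                          block_h = 6,
                          fps = 30,
                          fusion_split_radius = 5,
                          peak_radius = 100,
                          peak_depth_window = 50,
                          track_grace = 15) {
  cfg <- list(
    max_height = max_height, floor_band = floor_band,
    th_person = th_person, gap_coeff = gap_coeff, th_sobel = th_sobel,
    fall_threshold = fall_threshold,
    head_drop_range = head_drop_range, head_diag_range = head_diag_range,
    min_drop_directions = min_drop_directions,
    head_comparability_ratio = head_comparability_ratio,
    fov_half_x = fov_half_x, fov_half_y = fov_half_y,
    frame_width = frame_width, frame_height = frame_height,
    block_w = block_w, block_h = block_h, fps = fps,
    fusion_split_radius = fusion_split_radius,
    peak_radius = peak_radius, peak_depth_window = peak_depth_window,
    track_grace = track_grace
  )
  validate_config(cfg)
  structure(cfg, class = "system_config")
}

validate_config <- function(cfg) {
  mm_fields <- c("max_height", "floor_band", "th_person", "gap_coeff",
                 "fall_threshold", "peak_radius", "peak_depth_window")
  for (f in mm_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      stop("config field '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (cfg$th_person >= cfg$gap_coeff) {
    stop("th_person must be smaller than gap_coeff", call. = FALSE)
  }
  if (cfg$fall_threshold >= cfg$max_height) {
    stop("fall_threshold must be smaller than max_height", call. = FALSE)
  }
  if (cfg$frame_width %% cfg$block_w != 0 ||
      cfg$frame_height %% cfg$block_h != 0) {
    stop("frame dimensions must be divisible by the super-pixel block size",
         call. = FALSE)
  }
  for (f in c("head_drop_range", "head_diag_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2] || any(r < 0)) {
      stop("config field '", f, "' must be an increasing mm interval",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.system_config <- function(x, ...) {
  cat("<system_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-25s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}

## Super-pixel grid dimensions implied by a config.
grid_dims <- function(cfg) {
  c(rows = cfg$frame_height %/% cfg$block_h,
    cols = cfg$frame_width %/% cfg$block_w)
}

#' Read and write flat key-value configuration files
#'
#' The on-disk format is one `key = value` pair per line (two numbers for
#' interval fields), `#` comments allowed.  Unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path File path.
#' @param cfg A [system_config()] object.
#' @return `read_config()` returns a `system_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- formals(system_config)
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    val <- as.numeric(strsplit(trimws(kv[2]), "[ ,]+")[[1]])
    if (anyNA(val)) stop("non-numeric value for config key ", key, call. = FALSE)
    args[[key]] <- val
  }
  do.call(system_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "system_config"))
  lines <- vapply(names(cfg), function(nm) {
    sprintf("%s = %s", nm, paste(format(cfg[[nm]], scientific = FALSE),
                                 collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
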