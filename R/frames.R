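## Processing stages a depth frame moves through:
##   DF      raw sensor frame (null pixels = 0 allowed)
##   DFm     after floor clamping
##   CF      after null filling (no zeros remain)
##   RF      reference frame of the empty scene (a CF by construction)
##   FF      foreground frame (CF with deviating pixels boosted by gap_coeff)
##   FFSobel FF after edge carving
FRAME_STAGES <- c("DF", "DFm", "CF", "RF", "FF", "FFSobel")

#' Depth frames
#'
#' A depth frame is an integer matrix (rows = image rows, default 240x320)
#' of distances in millimetres from the sensor plane to the nearest surface,
#' tagged with its processing `stage` and capture `index`.  A value of 0 is
#' a sensor dropout (null pixel) and is only legal in stages `DF`/`DFm`.
#'
#' @param grid Numeric matrix of depth values in mm.
#' @param stage One of `"DF"`, `"DFm"`, `"CF"`, `"RF"`, `"FF"`, `"FFSobel"`.
#' @param index Frame number within its sequence (1-based).
#' @return An integer matrix of class `depth_frame` with attributes `stage`
#'   and `index`.
#' @examples
#' f <- depth_frame(matrix(3000L, 240, 320))
#' frame_stage(f)
#' @export
depth_frame <- function(grid, stage = "DF", index = 1L) {
  stage <- match.arg(stage, FRAME_STAGES)
  if (!is.matrix(grid)) stop("grid must be a matrix", call. = FALSE)
  if (any(grid < 0, na.rm = TRUE)) stop("depth values must be >= 0", call. = FALSE)
  storage.mode(grid) <- "integer"
  if (stage %in% c("CF", "RF", "FF", "FFSobel") && any(grid == 0L)) {
    stop("stage ", stage, " frames must not contain null (0) pixels",
         call. = FALSE)
  }
  structure(grid, stage = stage, index = as.integer(index),
            class = c("depth_frame", "matrix", "array"))
}

#' @rdname depth_frame
#' @param frame A `depth_frame`.
#' @export
frame_stage <- function(frame) attr(frame, "stage")

#' @rdname depth_frame
#' @export
frame_index <- function(frame) attr(frame, "index")

## Re-tag a frame's grid with a new stage, preserving index.
restage <- function(frame, stage) {
  depth_frame(unclass_grid(frame), stage = stage,
              index = attr(frame, "index") %||% 1L)
}

unclass_grid <- function(frame) {
  g <- frame
  attributes(g) <- list(dim = dim(frame))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_stage <- function(frame, stages, op) {
  if (!inherits(frame, "depth_frame")) {
    stop(op, "() expects a depth_frame", call. = FALSE)
  }
  if (!frame_stage(frame) %in% stages) {
    stop(op, "() expects a frame in stage ", paste(stages, collapse = "/"),
         ", got ", frame_stage(frame), call. = FALSE)
  }
  invisible(frame)
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame %dx%d stage=%s index=%d range=[%d, %d] mm>\n",
              nrow(x), ncol(x), frame_stage(x), frame_index(x),
              min(x), max(x)))
  invisible(x)
}

#' Read and write depth-frame sequences
#'
#' Two interchange formats are supported.  `raw16` is a flat little-endian
#' unsigned 16-bit stream, frames concatenated row-major (row by row); one
#' file holds a whole sequence.  `image16` is one 16-bit single-channel
#' grayscale TIFF per frame; a directory is read in lexicographic filename
#' order.  Depth values are never rescaled, clipped or otherwise altered,
#' and null (0) pixels are preserved, so a write/read round trip is
#' bit-exact.
#'
#' @param path For `raw16` a file; for `image16` a directory (reading) or a
#'   directory to be created (writing).
#' @param format `"image16"` or `"raw16"`.
#' @param width,height Frame size in pixels (needed to slice `raw16`).
#' @return `read_sequence()` returns a list of `depth_frame`s in capture
#'   order, stage `DF`; `write_sequence()` returns `path` invisibly.
#' @export
read_sequence <- function(path, format = c("image16", "raw16"),
                          width = 320, height = 240) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path, call. = FALSE)
  if (format == "raw16") {
    sz <- file.size(path)
    bytes_per_frame <- width * height * 2
    if (sz == 0 || sz %% bytes_per_frame != 0) {
      stop("raw16 payload of ", sz, " bytes is not a multiple of ",
           bytes_per_frame, " (", width, "x", height, "x2)", call. = FALSE)
    }
    n_frames <- sz %/% bytes_per_frame
    con <- file(path, "rb")
    on.exit(close(con))
    lapply(seq_len(n_frames), function(i) {
      v <- readBin(con, what = "integer", n = width * height, size = 2L,
                   signed = FALSE, endian = "little")
      depth_frame(matrix(v, nrow = height, ncol = width, byrow = TRUE),
                  stage = "DF", index = i)
    })
  } else {
    files <- if (dir.exists(path)) {
      sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    } else {
      path
    }
    if (length(files) == 0) stop("no TIFF frames under ", path, call. = FALSE)
    lapply(seq_along(files), function(i) {
      img <- tiff::readTIFF(files[i], as.is = TRUE)
      if (!is.matrix(img)) {
        stop("frame ", files[i], " is not single-channel", call. = FALSE)
      }
      if (attr(img, "bits.per.sample") %||% 16L != 16L) {
        stop("frame ", files[i], " is not 16-bit", call. = FALSE)
      }
      depth_frame(img, stage = "DF", index = i)
    })
  }
}

#' @rdname read_sequence
#' @param frames List of `depth_frame`s.
#' @export
write_sequence <- function(frames, path, format = c("image16", "raw16")) {
  format <- match.arg(format)
  stopifnot(length(frames) > 0)
  if (format == "raw16") {
    con <- file(path, "wb")
    on.exit(close(con))
    for (f in frames) {
      v <- as.integer(t(unclass_grid(f)))          # row-major on disk
      writeBin(as.raw(rbind(v %% 256L, v %/% 256L)), con)  # little-endian
    }
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_along(frames)) {
      g <- unclass_grid(frames[[i]])
      tiff::writeTIFF(g / 65535, file.path(path, sprintf("frame_%05d.tif", i)),
                      bits.per.sample = 16L, compression = "none")
    }
  }
  invisible(path)
}

#' Fall events
#'
#' A fall event records the frame at which a tracked person's central-point
#' height above the floor first drops below the fall threshold.
#'
#' @param frame_index Frame number of the detection.
#' @param person_id Identifier of the tracked person.
#' @param height_above_floor Height in mm at the triggering frame (always
#'   strictly below the configured threshold).
#' @return A one-row tibble with the three fields above.
#' @export
fall_event <- function(frame_index, person_id, height_above_floor) {
  tibble(frame_index = as.integer(frame_index),
         person_id = as.integer(person_id),
         height_above_floor = as.numeric(height_above_floor))
}

empty_events <- function() {
  tibble(frame_index = integer(), person_id = integer(),
         height_above_floor = numeric())
}

#' Write and read fall events as JSON lines
#'
#' One JSON object per line with the fixed field order `frame_index`,
#' `person_id`, `height_above_floor`, in frame order.  An empty event table
#' produces an empty file.
#'
#' @param events Tibble of events (as produced by the tracker).
#' @param path Output file.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the events tibble.
#' @export
write_events <- function(events, path) {
  events <- events[order(events$frame_index), , drop = FALSE]
  lines <- vapply(seq_len(nrow(events)), function(i) {
    as.character(jsonlite::toJSON(list(
      frame_index = events$frame_index[i],
      person_id = events$person_id[i],
      height_above_floor = events$height_above_floor[i]
    ), auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_events())
  rows <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    fall_event(x$frame_index, x$person_id, x$height_above_floor)
  })
  bind_rows(rows)
}

#' Write per-frame tracked heights as CSV
#'
#' Produces the `frame_index, person_id, height_mm` table used for
#' height-trace plots of a tracked subject over time.
#'
#' @param heights Tibble with columns `frame_index`, `person_id`,
#'   `height_mm` (extra columns are preserved).
#' @param path Output CSV path.
#' @export
write_heights <- function(heights, path) {
  write.csv(heights, path, row.names = FALSE)
  invisible(path)
}
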