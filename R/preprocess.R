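#' Clamp near-floor pixels to the floor depth
#'
#' Every non-null pixel whose depth is within `floor_band` mm of
#' `max_height` is set to `max_height`, so carpet texture, sensor jitter
#' and body parts lying almost flat on the floor (e.g. a standing person's
#' feet) are absorbed into the floor surface.  Null (0) pixels pass through
#' untouched.
#'
#' @param frame A `depth_frame` in stage `DF`.
#' @param cfg A [system_config()].
#' @return A `depth_frame` in stage `DFm`.
#' @export
clamp_floor <- function(frame, cfg = system_config()) {
  assert_stage(frame, "DF", "clamp_floor")
  g <- unclass_grid(frame)
  sel <- g != 0L & (cfg$max_height - g) <= cfg$floor_band
  g[sel] <- as.integer(cfg$max_height)
  depth_frame(g, stage = "DFm", index = frame_index(frame))
}

#' Replace null pixels with the nearest valid value in the same row
#'
#' Sensor dropouts (value 0) are replaced row by row: each null run takes
#' the nearest valid depth to its left; a run at the start of a row takes
#' the first valid value to its right; a row with no valid pixel at all
#' becomes floor (`max_height`).  The operation is total (no zero survives)
#' and idempotent.
#'
#' @param frame A `depth_frame` in stage `DFm`.
#' @param cfg A [system_config()] (supplies `max_height` for all-null rows).
#' @return A `depth_frame` in stage `CF`.
#' @export
fill_nulls <- function(frame, cfg = system_config()) {
  assert_stage(frame, "DFm", "fill_nulls")
  g <- unclass_grid(frame)
  if (any(g == 0L)) {
    for (r in seq_len(nrow(g))) {
      v <- g[r, ]
      if (!any(v == 0L)) next
      valid <- which(v != 0L)
      if (length(valid) == 0L) {
        g[r, ] <- as.integer(cfg$max_height)
      } else {
        nulls <- which(v == 0L)
        src <- findInterval(nulls, valid)   # 0 => leading run
        src[src == 0L] <- 1L                # first valid value to the right
        g[r, nulls] <- v[valid][src]
      }
    }
  }
  depth_frame(g, stage = "CF", index = frame_index(frame))
}

#' Extract the foreground by depth-level slicing against a reference frame
#'
#' Pixels whose depth differs from the reference frame by more than
#' `th_person` mm belong to elements that were not in the empty scene
#' (people, moved objects); their depth is boosted by `gap_coeff` so that a
#' fixed Sobel threshold later separates them from static surfaces however
#' similar the raw depths are.  All other pixels are copied unchanged.
#'
#' @param cf Current frame (`depth_frame`, stage `CF`).
#' @param rf Reference frame (`depth_frame`, stage `RF`), same shape.
#' @param cfg A [system_config()].
#' @return A `depth_frame` in stage `FF`.
#' @export
compute_foreground <- function(cf, rf, cfg = system_config()) {
  assert_stage(cf, "CF", "compute_foreground")
  assert_stage(rf, "RF", "compute_foreground")
  if (!identical(dim(cf), dim(rf))) {
    stop("current and reference frames must have the same shape",
         call. = FALSE)
  }
  g <- unclass_grid(cf)
  r <- unclass_grid(rf)
  sel <- abs(g - r) > cfg$th_person
  g[sel] <- g[sel] + as.integer(cfg$gap_coeff)
  depth_frame(g, stage = "FF", index = frame_index(cf))
}

## 3x3 Sobel gradient magnitude |Gx| + |Gy| with replicated borders.
## The L1 combination keeps integer exactness; th_sobel is calibrated to it.
sobel_magnitude <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  p <- g[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]  # replicate edges
  rr <- seq_len(nr) + 1L; cc <- seq_len(nc) + 1L
  nw <- p[rr - 1L, cc - 1L]; no <- p[rr - 1L, cc]; ne <- p[rr - 1L, cc + 1L]
  we <- p[rr, cc - 1L];                         ea <- p[rr, cc + 1L]
  sw <- p[rr + 1L, cc - 1L]; so <- p[rr + 1L, cc]; se <- p[rr + 1L, cc + 1L]
  gx <- (ne + 2 * ea + se) - (nw + 2 * we + sw)
  gy <- (sw + 2 * so + se) - (nw + 2 * no + ne)
  abs(gx) + abs(gy)
}

#' Carve object boundaries to the floor level
#'
#' Pixels whose Sobel gradient magnitude reaches `th_sobel` are object
#' bounds; they are set to `max_height` so touching elements become
#' separable at the super-pixel stage.  Because foreground pixels were
#' boosted by `gap_coeff`, the person/object boundary always exceeds the
#' threshold even when raw depths are nearly equal.
#'
#' @param ff A `depth_frame` in stage `FF`.
#' @param cfg A [system_config()].
#' @return A `depth_frame` in stage `FFSobel`.
#' @export
carve_edges <- function(ff, cfg = system_config()) {
  assert_stage(ff, "FF", "carve_edges")
  g <- unclass_grid(ff)
  mag <- sobel_magnitude(g)
  g[mag >= cfg$th_sobel] <- as.integer(cfg$max_height)
  depth_frame(g, stage = "FFSobel", index = frame_index(ff))
}

#' Binarize a carved frame into the super-pixel occupancy grid
#'
#' The frame is tiled into `block_h` x `block_w` pixel blocks (6x8 for
#' 240x320, giving a 40x40 grid).  A super-pixel is occupied (1) iff every
#' pixel of its block differs from `max_height`; a single floor pixel
#' empties the cell.
#'
#' @param fs A `depth_frame` in stage `FFSobel`.
#' @param cfg A [system_config()].
#' @return A `super_pixel_frame`: binary integer matrix with attribute
#'   `source_index`.
#' @export
superpixelize <- function(fs, cfg = system_config()) {
  assert_stage(fs, "FFSobel", "superpixelize")
  g <- unclass_grid(fs)
  nr <- nrow(g); nc <- ncol(g)
  if (nr %% cfg$block_h != 0 || nc %% cfg$block_w != 0) {
    stop("frame dimensions not divisible by the super-pixel block size",
         call. = FALSE)
  }
  occ <- g != as.integer(cfg$max_height)
  gr <- nr %/% cfg$block_h; gc <- nc %/% cfg$block_w
  # block sums via aggregation matrices: S = A %*% occ %*% B
  a <- matrix(0, gr, nr); a[cbind(rep(seq_len(gr), each = cfg$block_h),
                                  seq_len(nr))] <- 1
  b <- matrix(0, nc, gc); b[cbind(seq_len(nc),
                                  rep(seq_len(gc), each = cfg$block_w))] <- 1
  s <- a %*% occ %*% b
  grid <- matrix(as.integer(s == cfg$block_h * cfg$block_w), gr, gc)
  structure(grid, source_index = frame_index(fs),
            class = c("super_pixel_frame", "matrix", "array"))
}

#' @export
print.super_pixel_frame <- function(x, ...) {
  cat(sprintf("<super_pixel_frame %dx%d, %d occupied>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Capture the reference frame of the empty scene
#'
#' The reference frame is the pixel-wise median of the first `n` current
#' frames, captured while no person is in the scene (the caller's
#' responsibility).  It is static for a whole run: the background is never
#' updated afterwards.
#'
#' @param frames List of `depth_frame`s in stage `CF`.
#' @param n Number of leading frames to use (default: all supplied).
#' @return A `depth_frame` in stage `RF`.
#' @export
capture_reference <- function(frames, n = length(frames)) {
  if (n < 1 || length(frames) < n) {
    stop("capture_reference() needs at least one CF frame", call. = FALSE)
  }
  frames <- frames[seq_len(n)]
  for (f in frames) assert_stage(f, "CF", "capture_reference")
  if (n == 1) return(restage(frames[[1]], "RF"))
  arr <- vapply(frames, unclass_grid,
                matrix(0L, nrow(frames[[1]]), ncol(frames[[1]])))
  med <- apply(arr, c(1, 2), median)
  depth_frame(round(med), stage = "RF", index = frame_index(frames[[1]]))
}
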