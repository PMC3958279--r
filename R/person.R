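## Eight scan directions as (dx, dy) pixel steps; x = column, y = row.
## North is up in the image (decreasing row).
DIRECTIONS <- list(
  N  = c(0L, -1L), NE = c(1L, -1L), E = c(1L, 0L), SE = c(1L, 1L),
  S  = c(0L,  1L), SW = c(-1L, 1L), W = c(-1L, 0L), NW = c(-1L, -1L)
)
## Opposite pairs summed into the four principal extents.
DIRECTION_PAIRS <- list(
  vertical   = c("N", "S"),
  diag_ne_sw = c("NE", "SW"),
  horizontal = c("E", "W"),
  diag_se_nw = c("SE", "NW")
)

#' Central super-pixel of a blob
#'
#' The blob member closest (Euclidean) to the mean of the member
#' coordinates; keeping the point on the blob itself keeps the tracking
#' anchor inside the subject.  Ties break to the smallest row, then the
#' smallest column.
#'
#' @param cells Two-column matrix or data frame of member coordinates
#'   (`x` = column, `y` = row).
#' @return Named integer vector `c(x, y)`.
#' @export
central_superpixel <- function(cells) {
  cells <- as.matrix(cells[, c("x", "y"), drop = FALSE])
  if (nrow(cells) == 0L) stop("empty blob", call. = FALSE)
  mx <- mean(cells[, "x"]); my <- mean(cells[, "y"])
  d2 <- (cells[, "x"] - mx)^2 + (cells[, "y"] - my)^2
  best <- which(d2 == min(d2))
  if (length(best) > 1L) {
    best <- best[order(cells[best, "y"], cells[best, "x"])][1L]
  }
  c(x = as.integer(cells[best, "x"]), y = as.integer(cells[best, "y"]))
}

## Pixel at the centre of a super-pixel's block (8x6 pixels by default).
superpixel_center_pixel <- function(sp, cfg = system_config()) {
  c(x = as.integer((sp[["x"]] - 1L) * cfg$block_w + ceiling(cfg$block_w / 2)),
    y = as.integer((sp[["y"]] - 1L) * cfg$block_h + ceiling(cfg$block_h / 2)))
}

## Super-pixel containing a pixel.
pixel_to_superpixel <- function(px, cfg = system_config()) {
  c(x = as.integer(ceiling(px[["x"]] / cfg$block_w)),
    y = as.integer(ceiling(px[["y"]] / cfg$block_h)))
}

## Logical pixel mask (frame-sized) of a blob's super-pixel footprint.
blob_footprint <- function(cells, cfg = system_config(),
                           nrow_px = cfg$frame_height,
                           ncol_px = cfg$frame_width) {
  m <- matrix(FALSE, nrow_px, ncol_px)
  cells <- as.matrix(cells[, c("x", "y"), drop = FALSE])
  for (i in seq_len(nrow(cells))) {
    rows <- (cells[i, "y"] - 1L) * cfg$block_h + seq_len(cfg$block_h)
    cols <- (cells[i, "x"] - 1L) * cfg$block_w + seq_len(cfg$block_w)
    m[rows, cols] <- TRUE
  }
  m
}

#' Peak (head) point of a blob
#'
#' Finds the blob pixel nearest the sensor (minimum depth, i.e. maximum
#' height) and returns the rounded centroid of the blob pixels lying within
#' a planar radius (`peak_radius`, mm, converted to pixels at the peak's
#' depth) and a depth window (`peak_depth_window`, mm) of that minimum.
#' Averaging over the head cap instead of taking the raw minimum makes the
#' point robust to single-pixel noise; for a human blob it sits near the
#' centre of the head.  The result always lies on the blob footprint.
#'
#' @param cells Blob cells (super-pixel coordinates, columns `x`, `y`).
#' @param cf Current frame (`depth_frame`, stage `CF` or `RF`).
#' @param cfg A [system_config()].
#' @return Named integer vector `c(x, y)` in pixel coordinates.
#' @export
peak_point <- function(cells, cf, cfg = system_config()) {
  cells <- as.matrix(cells[, c("x", "y"), drop = FALSE])
  if (nrow(cells) == 0L) stop("empty blob", call. = FALSE)
  assert_stage(cf, c("CF", "RF"), "peak_point")
  g <- unclass_grid(cf)
  mask <- blob_footprint(cells, cfg, nrow(g), ncol(g))
  depths <- ifelse(mask, g, NA_integer_)
  dmin <- min(depths, na.rm = TRUE)
  peak <- which(depths == dmin, arr.ind = TRUE)[1L, ]   # first row-major tie
  # planar radius in pixels at the peak's depth (elliptical: the per-pixel
  # footprint differs along x and y)
  rx <- cfg$peak_radius / mm_per_pixel(dmin, "horizontal", cfg)
  ry <- cfg$peak_radius / mm_per_pixel(dmin, "vertical", cfg)
  sel <- which(!is.na(depths) & depths - dmin <= cfg$peak_depth_window,
               arr.ind = TRUE)
  dx <- (sel[, "col"] - peak[["col"]]) / rx
  dy <- (sel[, "row"] - peak[["row"]]) / ry
  sel <- sel[dx^2 + dy^2 <= 1, , drop = FALSE]
  mp <- c(x = as.integer(round(mean(sel[, "col"]))),
          y = as.integer(round(mean(sel[, "row"]))))
  if (!mask[mp[["y"]], mp[["x"]]]) {
    # snap to the nearest footprint pixel (rounding can leave a concave blob)
    cand <- which(mask, arr.ind = TRUE)
    d2 <- (cand[, "col"] - mp[["x"]])^2 + (cand[, "row"] - mp[["y"]])^2
    best <- which(d2 == min(d2))
    best <- best[order(cand[best, "row"], cand[best, "col"])][1L]
    mp <- c(x = as.integer(cand[best, "col"]), y = as.integer(cand[best, "row"]))
  }
  mp
}

#' Scan the depth field in the eight cardinal directions
#'
#' From a starting pixel, steps of one pixel are taken towards N, NE, E,
#' SE, S, SW, W, NW until the frame border; the depth difference between
#' consecutive pixels is recorded for each step.  These consecutive
#' differences drive all three anthropometric checks.
#'
#' @param cf Current frame (`depth_frame`, stage `CF`).
#' @param mp Starting pixel, named vector `c(x, y)`.
#' @return A `directional_scan`: list with `depth` (depth at `mp`, mm) and
#'   `diffs`, a named list of per-direction difference vectors (mm, signed;
#'   positive = dropping away from the sensor target, i.e. surface farther
#'   than the previous pixel).
#' @export
directional_scan <- function(cf, mp) {
  assert_stage(cf, c("CF", "RF"), "directional_scan")
  g <- unclass_grid(cf)
  nr <- nrow(g); nc <- ncol(g)
  x0 <- mp[["x"]]; y0 <- mp[["y"]]
  if (x0 < 1 || x0 > nc || y0 < 1 || y0 > nr) {
    stop("mp outside the frame", call. = FALSE)
  }
  diffs <- lapply(DIRECTIONS, function(d) {
    nx <- if (d[1] > 0) (nc - x0) else if (d[1] < 0) (x0 - 1L) else NA_integer_
    ny <- if (d[2] > 0) (nr - y0) else if (d[2] < 0) (y0 - 1L) else NA_integer_
    n_steps <- min(nx, ny, na.rm = TRUE)
    if (n_steps == 0L) return(numeric(0))
    xs <- x0 + d[1] * (0:n_steps)
    ys <- y0 + d[2] * (0:n_steps)
    diff(g[cbind(ys, xs)])
  })
  structure(list(depth = g[y0, x0], diffs = diffs),
            class = "directional_scan")
}

#' @export
print.directional_scan <- function(x, ...) {
  cat(sprintf("<directional_scan depth=%d mm, steps: %s>\n", x$depth,
              paste(names(x$diffs), lengths(x$diffs), sep = "=",
                    collapse = " ")))
  invisible(x)
}

## Per-direction pixel distance to the first single step dropping by at
## least half the depth at the origin (the head-to-ground silhouette step);
## the border distance if never met.
ground_gap_distances <- function(scan, depth_at_mp = scan$depth) {
  vapply(scan$diffs, function(d) {
    k <- which(d >= depth_at_mp / 2)
    if (length(k)) k[1L] else length(d)
  }, numeric(1))
}

ground_gap_met <- function(scan, depth_at_mp = scan$depth) {
  vapply(scan$diffs, function(d) any(d >= depth_at_mp / 2), logical(1))
}

#' Head-ground gap check
#'
#' True iff in some direction a single consecutive-pixel step drops by at
#' least half the depth at the starting point: the silhouette step from the
#' head down to the floor, which low furniture cannot produce.
#'
#' @param scan A [directional_scan()].
#' @param depth_at_mp Depth at the scan origin in mm (defaults to the
#'   scan's own).
#' @return Logical scalar.
#' @export
head_ground_gap <- function(scan, depth_at_mp = scan$depth) {
  any(ground_gap_met(scan, depth_at_mp))
}

## Per-direction pixel distance at which the cumulative drop from the scan
## origin first lands inside [lo, hi] (head-over-shoulder height); NA if the
## drop skips the window or never reaches it.
shoulder_gap_distances <- function(scan, lo, hi) {
  vapply(scan$diffs, function(d) {
    cum <- cumsum(d)
    k <- which(cum >= lo)
    if (length(k) && cum[k[1L]] <= hi) k[1L] else NA_real_
  }, numeric(1))
}

#' Head-shoulder gap check
#'
#' Counts the directions in which the cumulative depth drop from the peak
#' point first lands inside the configured head height window
#' (`head_drop_range`, default 200-300 mm: the head-over-shoulder height of
#' an adult) before exceeding it.  A drop straight past the window (e.g.
#' head to floor with no shoulder underneath) does not count.  The person
#' check requires at least `min_drop_directions` such directions.
#'
#' @param scan A [directional_scan()].
#' @param cfg A [system_config()].
#' @return Integer: number of directions (0-8) meeting the condition.
#' @export
head_shoulder_gap <- function(scan, cfg = system_config()) {
  sum(!is.na(shoulder_gap_distances(scan, cfg$head_drop_range[1],
                                    cfg$head_drop_range[2])))
}

## Real-world length in mm of one pixel step at depth d, per axis.
mm_per_pixel <- function(d, axis, cfg = system_config()) {
  switch(axis,
    horizontal = 2 * d * tan(cfg$fov_half_x * pi / 180) / cfg$frame_width,
    vertical   = 2 * d * tan(cfg$fov_half_y * pi / 180) / cfg$frame_height,
    stop("axis must be horizontal or vertical", call. = FALSE)
  )
}

#' Convert a pixel segment to a real-world length
#'
#' Pinhole conversion at depth `d`: the half field of view subtends
#' `b = d * tan(fov_half)` mm over half the frame width, so a segment of
#' `wp` pixels parallel to an axis measures `2 * b * wp / n_pixels` mm.  A
#' diagonal segment (where `wp` counts diagonal steps, each advancing one
#' row and one column) combines the two axis terms by Pythagoras.
#'
#' @param wp Segment length in pixels (diagonal: number of diagonal steps).
#' @param d Depth of the segment in mm (> 0).
#' @param axis `"horizontal"`, `"vertical"` or `"diagonal"`.
#' @param cfg A [system_config()].
#' @return Length in mm.
#' @examples
#' pixel_to_mm(320, 3000, "horizontal")  # full frame width at the floor
#' @export
pixel_to_mm <- function(wp, d, axis = c("horizontal", "vertical", "diagonal"),
                        cfg = system_config()) {
  axis <- match.arg(axis)
  if (any(d <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(wp < 0)) stop("pixel length must be non-negative", call. = FALSE)
  switch(axis,
    horizontal = wp * mm_per_pixel(d, "horizontal", cfg),
    vertical   = wp * mm_per_pixel(d, "vertical", cfg),
    diagonal   = sqrt((wp * mm_per_pixel(d, "horizontal", cfg))^2 +
                      (wp * mm_per_pixel(d, "vertical", cfg))^2)
  )
}

#' Head extents through the peak point
#'
#' For each direction the head boundary is the pixel distance at which
#' either depth-gap condition (head-ground single step, or head-shoulder
#' cumulative drop) is first verified; directions meeting neither take the
#' distance from the peak point to the frame border, which pushes the
#' corresponding extent out of range for blobs that are not head-like.
#' Opposite directions are summed into four segments crossing the peak
#' point (N+S, NE+SW, E+W, SE+NW) and converted to mm at the peak's depth.
#'
#' @param scan A [directional_scan()].
#' @param d Depth at the peak point in mm (defaults to the scan's own).
#' @param cfg A [system_config()].
#' @return Named numeric vector of the four extents in mm (`vertical`,
#'   `diag_ne_sw`, `horizontal`, `diag_se_nw`).
#' @export
head_dimensions <- function(scan, d = scan$depth, cfg = system_config()) {
  borders <- lengths(scan$diffs)
  dg <- ground_gap_distances(scan, d)
  ds <- shoulder_gap_distances(scan, cfg$head_drop_range[1],
                               cfg$head_drop_range[2])
  extent <- pmin(dg, ds, borders, na.rm = TRUE)
  vapply(names(DIRECTION_PAIRS), function(pair) {
    dirs <- DIRECTION_PAIRS[[pair]]
    wp <- sum(extent[dirs])
    axis <- switch(pair, vertical = "vertical", horizontal = "horizontal",
                   "diagonal")
    pixel_to_mm(wp, d, axis, cfg)
  }, numeric(1))
}

head_dimensions_pass <- function(dims, cfg) {
  all(dims >= cfg$head_diag_range[1]) && all(dims <= cfg$head_diag_range[2]) &&
    max(dims) / min(dims) <= cfg$head_comparability_ratio
}

#' Decide whether a blob is a human subject
#'
#' Runs the three anthropometric checks from the blob's peak point: a
#' head-ground silhouette step of at least half the head depth in some
#' direction, a head-shoulder drop inside `head_drop_range` in at least
#' `min_drop_directions` directions, and four head extents inside
#' `head_diag_range` that are mutually comparable.  All three must pass.
#'
#' @param cells Blob cells (super-pixel coordinates, columns `x`, `y`).
#' @param cf Current frame (`depth_frame`, stage `CF`).
#' @param cfg A [system_config()].
#' @return Logical scalar.
#' @export
is_person <- function(cells, cf, cfg = system_config()) {
  cells <- as.matrix(cells[, c("x", "y"), drop = FALSE])
  if (nrow(cells) == 0L) stop("empty blob", call. = FALSE)
  mp <- peak_point(cells, cf, cfg)
  scan <- directional_scan(cf, mp)
  if (!head_ground_gap(scan)) return(FALSE)
  if (head_shoulder_gap(scan, cfg) < cfg$min_drop_directions) return(FALSE)
  head_dimensions_pass(head_dimensions(scan, scan$depth, cfg), cfg)
}

#' Anchor points of a blob
#'
#' Computes the four anchor coordinates stored per tracked element: the
#' central super-pixel `scp` and its pixel-level centre `cp`, and the peak
#' (head) point `mp` with its super-pixel equivalent `smp`.
#'
#' @param cells Blob cells (super-pixel coordinates, columns `x`, `y`).
#' @param cf Current frame (`depth_frame`, stage `CF`).
#' @param cfg A [system_config()].
#' @return Named list with integer `c(x, y)` vectors `cp`, `scp`, `mp`,
#'   `smp`.
#' @export
body_points <- function(cells, cf, cfg = system_config()) {
  scp <- central_superpixel(cells)
  mp <- peak_point(cells, cf, cfg)
  list(cp = superpixel_center_pixel(scp, cfg), scp = scp,
       mp = mp, smp = pixel_to_superpixel(mp, cfg))
}
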