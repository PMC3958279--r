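#' Scene specifications for the synthetic depth-scene simulator
#'
#' A scene is a flat floor `ceiling` mm under a downward-looking sensor,
#' axis-aligned furniture slabs, and human actors with explicit head and
#' shoulder geometry.  Planar coordinates are mm on the floor plane, origin
#' directly under the sensor, `x` increasing with image columns and `y`
#' with image rows.  Everything is deterministic given the spec and a seed.
#'
#' @param furniture List of [sim_furniture()] slabs.
#' @param actors List of [sim_actor()]s.
#' @param ceiling Sensor height above the floor in mm.
#' @param null_rate Fraction of pixels per frame turned into sensor
#'   dropouts (value 0).
#' @param noise_mm Half-width of the additive uniform integer depth noise
#'   in mm (0 disables it).
#' @param seed Base seed for per-frame noise and dropout draws.
#' @param duration Sequence length in seconds.
#' @param fps Frame rate in Hz.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(furniture = list(), actors = list(), ceiling = 3000,
                       null_rate = 0, noise_mm = 0, seed = 1L,
                       duration = 1, fps = 30) {
  stopifnot(null_rate >= 0, null_rate < 1, ceiling > 0)
  for (a in actors) {
    if (a$height >= ceiling) stop("actor taller than the ceiling", call. = FALSE)
  }
  structure(list(furniture = furniture, actors = actors, ceiling = ceiling,
                 null_rate = null_rate, noise_mm = noise_mm,
                 seed = as.integer(seed), duration = duration, fps = fps),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param x,y Slab centre on the floor plane (mm).
#' @param w,d Slab width (along x) and depth (along y) in mm.
#' @param h Slab top height above the floor in mm.
#' @export
sim_furniture <- function(x, y, w, d, h) {
  list(x = x, y = y, w = w, d = d, h = h)
}

#' @rdname scene_spec
#' @param trajectory Data frame of waypoints `t` (s), `x`, `y` (mm);
#'   position is linearly interpolated and held constant outside the span.
#' @param height Standing height (head apex) in mm.
#' @param head_diam Head diameter in mm.
#' @param breadth Shoulder breadth in mm (rendered along y; actors walk
#'   facing along x).
#' @param shoulder_drop Head-over-shoulder height in mm.
#' @param torso_depth Front-to-back torso extent in mm (along x).
#' @param fall Optional fall interval `c(start, end)` in seconds during
#'   which the actor lies prone.
#' @param prone_offset Planar displacement `c(dx, dy)` of the prone body
#'   centre relative to the standing position at the start of the fall.
#' @param prone_axis Axis of the lying body, `"x"` or `"y"`.
#' @param prone_len Body length when lying, in mm.
#' @param prone_thickness Body thickness when lying, in mm (kept below the
#'   400 mm fall rule so a settled fall is detectable by construction).
#' @param transition Duration in seconds of the falling / rising motion.
#' @param arm_span When non-`NULL`, the actor holds both arms outstretched
#'   (renders the U-shaped silhouette); value is the total span in mm.
#' @export
sim_actor <- function(trajectory, height = 1700, head_diam = 250,
                      breadth = 450, shoulder_drop = 250, torso_depth = 300,
                      fall = NULL, prone_offset = c(0, 0), prone_axis = "x",
                      prone_len = 1650, prone_thickness = 350,
                      transition = 0.4, arm_span = NULL) {
  stopifnot(is.data.frame(trajectory), all(c("t", "x", "y") %in%
                                             names(trajectory)))
  list(trajectory = trajectory, height = height, head_diam = head_diam,
       breadth = breadth, shoulder_drop = shoulder_drop,
       torso_depth = torso_depth, fall = fall, prone_offset = prone_offset,
       prone_axis = prone_axis, prone_len = prone_len,
       prone_thickness = prone_thickness, transition = transition,
       arm_span = arm_span)
}

## Interpolated actor position at time t (constant outside the waypoints).
actor_position <- function(actor, t) {
  tr <- actor$trajectory
  if (nrow(tr) == 1L) return(c(x = tr$x[1], y = tr$y[1]))
  c(x = approx(tr$t, tr$x, xout = t, rule = 2)$y,
    y = approx(tr$t, tr$y, xout = t, rule = 2)$y)
}

## Posture of an actor at time t: upright / falling / prone / rising,
## with the motion fraction alpha in [0, 1] (1 = fully prone).
actor_phase <- function(actor, t) {
  if (is.null(actor$fall)) return(list(phase = "upright", alpha = 0))
  t1 <- actor$fall[1]; t2 <- actor$fall[2]; tt <- actor$transition
  if (t < t1 - tt) list(phase = "upright", alpha = 0)
  else if (t < t1) list(phase = "falling", alpha = (t - (t1 - tt)) / tt)
  else if (t <= t2) list(phase = "prone", alpha = 1)
  else if (t <= t2 + tt) list(phase = "rising", alpha = 1 - (t - t2) / tt)
  else list(phase = "upright", alpha = 0)
}

## Surfaces (slabs and spheres) composing an actor at time t.
actor_surfaces <- function(actor, t) {
  pos <- actor_position(actor, t)
  ph <- actor_phase(actor, t)
  px <- pos[["x"]]; py <- pos[["y"]]
  if (ph$alpha == 0) {
    sh <- actor$height - actor$shoulder_drop
    surfs <- list(
      list(type = "slab", x1 = px - actor$torso_depth / 2,
           x2 = px + actor$torso_depth / 2,
           y1 = py - actor$breadth / 2, y2 = py + actor$breadth / 2, h = sh),
      list(type = "disk", xc = px, yc = py, r = actor$breadth * 0.3, h = sh),
      list(type = "sphere", xc = px, yc = py,
           hc = actor$height - actor$head_diam / 2, r = actor$head_diam / 2)
    )
    if (!is.null(actor$arm_span)) {
      half <- actor$arm_span / 2
      surfs <- c(surfs, list(
        list(type = "slab", x1 = px - half - 60, x2 = px - half + 60,
             y1 = py - 750, y2 = py - 150, h = sh),
        list(type = "slab", x1 = px + half - 60, x2 = px + half + 60,
             y1 = py - 750, y2 = py - 150, h = sh),
        list(type = "slab", x1 = px - half - 60, x2 = px + half + 60,
             y1 = py - 150, y2 = py + 150, h = sh)
      ))
    }
    surfs
  } else {
    # falling / prone / rising: one slab morphing between the upright
    # torso footprint (top at head height) and the lying body
    a <- ph$alpha
    cx <- px + a * actor$prone_offset[1]
    cy <- py + a * actor$prone_offset[2]
    if (actor$prone_axis == "x") {
      lx <- actor$torso_depth + a * (actor$prone_len - actor$torso_depth)
      ly <- actor$breadth
    } else {
      lx <- actor$torso_depth
      ly <- actor$breadth + a * (actor$prone_len - actor$breadth)
    }
    top <- actor$height + a * (actor$prone_thickness - actor$height)
    list(list(type = "slab", x1 = cx - lx / 2, x2 = cx + lx / 2,
              y1 = cy - ly / 2, y2 = cy + ly / 2, h = top))
  }
}

## Body-top height (mm above floor) reported in the ground truth.
actor_top_height <- function(actor, t) {
  ph <- actor_phase(actor, t)
  actor$height + ph$alpha * (actor$prone_thickness - actor$height)
}

## z-buffer one surface into `depth` (matrix of mm), returning the new
## buffer.  Perspective: at depth z the ray through pixel (r, c) hits the
## plane at x = z * tan(fov_x) * u_c, y = z * tan(fov_y) * v_r.
render_surface <- function(depth, surf, ceiling, u, v, tanx, tany) {
  if (surf$type %in% c("slab", "disk")) {
    z <- ceiling - surf$h
    if (z <= 0) stop("surface above the sensor", call. = FALSE)
    xs <- z * tanx * u
    ys <- z * tany * v
    if (surf$type == "slab") {
      mask <- outer(ys >= surf$y1 & ys <= surf$y2,
                    xs >= surf$x1 & xs <= surf$x2, `&`)
      depth[mask] <- pmin(depth[mask], z)
    } else {
      mask <- outer((ys - surf$yc)^2, (xs - surf$xc)^2, `+`) <= surf$r^2
      depth[mask] <- pmin(depth[mask], z)
    }
  } else if (surf$type == "sphere") {
    z0 <- ceiling - surf$hc
    xs <- z0 * tanx * u
    ys <- z0 * tany * v
    rho2 <- outer((ys - surf$yc)^2, (xs - surf$xc)^2, `+`)
    mask <- rho2 <= surf$r^2
    if (any(mask)) {
      zz <- ceiling - (surf$hc + sqrt(surf$r^2 - rho2[mask]))
      depth[mask] <- pmin(depth[mask], zz)
    }
  } else {
    stop("unknown surface type: ", surf$type, call. = FALSE)
  }
  depth
}

#' Render one synthetic depth frame
#'
#' Perspective projection with the sensor's half field-of-view angles;
#' each pixel takes the depth (mm) of the nearest surface along its ray,
#' the floor by default.  Actors outside the field of view are simply
#' absent.  Noise and dropouts are *not* applied here (see
#' [inject_nulls()] and [make_scenario()]), so rendering is exactly
#' deterministic.
#'
#' @param spec A [scene_spec()].
#' @param t Time in seconds.
#' @param index Frame index to tag the output with.
#' @param cfg A [system_config()] (frame geometry and angles).
#' @return List with `frame` (a `depth_frame`, stage `DF`), `truth` (one
#'   tibble row per actor: `actor`, `center_x`, `center_y` in pixels,
#'   `height_mm`, `fallen`, `visible`) and `masks` (list of per-actor
#'   logical pixel masks).
#' @export
render_frame <- function(spec, t, index = 1L, cfg = system_config()) {
  nr <- cfg$frame_height; nc <- cfg$frame_width
  tanx <- tan(cfg$fov_half_x * pi / 180)
  tany <- tan(cfg$fov_half_y * pi / 180)
  u <- (2 * seq_len(nc) - nc - 1) / nc
  v <- (2 * seq_len(nr) - nr - 1) / nr
  depth <- matrix(spec$ceiling, nr, nc)
  for (f in spec$furniture) {
    depth <- render_surface(depth, list(type = "slab",
                                        x1 = f$x - f$w / 2, x2 = f$x + f$w / 2,
                                        y1 = f$y - f$d / 2, y2 = f$y + f$d / 2,
                                        h = f$h),
                            spec$ceiling, u, v, tanx, tany)
  }
  actor_buffers <- lapply(spec$actors, function(a) {
    buf <- matrix(spec$ceiling, nr, nc)
    for (s in actor_surfaces(a, t)) {
      buf <- render_surface(buf, s, spec$ceiling, u, v, tanx, tany)
    }
    buf
  })
  for (buf in actor_buffers) depth <- pmin(depth, buf)

  claimed <- matrix(FALSE, nr, nc)
  masks <- lapply(actor_buffers, function(buf) {
    m <- buf < spec$ceiling & buf == depth & !claimed
    claimed <<- claimed | m
    m
  })
  truth <- bind_rows(lapply(seq_along(spec$actors), function(i) {
    a <- spec$actors[[i]]
    pos <- actor_position(a, t)
    ph <- actor_phase(a, t)
    top <- actor_top_height(a, t)
    z <- spec$ceiling - top
    cx <- round((pos[["x"]] / (z * tanx) + 1) / 2 * nc)
    cy <- round((pos[["y"]] / (z * tany) + 1) / 2 * nr)
    fallen <- !is.null(a$fall) && t >= a$fall[1] && t <= a$fall[2]
    tibble(actor = i, center_x = cx, center_y = cy, height_mm = top,
           fallen = fallen, visible = any(masks[[i]]))
  }))
  list(frame = depth_frame(round(depth), stage = "DF", index = index),
       truth = truth, masks = masks)
}

#' Inject sensor dropouts into a frame
#'
#' Sets exactly `round(rate * n_pixels)` pixels to the null value 0, the
#' positions drawn without replacement from a generator seeded with
#' `seed`; the draw is reproducible and does not disturb the caller's
#' random-number state.
#'
#' @param frame A `depth_frame` (stage `DF`).
#' @param rate Dropout fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return The frame with dropouts applied (stage unchanged).
#' @export
inject_nulls <- function(frame, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(frame)
  g <- unclass_grid(frame)
  n <- round(rate * length(g))
  idx <- with_local_seed(seed, sample.int(length(g), n))
  g[idx] <- 0L
  depth_frame(g, stage = frame_stage(frame), index = frame_index(frame))
}

## Additive uniform integer noise in [-noise_mm, +noise_mm], seeded.
inject_noise <- function(frame, noise_mm, seed) {
  if (noise_mm == 0) return(frame)
  g <- unclass_grid(frame)
  eps <- with_local_seed(seed, {
    sample.int(2L * noise_mm + 1L, length(g), replace = TRUE) - noise_mm - 1L
  })
  g <- pmax(g + eps, 1L)
  depth_frame(g, stage = frame_stage(frame), index = frame_index(frame))
}

## Deterministic per-frame sub-seed below 2^31.
frame_seed <- function(seed, i, salt = 0L) {
  (as.numeric(seed) * 1009 + i * 97 + salt * 131071) %% 2147483647
}

#' Render a whole scenario
#'
#' Renders every frame of a [scene_spec()], applying depth noise and
#' dropouts with per-frame seeds derived from the spec's base seed.
#'
#' @param spec A [scene_spec()].
#' @param cfg A [system_config()].
#' @param keep_masks Keep the per-frame, per-actor pixel masks (memory
#'   heavy; off by default).
#' @return List with `spec`, `frames` (list of `depth_frame`s), `truth`
#'   (tibble with one row per frame and actor, `frame_index` column
#'   added) and, if requested, `masks`.
#' @export
render_scenario <- function(spec, cfg = system_config(), keep_masks = FALSE) {
  n <- round(spec$duration * spec$fps)
  frames <- vector("list", n)
  truth <- vector("list", n)
  masks <- if (keep_masks) vector("list", n) else NULL
  for (i in seq_len(n)) {
    t <- (i - 1) / spec$fps
    out <- render_frame(spec, t, index = i, cfg = cfg)
    f <- inject_noise(out$frame, spec$noise_mm, frame_seed(spec$seed, i, 1L))
    f <- inject_nulls(f, spec$null_rate, frame_seed(spec$seed, i, 2L))
    frames[[i]] <- f
    truth[[i]] <- mutate(out$truth, frame_index = i)
    if (keep_masks) masks[[i]] <- out$masks
  }
  res <- list(spec = spec, frames = frames, truth = bind_rows(truth))
  if (keep_masks) res$masks <- masks
  res
}

#' Canonical test scenarios
#'
#' Fixed scene layouts exercising the pipeline's behaviours end to end:
#'
#' * `simple_fall` — one person enters, walks to the centre, falls (no
#'   object contact), lies still, gets up and leaves; one desk far from
#'   the path.
#' * `complex_fall` — the person brushes a chair while walking, then falls
#'   against a desk so that the lying body touches the desk footprint.
#'   With a proper reference frame the person stays separable from the
#'   desk; without one their blobs merge and the fall is missed.
#' * `fusion_walk` — two persons walk towards each other among three
#'   furniture pieces, meet in shoulder contact (one merged blob), then
#'   separate.
#' * `outstretched_arms` — one static person with both arms extended: the
#'   U-shaped silhouette whose parts must be merged by the labeler's
#'   side-effect rule.
#' * `table1_seven_blobs` — seven disjoint static slabs laid out so the
#'   labeler discovers them in a fixed row-major order.
#'
#' @param name Scenario name.
#' @param seed Integer seed driving noise and dropouts.
#' @param cfg A [system_config()].
#' @param keep_masks See [render_scenario()].
#' @return See [render_scenario()].
#' @export
make_scenario <- function(name = c("simple_fall", "complex_fall",
                                   "fusion_walk", "outstretched_arms",
                                   "table1_seven_blobs"),
                          seed = 1L, cfg = system_config(),
                          keep_masks = FALSE) {
  name <- match.arg(name)
  spec <- switch(name,
    simple_fall = scene_spec(
      furniture = list(sim_furniture(1100, 550, 400, 400, 750)),
      actors = list(sim_actor(
        trajectory = data.frame(t = c(0, 2.2, 4.9, 6.0),
                                x = c(-1150, -150, -150, 1150),
                                y = c(50, 50, 50, 50)),
        fall = c(3.0, 4.3), prone_offset = c(-250, 0), prone_axis = "x")),
      null_rate = 0.005, noise_mm = 5, seed = seed, duration = 6.0),
    complex_fall = scene_spec(
      furniture = list(sim_furniture(650, 0, 700, 500, 750),
                       sim_furniture(-350, 450, 450, 450, 450)),
      actors = list(sim_actor(
        trajectory = data.frame(t = c(0, 2.4, 5.8, 7.0),
                                x = c(-1100, 100, 100, -1100),
                                y = c(50, 0, 0, 0)),
        fall = c(3.2, 5.2), prone_offset = c(-400, 0), prone_axis = "x")),
      null_rate = 0.005, noise_mm = 5, seed = seed, duration = 7.0),
    fusion_walk = scene_spec(
      furniture = list(sim_furniture(1050, 600, 500, 350, 750),
                       sim_furniture(-1050, 600, 450, 450, 450),
                       sim_furniture(0, -800, 500, 300, 600)),
      actors = list(
        sim_actor(trajectory = data.frame(t = c(0, 2.0, 3.4, 5.0),
                                          x = c(-1250, -145, -145, -1250),
                                          y = c(0, 0, 0, 0)),
                  height = 1700),
        sim_actor(trajectory = data.frame(t = c(0, 2.0, 3.4, 5.0),
                                          x = c(1250, 145, 145, 1250),
                                          y = c(0, 0, 0, 0)),
                  height = 1680)),
      null_rate = 0.005, noise_mm = 5, seed = seed, duration = 5.0),
    outstretched_arms = scene_spec(
      actors = list(sim_actor(
        trajectory = data.frame(t = c(0, 0.49, 0.5, 1.5),
                                x = c(-4000, -4000, 0, 0),
                                y = c(100, 100, 100, 100)),
        arm_span = 1300)),
      null_rate = 0, noise_mm = 0, seed = seed, duration = 1.5),
    table1_seven_blobs = {
      # seven disjoint clusters defined directly as super-pixel cells;
      # each is rendered as per-row slabs at a common height
      clusters <- list(
        list(c(4, 2, 2), c(5, 2, 2)),
        list(c(9, 8, 9), c(10, 7, 9)),
        list(c(11, 27, 29), c(12, 26, 29)),
        list(c(16, 7, 10)),
        list(c(18, 14, 16), c(19, 14, 16)),
        list(c(25, 20, 20), c(26, 20, 23)),
        list(c(31, 4, 6), c(32, 4, 6))
      )
      furn <- list()
      h <- 700; z <- 3000 - h
      tanx <- tan(cfg$fov_half_x * pi / 180)
      tany <- tan(cfg$fov_half_y * pi / 180)
      px_x <- function(p) z * tanx * (2 * p - cfg$frame_width - 1) /
        cfg$frame_width
      px_y <- function(p) z * tany * (2 * p - cfg$frame_height - 1) /
        cfg$frame_height
      for (cl in clusters) {
        for (rowspec in cl) {
          sy <- rowspec[1]; c1 <- rowspec[2]; c2 <- rowspec[3]
          # pixel extent of the cell range, plus a 2-pixel guard so the
          # Sobel carve (1-pixel erosion) leaves every block fully covered
          pc1 <- (c1 - 1) * cfg$block_w + 1 - 2
          pc2 <- c2 * cfg$block_w + 2
          pr1 <- (sy - 1) * cfg$block_h + 1 - 2
          pr2 <- sy * cfg$block_h + 2
          x1 <- px_x(pc1 - 0.4); x2 <- px_x(pc2 + 0.4)
          y1 <- px_y(pr1 - 0.4); y2 <- px_y(pr2 + 0.4)
          furn[[length(furn) + 1]] <-
            sim_furniture((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1, h)
        }
      }
      scene_spec(furniture = furn, null_rate = 0, noise_mm = 0, seed = seed,
                 duration = 0.2)
    })
  render_scenario(spec, cfg = cfg, keep_masks = keep_masks)
}
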