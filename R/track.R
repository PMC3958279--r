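#' Track registry
#'
#' Holds the anchor points of every tracked element: persons (blobs that
#' passed the anthropometric checks) and objects (everything else), each
#' with a stable id, the four anchor points, a count of consecutive
#' unmatched frames, and — for persons — the below-threshold latch used for
#' edge-triggered fall events.
#'
#' @return An empty `track_registry`.
#' @export
track_registry <- function() {
  pts <- tibble(id = integer(),
                cp_x = integer(), cp_y = integer(),
                scp_x = integer(), scp_y = integer(),
                mp_x = integer(), mp_y = integer(),
                smp_x = integer(), smp_y = integer(),
                missed = integer())
  structure(list(persons = mutate(pts, fallen = logical()),
                 objects = pts,
                 next_person = 1L, next_object = 1L),
            class = "track_registry")
}

#' @export
print.track_registry <- function(x, ...) {
  cat(sprintf("<track_registry: %d person(s), %d object(s)>\n",
              nrow(x$persons), nrow(x$objects)))
  invisible(x)
}

points_row <- function(id, bp) {
  tibble(id = as.integer(id),
         cp_x = bp$cp[["x"]], cp_y = bp$cp[["y"]],
         scp_x = bp$scp[["x"]], scp_y = bp$scp[["y"]],
         mp_x = bp$mp[["x"]], mp_y = bp$mp[["y"]],
         smp_x = bp$smp[["x"]], smp_y = bp$smp[["y"]],
         missed = 0L)
}

## TRUE for each registry row whose anchor super-pixel (x, y) lies in cells.
anchor_in_cells <- function(xs, ys, cells) {
  if (length(xs) == 0L) return(logical(0))
  key <- paste(cells[, "x"], cells[, "y"])
  paste(xs, ys) %in% key
}

#' Associate tracked elements with the blobs of a new frame
#'
#' Each person recognised in the previous frame is placed into the new
#' frame at its stored central super-pixel `scp`; the blob containing that
#' point carries the person on.  Objects are placed by their stored peak
#' super-pixel `smp`.  The result is one row per blob with the lists of
#' person and object ids found inside it.
#'
#' @param registry A [track_registry()] (state after the previous frame).
#' @param table A `blob_table` for the current frame.
#' @return Tibble with columns `blob` (object id in `table`), `pers`,
#'   `obj` (list-columns of ids), `n_pers`, `n_obj`.
#' @export
build_tracking_info <- function(registry, table) {
  ids <- blob_ids(table)
  rows <- lapply(ids, function(b) {
    cells <- blob_cells(table, b)
    p <- registry$persons$id[anchor_in_cells(registry$persons$scp_x,
                                             registry$persons$scp_y, cells)]
    o <- registry$objects$id[anchor_in_cells(registry$objects$smp_x,
                                             registry$objects$smp_y, cells)]
    tibble(blob = b, pers = list(p), obj = list(o),
           n_pers = length(p), n_obj = length(o))
  })
  if (length(rows) == 0L) {
    return(tibble(blob = integer(), pers = list(), obj = list(),
                  n_pers = integer(), n_obj = integer()))
  }
  bind_rows(rows)
}

#' Classify a tracking-info row
#'
#' Condition `A`: no known person and at most one known object (a lone
#' object, possibly new — candidate for person identification).  Condition
#' `B`: exactly one person and no object (plain tracking update).
#' Condition `C`: anything else — a fusion of several tracked elements into
#' one blob that must be split.
#'
#' @param n_pers,n_obj Counts from a tracking-info row.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classify_row <- function(n_pers, n_obj) {
  if (n_pers == 0 && n_obj <= 1) return("A")
  if (n_pers == 1 && n_obj == 0) return("B")
  "C"
}

#' Split a fused blob around its participants
#'
#' For each participating element, the blob is restricted to the cells
#' within a Chebyshev radius of the element's peak super-pixel (cells
#' inside several participants' radii go to the nearest peak, ties to the
#' earlier participant), the restriction is re-labeled with
#' [distinguish_objects()], and the component containing the peak is
#' returned as that participant's blob.
#'
#' @param cells Cells of the fused blob (columns `x`, `y`).
#' @param members Data frame with one row per participant: columns `smp_x`,
#'   `smp_y`.
#' @param radius Chebyshev radius in super-pixels.
#' @return List (one element per member) of cell matrices; a member whose
#'   peak cell is not inside the blob is an error.
#' @export
split_fusion <- function(cells, members, radius = 5) {
  cells <- as.matrix(cells[, c("x", "y"), drop = FALSE])
  if (nrow(members) < 1L) stop("no members to split around", call. = FALSE)
  inside <- anchor_in_cells(members$smp_x, members$smp_y, cells)
  if (!all(inside)) {
    stop("member peak super-pixel not inside the fused blob", call. = FALSE)
  }
  # Chebyshev distance of every cell to every member's peak
  cheb <- sapply(seq_len(nrow(members)), function(i) {
    pmax(abs(cells[, "x"] - members$smp_x[i]),
         abs(cells[, "y"] - members$smp_y[i]))
  })
  cheb <- matrix(cheb, nrow = nrow(cells))
  eucl <- sapply(seq_len(nrow(members)), function(i) {
    (cells[, "x"] - members$smp_x[i])^2 + (cells[, "y"] - members$smp_y[i])^2
  })
  eucl <- matrix(eucl, nrow = nrow(cells))
  eucl[cheb > radius] <- Inf        # outside the spatial range: discarded
  owner <- apply(eucl, 1L, function(e) {
    if (all(is.infinite(e))) NA_integer_ else which.min(e)
  })
  lapply(seq_len(nrow(members)), function(i) {
    sub <- cells[!is.na(owner) & owner == i, , drop = FALSE]
    if (nrow(sub) == 0L) return(sub)
    # re-label the restriction and keep the component holding the peak
    xr <- range(sub[, "x"]); yr <- range(sub[, "y"])
    m <- matrix(0L, yr[2] - yr[1] + 1L, xr[2] - xr[1] + 1L)
    m[cbind(sub[, "y"] - yr[1] + 1L, sub[, "x"] - xr[1] + 1L)] <- 1L
    tab <- distinguish_objects(m)
    tab$x <- tab$x + xr[1] - 1L
    tab$y <- tab$y + yr[1] - 1L
    own <- tab$oi[tab$x == members$smp_x[i] & tab$y == members$smp_y[i]]
    blob_cells(tab, own[1L])
  })
}

#' Update the track registry with the blobs of a new frame
#'
#' Runs the frame-to-frame association and handles each blob by its
#' condition: `A` blobs are checked with [is_person()] (promotion to a new
#' person id, or creation/update of an object); `B` blobs refresh the
#' tracked person's anchor points on the new shape; `C` blobs are split
#' with [split_fusion()] and every participant is re-anchored on its own
#' sub-blob.  Person identification is only attempted on blobs not already
#' carrying a person.  Elements unmatched for more than `track_grace`
#' consecutive frames are retired.
#'
#' @param registry A [track_registry()].
#' @param table A `blob_table` for the current frame.
#' @param cf The current frame (`depth_frame`, stage `CF`).
#' @param cfg A [system_config()].
#' @return The updated `track_registry`, with attribute `info` holding the
#'   tracking-info tibble (with the assigned condition per blob).
#' @export
update_tracks <- function(registry, table, cf, cfg = system_config()) {
  info <- build_tracking_info(registry, table)
  info$condition <- vapply(seq_len(nrow(info)), function(i) {
    classify_row(info$n_pers[i], info$n_obj[i])
  }, character(1))
  matched_p <- integer(); matched_o <- integer()

  for (i in seq_len(nrow(info))) {
    cells <- blob_cells(table, info$blob[i])
    cond <- info$condition[i]
    if (cond == "A") {
      bp <- body_points(cells, cf, cfg)
      if (is_person(cells, cf, cfg)) {
        # a (possibly brand-new) human subject: promote
        if (info$n_obj[i] == 1L) {
          registry$objects <-
            registry$objects[registry$objects$id != info$obj[[i]], ,
                             drop = FALSE]
        }
        registry$persons <- bind_rows(
          registry$persons,
          mutate(points_row(registry$next_person, bp), fallen = FALSE))
        matched_p <- c(matched_p, registry$next_person)
        registry$next_person <- registry$next_person + 1L
      } else if (info$n_obj[i] == 1L) {
        id <- info$obj[[i]]
        registry$objects[registry$objects$id == id, names(points_row(id, bp))] <-
          points_row(id, bp)
        matched_o <- c(matched_o, id)
      } else {
        registry$objects <- bind_rows(registry$objects,
                                      points_row(registry$next_object, bp))
        matched_o <- c(matched_o, registry$next_object)
        registry$next_object <- registry$next_object + 1L
      }
    } else if (cond == "B") {
      id <- info$pers[[i]]
      bp <- body_points(cells, cf, cfg)
      registry$persons[registry$persons$id == id, names(points_row(id, bp))] <-
        points_row(id, bp)
      matched_p <- c(matched_p, id)
    } else {
      # condition C: fusion — split around every tracked person's peak.
      # Objects do not take part in the split: an object inside a fused
      # blob keeps its stored anchors and is re-acquired once its peak
      # super-pixel falls in a plain condition-A blob again (or starves
      # past the grace period); re-anchoring static objects onto moving
      # fused cells would let stale tracks ride the person around.
      p_ids <- info$pers[[i]]
      members <- tibble(
        kind = rep("person", length(p_ids)), id = p_ids,
        smp_x = registry$persons$smp_x[match(p_ids, registry$persons$id)],
        smp_y = registry$persons$smp_y[match(p_ids, registry$persons$id)],
        scp_x = registry$persons$scp_x[match(p_ids, registry$persons$id)],
        scp_y = registry$persons$scp_y[match(p_ids, registry$persons$id)])
      # a person whose peak cell left the blob is re-seeded at its central
      # super-pixel (which is inside by construction of the association)
      key <- paste(cells[, "x"], cells[, "y"])
      out <- !(paste(members$smp_x, members$smp_y) %in% key)
      members$smp_x[out] <- members$scp_x[out]
      members$smp_y[out] <- members$scp_y[out]
      still_out <- !(paste(members$smp_x, members$smp_y) %in% key)
      members <- members[!still_out, , drop = FALSE]
      if (nrow(members) > 0L) {
        subs <- split_fusion(cells, members, cfg$fusion_split_radius)
        for (m in seq_len(nrow(members))) {
          sub <- subs[[m]]
          if (nrow(sub) == 0L) next
          id <- members$id[m]
          if (members$kind[m] == "person") {
            # the split output must be recognised again: a sub-blob that no
            # longer looks like a person (e.g. a body lying merged against
            # furniture) does not carry the track on; the person stays
            # unmatched and is retired after the grace period
            if (!is_person(sub, cf, cfg)) next
            bp <- body_points(sub, cf, cfg)
            registry$persons[registry$persons$id == id,
                             names(points_row(id, bp))] <- points_row(id, bp)
            matched_p <- c(matched_p, id)
          } else {
            bp <- body_points(sub, cf, cfg)
            registry$objects[registry$objects$id == id,
                             names(points_row(id, bp))] <- points_row(id, bp)
            matched_o <- c(matched_o, id)
          }
        }
      }
    }
  }

  # unmatched elements age and are eventually retired
  pu <- !(registry$persons$id %in% matched_p)
  registry$persons$missed[pu] <- registry$persons$missed[pu] + 1L
  registry$persons <- registry$persons[
    registry$persons$missed <= cfg$track_grace, , drop = FALSE]
  ou <- !(registry$objects$id %in% matched_o)
  registry$objects$missed[ou] <- registry$objects$missed[ou] + 1L
  registry$objects <- registry$objects[
    registry$objects$missed <= cfg$track_grace, , drop = FALSE]

  attr(registry, "info") <- info
  registry
}

#' Detect fall events for the tracked persons
#'
#' A person's height above the floor is `max_height` minus the depth read
#' at the central point `cp`.  A fall event is emitted when the height
#' drops strictly below `fall_threshold` (400 mm by default: the thickness
#' of a human body lying on the floor); the event is edge-triggered — one
#' event per excursion below the threshold, re-armed when the person rises
#' above it again.
#'
#' @param registry A [track_registry()] current for this frame.
#' @param cf The current frame (`depth_frame`, stage `CF`).
#' @param cfg A [system_config()].
#' @param frame Frame index recorded in the events.
#' @return List with the updated `registry` (below-threshold latches),
#'   `events` (tibble of new fall events) and `heights` (tibble with one
#'   row per tracked person: `frame_index`, `person_id`, `height_mm`,
#'   `below`).
#' @export
detect_fall <- function(registry, cf, cfg = system_config(), frame = 1L) {
  g <- unclass_grid(cf)
  # only persons matched in this frame have a valid central point; an
  # unmatched track's stale cp would read the floor
  cur <- registry$persons$missed == 0L
  p <- registry$persons[cur, , drop = FALSE]
  events <- empty_events()
  if (nrow(p) > 0L) {
    h <- cfg$max_height - g[cbind(p$cp_y, p$cp_x)]
    below <- h < cfg$fall_threshold
    new_fall <- below & !p$fallen
    registry$persons$fallen[cur] <- below
    if (any(new_fall)) {
      events <- tibble(frame_index = as.integer(frame),
                       person_id = p$id[new_fall],
                       height_above_floor = as.numeric(h[new_fall]))
    }
    heights <- tibble(frame_index = as.integer(frame), person_id = p$id,
                      height_mm = as.numeric(h), below = below)
  } else {
    heights <- tibble(frame_index = integer(), person_id = integer(),
                      height_mm = numeric(), below = logical())
  }
  list(registry = registry, events = events, heights = heights)
}

#' Initialise pipeline state
#'
#' @param rf Reference frame (`depth_frame`, stage `RF`).
#' @param cfg A [system_config()].
#' @return A `pipeline_state` carrying the reference frame, configuration
#'   and an empty [track_registry()].
#' @export
pipeline_state <- function(rf, cfg = system_config()) {
  assert_stage(rf, "RF", "pipeline_state")
  structure(list(rf = rf, cfg = cfg, registry = track_registry(),
                 frame = 0L),
            class = "pipeline_state")
}

#' Process one raw depth frame through the whole pipeline
#'
#' Runs floor clamping, null filling, foreground extraction against the
#' stored reference frame, edge carving, super-pixel binarization, blob
#' labeling, track update and fall detection, and advances the state.
#'
#' @param df A raw `depth_frame` (stage `DF`).
#' @param state A [pipeline_state()].
#' @return List with `state` (updated), `events`, `heights` (see
#'   [detect_fall()]), `info` (tracking info with conditions) and `blobs`
#'   (the frame's `blob_table`).
#' @export
process_frame <- function(df, state) {
  stopifnot(inherits(state, "pipeline_state"))
  cfg <- state$cfg
  state$frame <- state$frame + 1L
  cf <- fill_nulls(clamp_floor(df, cfg), cfg)
  ff <- compute_foreground(cf, state$rf, cfg)
  fs <- superpixelize(carve_edges(ff, cfg), cfg)
  table <- distinguish_objects(fs)
  state$registry <- update_tracks(state$registry, table, cf, cfg)
  res <- detect_fall(state$registry, cf, cfg, frame = state$frame)
  state$registry <- res$registry
  list(state = state, events = res$events, heights = res$heights,
       info = attr(state$registry, "info"), blobs = table)
}
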