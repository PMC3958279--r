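#' Scan one super-pixel row into object parts
#'
#' An object part (OP) is a maximal horizontal run of occupied cells; two
#' runs in the same row belong to separate parts if at least one empty cell
#' lies between them.  Parts are returned left to right, unclassified
#' (`oi = 0`).
#'
#' @param row Binary vector (one super-pixel row).
#' @return Tibble with columns `first`, `last` (column indexes, 1-based)
#'   and `oi`.
#' @examples
#' r <- integer(40); r[5:10] <- 1L; r[25:29] <- 1L
#' scan_row(r)
#' @export
scan_row <- function(row) {
  if (!all(row %in% c(0, 1))) stop("row must be binary", call. = FALSE)
  r <- rle(as.integer(row))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  tibble(first = starts[keep], last = ends[keep],
         oi = rep(0L, sum(keep)))
}

#' Match current-row object parts against the previous row
#'
#' Implements the bitwise-AND comparison between the compare vector of one
#' current part and the occupancy of the previous row: a part continues
#' every previous-row object whose columns it overlaps; no overlap means a
#' new object.
#'
#' @param current Tibble of current-row spans (`first`, `last`, ...).
#' @param previous Tibble of previous-row spans with assigned `oi`.
#' @return A list, one element per current span, of the distinct previous
#'   object ids overlapped (integer(0) for a new object), in first-overlap
#'   order.
#' @export
match_spans <- function(current, previous) {
  lapply(seq_len(nrow(current)), function(i) {
    hit <- previous$last >= current$first[i] &
      previous$first <= current$last[i]
    unique(previous$oi[hit])
  })
}

#' Assign object ids to one row of spans
#'
#' The single-row association step of the labeler: each current span takes
#' the id of the previous-row object it overlaps, a fresh id if it overlaps
#' none, and triggers a merge when it bridges several previously distinct
#' objects.  Exposed separately so the row-level worked states of the
#' procedure can be driven directly.
#'
#' @param current Tibble of current-row spans (`first`, `last`).
#' @param previous Tibble of previous-row spans with `first`, `last`, `oi`.
#' @param next_id First unused object id.
#' @return List with `oi` (integer vector of assigned ids, one per current
#'   span), `merges` (list of merged id groups) and `next_id`.
#' @examples
#' cur <- tibble::tibble(first = c(5L, 25L), last = c(10L, 29L))
#' prev <- tibble::tibble(first = c(6L, 26L), last = c(10L, 29L),
#'                        oi = c(2L, 3L))
#' assign_spans(cur, prev, next_id = 4L)$oi   # 2 3
#' @export
assign_spans <- function(current, previous, next_id = 1L) {
  oi <- integer(nrow(current))
  merges <- list()
  matches <- match_spans(current, previous)
  for (i in seq_len(nrow(current))) {
    ids <- matches[[i]]
    if (length(ids) == 0L) {
      oi[i] <- next_id
      next_id <- next_id + 1L
    } else if (length(ids) == 1L) {
      oi[i] <- ids
    } else {
      merges[[length(merges) + 1L]] <- sort(ids)
      oi[i] <- min(ids)
    }
  }
  list(oi = oi, merges = merges, next_id = next_id)
}

#' Label the occupied super-pixels of a frame into blobs
#'
#' Row-scan connected-component labeling: each row is split into object
#' parts, every part is matched against the previous row by column overlap,
#' and a part bridging several previously distinct objects (e.g. the torso
#' row under outstretched arms) merges them into one, keeping the smallest
#' id and recompacting the rest.  The resulting partition equals 4-connected
#' components; object ids are ordered by first occurrence in the row-major
#' scan.
#'
#' Works on any binary matrix, not only the 40x40 grid.
#'
#' @param fs A `super_pixel_frame` or plain binary matrix.
#' @return A `blob_table`: tibble with columns `oi` (object id), `x`
#'   (column), `y` (row) and `ord` (global discovery order), cells grouped
#'   by object in discovery order.
#' @export
distinguish_objects <- function(fs) {
  g <- if (inherits(fs, "super_pixel_frame")) unclass(fs) else fs
  if (!is.matrix(g) || !all(g %in% c(0, 1))) {
    stop("distinguish_objects() expects a binary matrix", call. = FALSE)
  }
  cells_x <- vector("list", 16L)   # per-object cell columns (grown on demand)
  cells_y <- vector("list", 16L)
  cells_s <- vector("list", 16L)   # global discovery sequence
  n_obj <- 0L
  seq_no <- 0L
  prev <- list(first = integer(), last = integer(), oi = integer())

  for (r in seq_len(nrow(g))) {
    rl <- rle(as.integer(g[r, ]))
    ends <- cumsum(rl$lengths)
    keep <- rl$values == 1L
    cur <- list(first = (ends - rl$lengths + 1L)[keep], last = ends[keep])
    n_spans <- length(cur$first)
    if (n_spans == 0L) {
      prev <- list(first = integer(), last = integer(), oi = integer())
      next
    }
    oi <- integer(n_spans)
    for (i in seq_len(n_spans)) {
      hit <- prev$last >= cur$first[i] & prev$first <= cur$last[i]
      ids <- unique(prev$oi[hit])
      if (length(ids) == 0L) {
        # no continuation: a new object starts here
        n_obj <- n_obj + 1L
        cells_x[[n_obj]] <- integer()
        cells_y[[n_obj]] <- integer()
        cells_s[[n_obj]] <- integer()
        id <- n_obj
      } else if (length(ids) == 1L) {
        id <- ids
      } else {
        # side effect: one part bridges several previously distinct
        # objects (outstretched arms); merge them under the smallest id,
        # recompact, and remap every live reference immediately
        keep <- min(ids)
        gone <- setdiff(ids, keep)
        ord_all <- order(c(cells_s[[keep]], unlist(cells_s[gone])))
        cells_x[[keep]] <- c(cells_x[[keep]], unlist(cells_x[gone]))[ord_all]
        cells_y[[keep]] <- c(cells_y[[keep]], unlist(cells_y[gone]))[ord_all]
        cells_s[[keep]] <- sort(c(cells_s[[keep]], unlist(cells_s[gone])))
        survivors <- setdiff(seq_len(n_obj), gone)
        remap <- integer(n_obj)
        remap[survivors] <- seq_along(survivors)
        remap[gone] <- remap[keep]   # references to merged ids follow keep
        cells_x <- cells_x[survivors]
        cells_y <- cells_y[survivors]
        cells_s <- cells_s[survivors]
        n_obj <- length(survivors)
        assigned <- oi > 0L
        oi[assigned] <- remap[oi[assigned]]
        if (length(prev$oi)) prev$oi <- remap[prev$oi]
        id <- remap[keep]
      }
      cols <- cur$first[i]:cur$last[i]
      k <- length(cols)
      cells_x[[id]] <- c(cells_x[[id]], cols)
      cells_y[[id]] <- c(cells_y[[id]], rep.int(r, k))
      cells_s[[id]] <- c(cells_s[[id]], seq_no + seq_len(k))
      seq_no <- seq_no + k
      oi[i] <- id
    }
    prev <- list(first = cur$first, last = cur$last, oi = oi)
  }

  if (n_obj == 0L) return(empty_blob_table())
  out <- bind_rows(lapply(seq_len(n_obj), function(id) {
    idx <- order(cells_s[[id]])
    tibble(oi = id, x = cells_x[[id]][idx], y = cells_y[[id]][idx],
           ord = cells_s[[id]][idx])
  }))
  new_blob_table(out)
}

empty_blob_table <- function() {
  new_blob_table(tibble(oi = integer(), x = integer(), y = integer(),
                        ord = integer()))
}

new_blob_table <- function(tbl) {
  class(tbl) <- c("blob_table", class(tbl))
  tbl
}

#' Merge blobs under one id
#'
#' Concatenates the cells of the given objects under the smallest id,
#' preserving global discovery order, and renumbers the remaining ids
#' compactly (order of first occurrence).
#'
#' @param table A `blob_table`.
#' @param ids Object ids to merge (must all exist in `table`).
#' @return A `blob_table`.
#' @export
merge_objects <- function(table, ids) {
  if (length(ids) == 0L) stop("ids must be non-empty", call. = FALSE)
  if (!all(ids %in% table$oi)) {
    stop("unknown object id(s): ",
         paste(setdiff(ids, table$oi), collapse = ", "), call. = FALSE)
  }
  keep <- min(ids)
  tbl <- table
  tbl$oi[tbl$oi %in% ids] <- keep
  # recompact by first occurrence (rows keep their discovery order)
  tbl <- tbl[order(tbl$oi, tbl$ord), , drop = FALSE]
  first_ord <- vapply(split(tbl$ord, tbl$oi), min, numeric(1))
  lvl <- as.integer(names(first_ord))[order(first_ord)]
  tbl$oi <- match(tbl$oi, lvl)
  tbl <- tbl[order(tbl$oi, tbl$ord), , drop = FALSE]
  new_blob_table(tbl)
}

## Cells of one object as a two-column matrix (x, y).
blob_cells <- function(table, id) {
  sel <- table$oi == id
  cbind(x = table$x[sel], y = table$y[sel])
}

blob_ids <- function(table) unique(table$oi)
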