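# Independent flood-fill labeling oracle: 4-adjacency graph of occupied
# cells, components via igraph.  Deliberately unrelated to the row-scan
# implementation under test.
oracle_components <- function(m) {
  idx <- which(m == 1L)
  if (length(idx) == 0L) return(list())
  nr <- nrow(m)
  pos <- arrayInd(idx, dim(m))
  id_of <- integer(length(m))
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (k in seq_along(idx)) {
    r <- pos[k, 1]; c <- pos[k, 2]
    if (r < nr && m[r + 1, c] == 1L) {
      edges <- c(edges, k, id_of[idx[k] + 1L])
    }
    if (c < ncol(m) && m[r, c + 1] == 1L) {
      edges <- c(edges, k, id_of[idx[k] + nr])
    }
  }
  gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  memb <- igraph::components(gr)$membership
  # partition as a canonical set of sorted linear-index vectors
  unname(lapply(split(idx, memb), sort))
}

# Partition induced by a blob table, in the same canonical form.
table_components <- function(tab, nr) {
  if (nrow(tab) == 0L) return(list())
  lin <- (tab$x - 1L) * nr + tab$y
  unname(lapply(split(lin, tab$oi), sort))
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, function(v) paste(v, collapse = ","),
                                 character(1)))
  identical(key(a), key(b))
}

# Random binary grid with clustered structure (plain Bernoulli noise plus
# a few rectangles, so merges and multi-span rows actually occur).
random_grid <- function(nr, nc, p = 0.3) {
  m <- matrix(as.integer(runif(nr * nc) < p), nr, nc)
  for (i in seq_len(3)) {
    r0 <- sample(nr, 1); c0 <- sample(nc, 1)
    h <- sample(1:max(2, nr %/% 4), 1); w <- sample(1:max(2, nc %/% 4), 1)
    m[r0:min(nr, r0 + h), c0:min(nc, c0 + w)] <- 1L
  }
  m
}

# A U shape (two verticals joined at the bottom) on a small grid.
u_shape_grid <- function() {
  m <- matrix(0L, 8, 10)
  m[2:6, 3] <- 1L
  m[2:6, 8] <- 1L
  m[7, 3:8] <- 1L
  m
}

# A W-like shape: three prongs collapsing into one bottom row.
w_shape_grid <- function() {
  m <- matrix(0L, 8, 12)
  m[2:6, 2] <- 1L
  m[2:6, 6] <- 1L
  m[2:6, 10] <- 1L
  m[7, 2:10] <- 1L
  m
}

# Uniform CF/RF frame builders for preprocessing tests.
flat_frame <- function(value = 3000L, stage = "DF", nr = 240, nc = 320) {
  depth_frame(matrix(as.integer(value), nr, nc), stage = stage)
}

as_cf <- function(frame, cfg = system_config()) {
  fill_nulls(clamp_floor(frame, cfg), cfg)
}

# Registry with a single person whose central point is at (cp_x, cp_y).
one_person_registry <- function(cp_x, cp_y, cfg = system_config()) {
  reg <- track_registry()
  scp <- c(x = ceiling(cp_x / cfg$block_w), y = ceiling(cp_y / cfg$block_h))
  reg$persons <- tibble::tibble(
    id = 1L, cp_x = as.integer(cp_x), cp_y = as.integer(cp_y),
    scp_x = scp[["x"]], scp_y = scp[["y"]],
    mp_x = as.integer(cp_x), mp_y = as.integer(cp_y),
    smp_x = scp[["x"]], smp_y = scp[["y"]],
    missed = 0L, fallen = FALSE)
  reg$next_person <- 2L
  reg
}

# Scenario cache: rendering and running the canonical scenes is the
# expensive part of the suite, so share them across test files.
.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(name, seed = 1L) {
  key <- paste(name, seed, sep = "#")
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- make_scenario(name, seed = seed)
  }
  .scenario_cache[[key]]
}

cached_run <- function(name, seed = 1L, flat_rf = FALSE) {
  key <- paste("run", name, seed, flat_rf, sep = "#")
  if (is.null(.scenario_cache[[key]])) {
    sc <- cached_scenario(name, seed)
    cfg <- system_config()
    rf <- if (flat_rf) flat_frame(cfg$max_height, stage = "RF") else NULL
    .scenario_cache[[key]] <-
      run_fall_detection(sc$frames, cfg = cfg, rf = rf, ref_frames = 10L)
  }
  .scenario_cache[[key]]
}
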