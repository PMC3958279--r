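cfg <- system_config()

test_that("the central super-pixel is the member nearest the centroid", {
  expect_identical(central_superpixel(cbind(x = 5L, y = 7L)),
                   c(x = 5L, y = 7L))
  # two-cell blob: tie broken by smaller row
  expect_identical(central_superpixel(cbind(x = c(2L, 2L), y = c(4L, 5L))),
                   c(x = 2L, y = 4L))
  set.seed(9)
  for (k in 1:25) {
    n <- sample(2:30, 1)
    cells <- cbind(x = sample.int(40, n, TRUE), y = sample.int(40, n, TRUE))
    cells <- cells[!duplicated(cells), , drop = FALSE]
    got <- central_superpixel(cells)
    mx <- mean(cells[, "x"]); my <- mean(cells[, "y"])
    d2 <- (cells[, "x"] - mx)^2 + (cells[, "y"] - my)^2
    expect_equal(sum((got[["x"]] - mx)^2 + (got[["y"]] - my)^2), min(d2))
  }
  expect_error(central_superpixel(cbind(x = integer(), y = integer())),
               "empty")
})

test_that("pixel-to-mm conversion matches direct trigonometry", {
  expect_identical(pixel_to_mm(0, 1500, "horizontal"), 0)
  expect_equal(pixel_to_mm(320, 3000, "horizontal"),
               2 * 3000 * tan(28.5 * pi / 180))
  expect_equal(pixel_to_mm(240, 3000, "vertical"),
               2 * 3000 * tan(21.5 * pi / 180))
  wx <- pixel_to_mm(10, 2000, "horizontal")
  wy <- pixel_to_mm(10, 2000, "vertical")
  expect_equal(pixel_to_mm(10, 2000, "diagonal"), sqrt(wx^2 + wy^2))
  expect_error(pixel_to_mm(10, 0, "horizontal"), "positive")
})

test_that("conversion is exactly linear in segment length and depth", {
  set.seed(13)
  for (axis in c("horizontal", "vertical")) {
    wp <- runif(50, 1, 320); d <- runif(50, 400, 3000)
    expect_equal(pixel_to_mm(2 * wp, d, axis), 2 * pixel_to_mm(wp, d, axis))
    expect_equal(pixel_to_mm(wp, 3 * d, axis), 3 * pixel_to_mm(wp, d, axis))
  }
})

test_that("the peak point averages the head cap", {
  # flat slab: every pixel is at the minimum, mp is the slab centroid
  g <- matrix(3000L, 240, 320)
  g[61:120, 81:160] <- 2000L
  cf <- depth_frame(g, stage = "CF")
  cells <- expand.grid(x = 11:20, y = 11:20)   # super-pixels of the slab
  mp <- peak_point(cells, cf, cfg)
  expect_equal(mp[["x"]], 120, tolerance = 2)
  expect_equal(mp[["y"]], 90, tolerance = 2)

  # a single-pixel peak isolated by more than the depth window wins alone
  g2 <- matrix(3000L, 240, 320)
  g2[61:120, 81:160] <- 2000L
  g2[100, 140] <- 1500L
  mp2 <- peak_point(cells, depth_frame(g2, stage = "CF"), cfg)
  expect_identical(mp2, c(x = 140L, y = 100L))

  # hemispherical head: mp lands within one pixel of the apex
  apex <- c(x = 160, y = 120)
  r_mm <- 125
  g3 <- matrix(3000L, 240, 320)
  z0 <- 1300
  px_w <- 2 * z0 * tan(28.5 * pi / 180) / 320
  px_h <- 2 * z0 * tan(21.5 * pi / 180) / 240
  for (r in 100:140) for (c in 130:190) {
    rho2 <- ((c - apex[["x"]]) * px_w)^2 + ((r - apex[["y"]]) * px_h)^2
    if (rho2 <= r_mm^2) g3[r, c] <- round(z0 + r_mm - sqrt(r_mm^2 - rho2))
  }
  head_cells <- expand.grid(x = 16:25, y = 16:25)
  mp3 <- peak_point(head_cells, depth_frame(g3, stage = "CF"), cfg)
  expect_true(abs(mp3[["x"]] - apex[["x"]]) <= 1)
  expect_true(abs(mp3[["y"]] - apex[["y"]]) <= 1)
})

test_that("directional scans cover eight directions to the border", {
  cf <- depth_frame(matrix(2000L, 240, 320), stage = "CF")
  sc <- directional_scan(cf, c(x = 160L, y = 120L))
  expect_named(sc$diffs, c("N", "NE", "E", "SE", "S", "SW", "W", "NW"))
  expect_true(all(vapply(sc$diffs, function(d) all(d == 0), logical(1))))
  expect_identical(length(sc$diffs$E), 160L)
  expect_identical(length(sc$diffs$W), 159L)

  # at a corner only the three inward directions have steps
  sc2 <- directional_scan(cf, c(x = 1L, y = 1L))
  lens <- lengths(sc2$diffs)
  expect_identical(unname(lens[c("N", "NE", "W", "SW", "NW")]),
                   rep(0L, 5))
  expect_true(all(lens[c("E", "SE", "S")] > 0))
})

test_that("the head-ground gap needs one step of half the head depth", {
  mk <- function(depth, step) {
    d <- lapply(1:8, function(i) c(0, 0, step, 0))
    names(d) <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
    structure(list(depth = depth, diffs = d), class = "directional_scan")
  }
  # head at 1300 under a 3 m ceiling: silhouette step 1700 >= 650
  expect_true(head_ground_gap(mk(1300, 1700)))
  # all flat: nothing found
  expect_false(head_ground_gap(mk(1300, 0)))
  # low box at 2600: largest step 400 < 1300
  expect_false(head_ground_gap(mk(2600, 400)))
  # boundary: exactly half the depth counts
  expect_true(head_ground_gap(mk(1300, 650)))
})

test_that("the head-shoulder window counts cumulative drops, not skips", {
  mk <- function(e, w, others = c(0, 0, 0)) {
    d <- lapply(1:8, function(i) others)
    names(d) <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
    d$E <- e; d$W <- w
    structure(list(depth = 1300, diffs = d), class = "directional_scan")
  }
  # 250 mm drop spread over pixels lands in [200, 300] in E and W
  expect_identical(head_shoulder_gap(mk(c(100, 150, 0), c(120, 130, 0)), cfg),
                   2L)
  # flat slab: no drop anywhere
  expect_identical(head_shoulder_gap(mk(c(0, 0), c(0, 0)), cfg), 0L)
  # a 350 mm drop straight to the floor skips the window
  expect_identical(head_shoulder_gap(mk(c(350, 0), c(0, 350)), cfg), 0L)
})

test_that("head extents come from gap distances, border-capped", {
  sc <- cached_scenario("simple_fall")
  cfg <- system_config()
  cf <- as_cf(sc$frames[[75]])   # standing still at the centre
  rf <- capture_reference(lapply(sc$frames[1:10], as_cf))
  fs <- superpixelize(carve_edges(compute_foreground(cf, rf, cfg), cfg), cfg)
  tab <- distinguish_objects(fs)
  person <- which.max(tapply(tab$oi, tab$oi, length))
  cells <- tab[tab$oi == as.integer(names(person)), ]
  mp <- peak_point(cells, cf, cfg)
  scan <- directional_scan(cf, mp)
  dims <- head_dimensions(scan, scan$depth, cfg)
  # all four extents close to the configured 250 mm head diameter
  expect_true(all(dims > 180 & dims < 330))
  expect_true(max(dims) / min(dims) <= cfg$head_comparability_ratio)
})

test_that("a wide slab fails the head dimension range", {
  # 1200 mm slab at desk height: E+W extent far beyond 400 mm
  g <- matrix(3000L, 240, 320)
  z <- 2250
  px_w <- 2 * z * tan(28.5 * pi / 180) / 320
  half <- round(600 / px_w)
  g[90:150, (160 - half):(160 + half)] <- as.integer(z)
  cf <- depth_frame(g, stage = "CF")
  mp <- c(x = 160L, y = 120L)
  scan <- directional_scan(cf, mp)
  dims <- head_dimensions(scan, scan$depth, cfg)
  expect_gt(dims[["horizontal"]], 400)
})

test_that("is_person separates people from furniture and floor blobs", {
  sc <- cached_scenario("simple_fall")
  cf <- as_cf(sc$frames[[75]])
  rf <- capture_reference(lapply(sc$frames[1:10], as_cf))
  fs <- superpixelize(carve_edges(compute_foreground(cf, rf, cfg), cfg), cfg)
  tab <- distinguish_objects(fs)
  sizes <- tapply(tab$oi, tab$oi, length)
  person_id <- as.integer(names(which.max(sizes)))
  expect_true(is_person(tab[tab$oi == person_id, ], cf, cfg))

  # the desk blob (furniture in the empty scene) is not a person
  cf0 <- as_cf(sc$frames[[1]])
  fs0 <- superpixelize(carve_edges(compute_foreground(cf0, rf, cfg), cfg),
                       cfg)
  tab0 <- distinguish_objects(fs0)
  expect_gt(nrow(tab0), 0)
  for (id in unique(tab0$oi)) {
    expect_false(is_person(tab0[tab0$oi == id, ], cf0, cfg))
  }
})

test_that("is_person is invariant under horizontal mirroring", {
  sc <- cached_scenario("simple_fall")
  cf <- as_cf(sc$frames[[75]])
  rf <- capture_reference(lapply(sc$frames[1:10], as_cf))
  fs <- superpixelize(carve_edges(compute_foreground(cf, rf, cfg), cfg), cfg)
  tab <- distinguish_objects(fs)
  gm <- unclass(cf)[, 320:1]
  cfm <- depth_frame(gm, stage = "CF")
  for (id in unique(tab$oi)) {
    cells <- tab[tab$oi == id, ]
    mirrored <- tibble::tibble(x = 41L - cells$x, y = cells$y)
    expect_identical(is_person(mirrored, cfm, cfg),
                     is_person(cells, cf, cfg))
  }
})
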