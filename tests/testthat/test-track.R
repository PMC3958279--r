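cfg <- system_config()

test_that("condition classification is total and matches the definitions", {
  expect_identical(classify_row(0, 0), "A")
  expect_identical(classify_row(0, 1), "A")
  expect_identical(classify_row(1, 0), "B")
  expect_identical(classify_row(2, 0), "C")
  expect_identical(classify_row(1, 1), "C")
  expect_identical(classify_row(0, 2), "C")
  for (np in 0:3) for (no in 0:3) {
    expect_true(classify_row(np, no) %in% c("A", "B", "C"))
  }
})

test_that("tracking info places ids by their stored anchor super-pixel", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[7:9, 6:9] <- 1L
  tab <- distinguish_objects(m)

  reg <- track_registry()
  expect_identical(build_tracking_info(reg, tab)$n_pers, c(0L, 0L))

  reg <- one_person_registry(cp_x = 20, cp_y = 20)   # scp (3, 4) -> ...
  reg$persons$scp_x <- 3L; reg$persons$scp_y <- 3L
  reg$objects <- reg$persons[, setdiff(names(reg$persons), "fallen")]
  reg$objects$id <- 1L
  reg$objects$smp_x <- 7L; reg$objects$smp_y <- 8L
  info <- build_tracking_info(reg, tab)
  expect_identical(info$n_pers, c(1L, 0L))
  expect_identical(info$n_obj, c(0L, 1L))
  expect_identical(info$pers[[1]], 1L)
  expect_identical(info$obj[[2]], 1L)
})

test_that("a merged blob reports every person whose anchor it contains", {
  m <- matrix(0L, 10, 12)
  m[3:6, 2:10] <- 1L
  tab <- distinguish_objects(m)
  reg <- track_registry()
  reg$persons <- dplyr::bind_rows(
    one_person_registry(1, 1)$persons,
    one_person_registry(1, 1)$persons)
  reg$persons$id <- 1:2
  reg$persons$scp_x <- c(3L, 8L); reg$persons$scp_y <- c(4L, 5L)
  info <- build_tracking_info(reg, tab)
  expect_identical(info$n_pers, 2L)
  expect_identical(info$pers[[1]], 1:2)
  expect_identical(classify_row(info$n_pers, info$n_obj), "C")
})

test_that("fusion splitting keeps each participant's own component", {
  # two square lobes joined by a thin bridge
  m <- matrix(0L, 15, 21)
  m[4:8, 2:6] <- 1L
  m[4:8, 14:18] <- 1L
  m[6, 7:13] <- 1L
  tab <- distinguish_objects(m)
  expect_identical(length(unique(tab$oi)), 1L)
  cells <- tab[tab$oi == 1L, ]
  members <- tibble::tibble(smp_x = c(4L, 16L), smp_y = c(6L, 6L))
  subs <- split_fusion(cells, members, radius = 5)
  expect_length(subs, 2L)
  expect_true(all(subs[[1]][, "x"] <= 9))
  expect_true(all(subs[[2]][, "x"] >= 11))
  # each sub-blob contains its member's peak cell
  expect_true(any(subs[[1]][, "x"] == 4 & subs[[1]][, "y"] == 6))
  expect_true(any(subs[[2]][, "x"] == 16 & subs[[2]][, "y"] == 6))

  # single member: the blob restricted to its radius
  one <- split_fusion(cells, members[1, ], radius = 5)
  expect_true(all(pmax(abs(one[[1]][, "x"] - 4), abs(one[[1]][, "y"] - 6))
                  <= 5))

  # a member outside the blob is a contract error
  expect_error(split_fusion(cells, tibble::tibble(smp_x = 1L, smp_y = 1L),
                            radius = 5), "not inside")
})

test_that("three-way fusions split into three sub-blobs", {
  m <- matrix(0L, 15, 30)
  m[4:8, 2:6] <- 1L; m[4:8, 13:17] <- 1L; m[4:8, 24:28] <- 1L
  m[6, 2:28] <- 1L
  tab <- distinguish_objects(m)
  expect_identical(length(unique(tab$oi)), 1L)
  members <- tibble::tibble(smp_x = c(4L, 15L, 26L), smp_y = c(6L, 6L, 6L))
  subs <- split_fusion(tab[tab$oi == 1L, ], members, radius = 5)
  expect_length(subs, 3L)
  for (i in 1:3) {
    expect_true(any(subs[[i]][, "x"] == members$smp_x[i] &
                    subs[[i]][, "y"] == members$smp_y[i]))
  }
  # contested bridge cells go to the nearest peak
  expect_true(all(abs(subs[[2]][, "x"] - 15) <= 5))
})

test_that("the fall rule is strict at the 400 mm threshold", {
  mk_cf <- function(height) {
    g <- matrix(3000L, 240, 320)
    g[100:140, 140:180] <- as.integer(3000 - height)
    depth_frame(g, stage = "CF")
  }
  reg <- one_person_registry(160, 120)
  expect_identical(nrow(detect_fall(reg, mk_cf(1700), cfg)$events), 0L)
  expect_identical(nrow(detect_fall(reg, mk_cf(400), cfg)$events), 0L)
  ev <- detect_fall(reg, mk_cf(350), cfg, frame = 9L)$events
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$frame_index, 9L)
  expect_identical(ev$height_above_floor, 350)
  expect_identical(nrow(detect_fall(reg, mk_cf(399), cfg)$events), 1L)
})

test_that("fall events are edge-triggered per excursion", {
  g <- matrix(3000L, 240, 320)
  g[100:140, 140:180] <- 2650L
  cf_low <- depth_frame(g, stage = "CF")
  g[100:140, 140:180] <- 1550L
  cf_up <- depth_frame(g, stage = "CF")
  reg <- one_person_registry(160, 120)
  r1 <- detect_fall(reg, cf_low, cfg, 1L)
  expect_identical(nrow(r1$events), 1L)
  r2 <- detect_fall(r1$registry, cf_low, cfg, 2L)
  expect_identical(nrow(r2$events), 0L)        # still down: no new event
  r3 <- detect_fall(r2$registry, cf_up, cfg, 3L)
  expect_identical(nrow(r3$events), 0L)        # back up: latch re-armed
  r4 <- detect_fall(r3$registry, cf_low, cfg, 4L)
  expect_identical(nrow(r4$events), 1L)        # second excursion
})

test_that("a static empty scene is a fixed point of the tracker", {
  sc <- cached_scenario("table1_seven_blobs")
  cfg <- system_config()
  cf <- as_cf(sc$frames[[1]])
  rf <- depth_frame(matrix(unclass(cf)[TRUE], 240, 320), stage = "RF")
  state <- pipeline_state(rf, cfg)
  out1 <- process_frame(sc$frames[[1]], state)
  reg1 <- out1$state$registry
  out2 <- process_frame(sc$frames[[2]], out1$state)
  reg2 <- out2$state$registry
  expect_identical(reg1$persons, reg2$persons)
  expect_identical(reg1$objects$id, reg2$objects$id)
  expect_identical(nrow(out2$events), 0L)
  # the seven static slabs are tracked as objects, never persons
  expect_identical(nrow(reg2$persons), 0L)
  expect_identical(nrow(reg2$objects), 7L)
})

test_that("identical frame sequences give identical runs", {
  sc <- cached_scenario("simple_fall")
  cfg <- system_config()
  frames <- sc$frames[seq(80, 120)]
  rf <- capture_reference(lapply(sc$frames[1:10], as_cf))
  r1 <- run_fall_detection(frames, cfg = cfg, rf = rf)
  r2 <- run_fall_detection(frames, cfg = cfg, rf = rf)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$heights, r2$heights)
})

test_that("no fall event is ever emitted for an unpromoted blob", {
  # the degraded complex scenario: the person merges with the desk and is
  # retired; the merged object must never trigger an alarm
  run <- cached_run("complex_fall", flat_rf = TRUE)
  expect_identical(nrow(run$events), 0L)
  below <- run$heights[run$heights$below, ]
  expect_identical(nrow(below), 0L)
})
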