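cfg <- system_config()

test_that("floor clamping absorbs the 200 mm band and spares the rest", {
  g <- matrix(3000L, 12, 16)
  g[1, 1] <- 2850L   # within 200 mm of the floor
  g[1, 2] <- 2800L   # boundary: gap exactly 200
  g[1, 3] <- 2799L   # gap 201: kept
  g[1, 4] <- 0L      # null: untouched
  out <- clamp_floor(depth_frame(g), cfg)
  expect_identical(out[1, 1], 3000L)
  expect_identical(out[1, 2], 3000L)
  expect_identical(out[1, 3], 2799L)
  expect_identical(out[1, 4], 0L)
  expect_identical(frame_stage(out), "DFm")
})

test_that("null filling uses the nearest valid value to the left, the first
           valid to the right for leading runs, and the floor for dead rows", {
  g <- matrix(2500L, 4, 6)
  g[1, ] <- c(0L, 0L, 2500L, 2400L, 0L, 2300L)
  g[2, ] <- 0L
  g[3, ] <- c(1000L, 0L, 0L, 0L, 0L, 900L)
  out <- fill_nulls(depth_frame(g, stage = "DFm"), cfg)
  expect_identical(out[1, ], c(2500L, 2500L, 2500L, 2400L, 2400L, 2300L))
  expect_identical(out[2, ], rep(3000L, 6))
  expect_identical(out[3, ], c(1000L, 1000L, 1000L, 1000L, 1000L, 900L))
  expect_identical(frame_stage(out), "CF")
})

test_that("null filling is total and idempotent on random dropout frames", {
  set.seed(7)
  for (k in 1:20) {
    g <- matrix(sample.int(3000L, 30 * 40, TRUE), 30, 40)
    g[sample.int(length(g), 200)] <- 0L
    once <- fill_nulls(depth_frame(g, stage = "DFm"), cfg)
    expect_false(any(once == 0L))
    # non-null pixels are never altered
    expect_identical(unclass(once)[g != 0L], g[g != 0L])
    twice <- fill_nulls(depth_frame(unclass(once)[TRUE] |>
                                      matrix(30, 40), stage = "DFm"), cfg)
    expect_identical(unclass(twice)[TRUE], unclass(once)[TRUE])
  }
})

test_that("foreground slicing boosts exactly the pixels deviating from the
           reference by more than the person threshold", {
  rf <- depth_frame(matrix(3000L, 6, 8), stage = "RF")
  g <- matrix(3000L, 6, 8)
  g[1, 1] <- 1300L   # person pixel: 1300 + 6000
  g[1, 2] <- 2850L   # |2850 - 3000| = 150 > 50: boosted
  g[1, 3] <- 2960L   # |diff| = 40: kept
  cf <- depth_frame(g, stage = "CF")
  ff <- compute_foreground(cf, rf, cfg)
  expect_identical(ff[1, 1], 7300L)
  expect_identical(ff[1, 2], 8850L)
  expect_identical(ff[1, 3], 2960L)
  expect_identical(ff[2, 2], 3000L)

  # boundary |CF - RF| == th_person stays (strict inequality)
  g2 <- matrix(2850L, 6, 8)
  rf2 <- depth_frame(matrix(2800L, 6, 8), stage = "RF")
  ff2 <- compute_foreground(depth_frame(g2, stage = "CF"), rf2, cfg)
  expect_true(all(ff2 == 2850L))

  # identity when CF == RF
  ff3 <- compute_foreground(depth_frame(matrix(2800L, 6, 8), stage = "CF"),
                            rf2, cfg)
  expect_true(all(ff3 == 2800L))
  expect_error(compute_foreground(cf, depth_frame(matrix(3000L, 5, 8),
                                                  stage = "RF"), cfg),
               "same shape")
})

test_that("foreground slicing leaves exactly the within-threshold pixels
           unchanged on random frames", {
  set.seed(11)
  for (k in 1:10) {
    g <- matrix(sample(2000:4000, 24 * 32, TRUE), 24, 32)
    r <- matrix(sample(2000:4000, 24 * 32, TRUE), 24, 32)
    ff <- compute_foreground(depth_frame(g, stage = "CF"),
                             depth_frame(r, stage = "RF"), cfg)
    keep <- abs(g - r) <= cfg$th_person
    expect_identical(unclass(ff)[keep], g[keep])
    expect_identical(unclass(ff)[!keep], g[!keep] + 6000L)
  }
})

test_that("edge carving removes a sliced step but not a gentle one", {
  # uniform frame: no gradients, nothing carved
  u <- depth_frame(matrix(5000L, 12, 16), stage = "FF")
  expect_true(all(carve_edges(u, cfg) == 5000L))

  # vertical step of +6000 between columns 8 and 9: the 3x3 Sobel gives
  # |Gx| = 4 * 6000 on both columns flanking the step, so both are carved
  g <- matrix(3000L, 12, 16)
  g[, 9:16] <- 9000L
  out <- carve_edges(depth_frame(g, stage = "FF"), cfg)
  expect_true(all(out[, 8] == 3000L))
  expect_true(all(out[, 9] == 3000L))
  expect_true(all(out[, 7] == 3000L))   # already floor
  expect_true(all(out[, 10] == 9000L))  # interior survives

  # step of +100: |Gx| = 400 < 2000, frame unchanged
  g2 <- matrix(3000L, 12, 16)
  g2[, 9:16] <- 3100L
  out2 <- carve_edges(depth_frame(g2, stage = "FF"), cfg)
  expect_identical(unclass(out2)[TRUE], g2[TRUE])
  expect_identical(frame_stage(out2), "FFSobel")
})

test_that("super-pixel binarization needs every pixel of a block off-floor", {
  f <- depth_frame(matrix(3000L, 240, 320), stage = "FFSobel")
  s <- superpixelize(f, cfg)
  expect_identical(dim(unclass(s)), c(40L, 40L))
  expect_true(all(s == 0L))

  g <- matrix(3000L, 240, 320)
  g[1:6, 1:8] <- 2000L          # block (1,1) fully covered
  g[1:6, 9:16] <- 2000L
  g[3, 12] <- 3000L             # one floor pixel in block (1,2)
  s2 <- superpixelize(depth_frame(g, stage = "FFSobel"), cfg)
  expect_identical(s2[1, 1], 1L)
  expect_identical(s2[1, 2], 0L)
  expect_identical(sum(s2), 1L)
})

test_that("super-pixel binarization equals a brute-force block scan", {
  set.seed(3)
  for (k in 1:25) {
    g <- matrix(sample(c(3000L, 2000L, 9000L), 240 * 320, TRUE,
                       prob = c(0.8, 0.1, 0.1)), 240, 320)
    s <- superpixelize(depth_frame(g, stage = "FFSobel"), cfg)
    brute <- matrix(0L, 40, 40)
    for (i in 1:40) for (j in 1:40) {
      blk <- g[(i - 1) * 6 + 1:6, (j - 1) * 8 + 1:8]
      brute[i, j] <- as.integer(all(blk != 3000L))
    }
    expect_identical(unclass(s)[TRUE], brute[TRUE])
  }
})

test_that("the reference frame is the pixel-wise median of the warm-up", {
  cf1 <- depth_frame(matrix(3000L, 6, 8), stage = "CF")
  expect_identical(unclass(capture_reference(list(cf1)))[TRUE],
                   unclass(cf1)[TRUE])
  expect_identical(frame_stage(capture_reference(list(cf1))), "RF")

  g2 <- matrix(3000L, 6, 8); g2[2, 2] <- 1200L   # transient outlier
  cf2 <- depth_frame(g2, stage = "CF")
  rf <- capture_reference(list(cf1, cf2, cf1))
  expect_identical(rf[2, 2], 3000L)
  expect_error(capture_reference(list(), n = 0), "at least one")
})
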