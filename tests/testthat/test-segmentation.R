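test_that("seed grids form the expected lattices", {
  expect_equal(nrow(make_seed_grid(roi(0, 0, 8, 8), 4)$points), 4)
  expect_equal(nrow(make_seed_grid(roi(0, 0, 128, 64), 4)$points), 32 * 16)

  g <- make_seed_grid(roi(2, 3, 2, 2), 10)  # spacing larger than the roi
  expect_equal(unname(g$points), matrix(c(2, 3), 1))
})

test_that("grid condensation scales the roi and multiplies the point count", {
  g <- make_seed_grid(roi(0, 0, 8, 8), 4)
  expect_equal(nrow(condense_grid(g, 2)$points), 16)
  expect_identical(condense_grid(g, 1), g)

  # condensing equals building the grid directly on the scaled roi
  g3 <- make_seed_grid(roi(4, 8, 16, 12), 2)
  expect_identical(condense_grid(g3, 4),
                   make_seed_grid(roi(16, 32, 64, 48), 2))
})

test_that("region growing segments exactly the seeded dark components", {
  frame <- matrix(200L, 12, 12)
  grid <- make_seed_grid(roi(0, 0, 12, 12), 4)
  expect_equal(region_grow(frame, grid, 100)$area, 0)

  frame[4:6, 4:6] <- 10L
  seeded <- structure(list(points = cbind(row = 4L, col = 4L), spacing = 1,
                           roi = roi(0, 0, 12, 12)), class = "seed_grid")
  m <- region_grow(frame, seeded, 100)
  expect_equal(m$area, 9)
  expect_true(all(which(m$mask) == which(frame == 10L)))

  # two blobs, seeds covering only one
  frame[9:10, 9:10] <- 10L
  m2 <- region_grow(frame, seeded, 100)
  expect_equal(m2$area, 9)
  oracle <- flood_fill_oracle(frame, cbind(5, 5), 100)
  expect_identical(region_grow(frame, seeded, 100)$mask[4:6, 4:6],
                   oracle[4:6, 4:6])
})

test_that("region growing matches the brute-force flood fill on random frames", {
  set.seed(42)
  grid <- make_seed_grid(roi(0, 0, 16, 16), 5)
  for (rep in 1:10) {
    frame <- matrix(sample.int(256, 256, replace = TRUE) - 1L, 16, 16)
    thr <- sample(50:200, 1)
    got <- region_grow(frame, grid, thr)$mask
    want <- flood_fill_oracle(frame, grid$points + 1L, thr)
    expect_identical(got, want)
    # 8-connectivity branch too
    got8 <- region_grow(frame, grid, thr, connectivity = "8")$mask
    want8 <- flood_fill_oracle(frame, grid$points + 1L, thr, conn8 = TRUE)
    expect_identical(got8, want8)
  }
})

test_that("raising the threshold never shrinks the grown region", {
  set.seed(8)
  grid <- make_seed_grid(roi(0, 0, 16, 16), 4)
  frame <- matrix(sample.int(256, 256, replace = TRUE) - 1L, 16, 16)
  prev <- matrix(FALSE, 16, 16)
  for (thr in seq(40, 240, by = 40)) {
    cur <- region_grow(frame, grid, thr)$mask
    expect_true(all(cur[prev]))  # set inclusion
    prev <- cur
  }
})

test_that("the midline of a symmetric lens is its long axis", {
  m <- lens_mask(41, 81, c(21, 41), half_length = 30, sagitta = 8)
  mid <- compute_midline(m)
  expect_equal(unname(mid$anterior["row"]), 21)
  expect_equal(unname(mid$posterior["row"]), 21)
  expect_equal(mid$length, 60, tolerance = 0.05)

  pa <- partial_areas(m, mid)
  expect_equal(unname(pa["left"]), unname(pa["right"]))
  expect_equal(sum(pa), sum(m))
})

test_that("midline recovery works on a rotated lens and matches the exhaustive oracle", {
  theta <- 30 * pi / 180
  m <- lens_mask(101, 101, c(51, 51), half_length = 35, sagitta = 9,
                 theta = theta)
  mid <- compute_midline(m)

  d <- mid$anterior - mid$posterior
  angle <- atan2(d["row"], d["col"]) * 180 / pi
  angle <- (angle + 180) %% 180          # undirected axis
  expect_lt(min(abs(angle - 30), abs(angle - 210)), 2)

  # exhaustive pairwise-distance oracle over all boundary points
  b <- which(m, arr.ind = TRUE)
  b <- b[apply(b, 1, function(p) {
    any(p[1] + c(-1, 1, 0, 0) < 1 | p[1] + c(-1, 1, 0, 0) > 101 |
          !m[cbind(p[1] + c(-1, 1, 0, 0), p[2] + c(0, 0, -1, 1))])
  }), ]
  dmax <- max(stats::dist(b))
  expect_equal(mid$length, dmax)
})

test_that("degenerate masks are rejected", {
  expect_error(compute_midline(matrix(FALSE, 5, 5)), "empty")
  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  expect_error(compute_midline(single), "single point")
})

test_that("empty masks split into zero partial areas", {
  mid <- list(anterior = c(row = 1, col = 1), posterior = c(row = 5, col = 1),
              length = 4)
  expect_equal(partial_areas(matrix(FALSE, 5, 5), mid),
               c(left = 0, right = 0))
})

test_that("segmenting a noise-free rendering recovers the rendered areas", {
  cfg <- subject_config("female", f0 = 200, frame_height = 96,
                        frame_width = 192, glottis_length_px = 110,
                        max_area_px = 1100, n_frames = 700, noise_sd = 0,
                        rng_seed = 17)
  rv <- render_video(cfg)
  thr <- (cfg$glottis_level + cfg$background_level) / 2
  d <- dim(rv$video$px)
  grid <- make_seed_grid(roi(0, 0, d[1], d[2]), 1)  # every pixel seeded
  triple <- segment_sequence(rv$video, segmentation_settings(thr), grid)

  # the grown region is exactly the rendered dark region, frame by frame
  expect_equal(triple$total, rv$truth$area_total)
  # closed-phase frames are exactly 0 px
  expect_true(all(triple$total[rv$gaw$total == 0] == 0))
  # the midline split matches the renderer's left/right ground truth
  open <- rv$truth$area_total > 0.5 * max(rv$truth$area_total)
  relerr <- abs(triple$left[open] - rv$truth$area_left[open]) /
    rv$truth$area_left[open]
  expect_lt(max(relerr), 0.05)
})

test_that("a threshold below the darkest pixel yields an all-zero waveform", {
  px <- array(sample.int(156, 8 * 8 * 30, replace = TRUE) + 99L, c(8, 8, 30))
  v <- video_stack(px, fps = 4000)
  grid <- make_seed_grid(roi(0, 0, 8, 8), 2)
  triple <- segment_sequence(v, segmentation_settings(50), grid)
  expect_true(all(triple$total == 0))
})
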