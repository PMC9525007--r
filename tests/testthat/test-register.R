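# Coarse thumbnail alignment, tile correspondences and cycle registration.

test_that("coarse alignment recovers a pure recorded-position offset", {
  f <- fixture_acq()
  ts <- f$sa$tilesets[[1L]]
  v <- c(120, -80)
  ts_off <- tileset(ts$tiles, sweep(ts$positions, 2L, -v), ts$pixel_size)
  cs <- coarse_align(ts, ts_off, downsample = 10L)
  # thumbnail pixel is 10 um here; agree within one downsampled pixel
  expect_lt(max(abs(cs - v)), 10)
  expect_equal(coarse_align(ts, ts, downsample = 10L), c(0, 0),
               tolerance = 1e-6)
})

test_that("coarse alignment recovers inter-cycle stage drift on content", {
  f <- fixture_acq()
  cs <- coarse_align(f$sa$tilesets[[1L]], f$sa$tilesets[[2L]],
                     downsample = 10L)
  # generator drift d moves content; recorded frames coincide, so the
  # drift convention gives coarse = -d
  d <- f$sa$transforms$drift_um[2L, ]
  expect_lt(max(abs(cs + d)), 10)
})

test_that("blank thumbnails warn and return zero drift", {
  blank <- tileset(replicate(4, matrix(0, 40, 40), simplify = FALSE),
                   grid_positions(2, 2, c(40, 40), 1, 0.1), pixel_size = 1)
  expect_warning(cs <- coarse_align(blank, blank), "blank|uninformative")
  expect_equal(cs, c(0, 0))
})

test_that("correspondences are nearest-neighbor with many-to-one allowed", {
  f <- fixture_acq()
  ts <- f$sa$tilesets[[1L]]
  expect_equal(find_correspondences(ts, ts, c(0, 0)), seq_len(n_tiles(ts)))
  # offset by exactly one tile pitch in x (stride 80 um): column shift
  ts_off <- tileset(ts$tiles, sweep(ts$positions, 2L, c(0, -80)), ts$pixel_size)
  m <- find_correspondences(ts, ts_off, c(0, 0))
  expect_equal(m[1L], 2L)   # first target tile maps one column over
  # an extra off-tissue tile maps to the nearest edge tile
  extra <- tileset(c(ts$tiles, ts$tiles[1L]),
                   rbind(ts$positions, c(-500, -500)), ts$pixel_size)
  m2 <- find_correspondences(ts, extra, c(0, 0))
  expect_equal(m2[n_tiles(extra)], 1L)
  expect_equal(anyDuplicated(m2) > 0, TRUE)
})

test_that("cycle registration recovers generator truth with drift and loss", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  ts1 <- f$sa$tilesets[[1L]]; ts2 <- f$sa$tilesets[[2L]]
  rr <- register_tiles(ts1, sr, ts2)
  expect_true(all(rr$source %in% c("aligned", "affine_fallback")))
  al <- rr$source == "aligned"
  expect_gt(mean(al), 0.6)
  off <- colMeans(sr$positions - truth_positions(f$sa, 1))
  err_px <- sweep(rr$positions - truth_positions(f$sa, 2), 2L, off) /
    ts1$pixel_size
  expect_lt(stats::median(sqrt(rowSums(err_px[al, , drop = FALSE]^2))), 0.2)
})

test_that("a tile erased in the target cycle falls back to the affine model", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  ts1 <- f$sa$tilesets[[1L]]
  ts2 <- f$sa$tilesets[[2L]]
  tiles <- ts2$tiles
  tiles[[6L]] <- array(0, dim = dim(tiles[[6L]]))  # simulated tissue loss
  ts2z <- tileset(tiles, ts2$positions, ts2$pixel_size)
  rr <- register_tiles(ts1, sr, ts2z)
  expect_equal(rr$source[6L], "affine_fallback")
  expect_true(is.na(rr$shift_um[6L]))
})

test_that("registering a cycle against itself returns its stitched positions", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  ts1 <- f$sa$tilesets[[1L]]
  rr <- register_tiles(ts1, sr, ts1, coarse_shift = c(0, 0))
  expect_true(all(rr$source == "aligned"))
  err_px <- abs(rr$positions - sr$positions) / ts1$pixel_size
  expect_lt(max(err_px), 0.1 + 1e-9)  # within 1/upsample px
})

test_that("forcing fallback reproduces the affine-transformed recorded grid", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  ts1 <- f$sa$tilesets[[1L]]; ts2 <- f$sa$tilesets[[2L]]
  cs <- coarse_align(ts1, ts2)
  rr <- register_tiles(ts1, sr, ts2, max_shift = 1e-9, coarse_shift = cs)
  expect_true(all(rr$source == "affine_fallback"))
  expected <- predict_affine(sr$affine, sweep(ts2$positions, 2L, cs))
  expect_equal(rr$positions, expected)
})

test_that("cycles register against the first in a star, never chained", {
  acq <- acquisition_spec(rows = 3L, cols = 3L, tile_px = c(80L, 80L),
                          overlap_px = 16L, pixel_size = 1, jitter_px = 1,
                          scale = 1.002, cycles = 3L, drift_um = 10,
                          loss_fraction = 0, seed = 21L)
  sc <- make_scene(scene_spec(size = scene_size_for(acq), nuclei_density = 25,
                              tile_px = c(80L, 80L), seed = 21L))
  sa <- cut_acquisition(sc, acq)
  sr <- stitch(sa$tilesets[[1L]], n_pairs = 60, seed = 2)
  r3 <- register_tiles(sa$tilesets[[1L]], sr, sa$tilesets[[3L]])
  # corrupt cycle 2 badly; cycle 3's registration must not change
  ts2_bad <- tileset(lapply(sa$tilesets[[2L]]$tiles, function(t) t * 0),
                     sa$tilesets[[2L]]$positions + 500,
                     sa$tilesets[[2L]]$pixel_size)
  suppressWarnings(register_tiles(sa$tilesets[[1L]], sr, ts2_bad))
  r3_after <- register_tiles(sa$tilesets[[1L]], sr, sa$tilesets[[3L]])
  expect_identical(r3_after$positions, r3$positions)
  expect_identical(r3_after$source, r3$source)
})
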