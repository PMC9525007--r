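# Block-dense flow-field evaluation of registration consistency.

make_textured <- function(size = 420L, seed = 31L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # read-noise floor keeps every block "imaged" (no exact zeros)
  pmin(blob_image(size, round(size^2 / 400), seed = seed) +
         matrix(runif(size^2, 0.005, 0.02), size, size), 1)
}

# bilinear rotation about the image center
rotate_bilinear <- function(a, deg) {
  th <- deg * pi / 180
  d <- dim(a); cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yy <- matrix(seq_len(d[1]), d[1], d[2]) - cy
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx
  ys <- cy + cos(th) * yy - sin(th) * xx
  xs <- cx + sin(th) * yy + cos(th) * xx
  y0 <- pmin(pmax(floor(ys), 1), d[1] - 1); x0 <- pmin(pmax(floor(xs), 1), d[2] - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  v <- (1 - fy) * (1 - fx) * a[cbind(as.vector(y0), as.vector(x0))] +
       fy * (1 - fx) * a[cbind(as.vector(y0 + 1), as.vector(x0))] +
       (1 - fy) * fx * a[cbind(as.vector(y0), as.vector(x0 + 1))] +
       fy * fx * a[cbind(as.vector(y0 + 1), as.vector(x0 + 1))]
  matrix(v, d[1], d[2])
}

test_that("global pre-alignment recovers a whole-mosaic shift", {
  a <- make_textured(300)
  b <- roll2(a, c(30, 0))
  expect_equal(global_prealign(a, b, downsample = 10), c(30, 0),
               tolerance = 1)
  expect_equal(global_prealign(a, a, downsample = 10), c(0, 0),
               tolerance = 1e-6)
  # downsample 1 is plain phase correlation
  d1 <- global_prealign(a, b, downsample = 1)
  pc <- phase_correlate(whiten(a), whiten(b))
  expect_equal(d1, pc$shift)
})

test_that("identical mosaics give a zero flow field", {
  a <- make_textured(400)
  ff <- block_flow(a, a, block = 100)
  expect_true(all(ff$valid))
  expect_equal(max(abs(ff$residual_dy[ff$valid])), 0, tolerance = 1e-9)
  st <- flow_stats(ff, pixel_size = 0.65)
  expect_equal(st$summary$median_um, 0, tolerance = 1e-9)
})

test_that("an affine discrepancy (small rotation) is absorbed by compensation", {
  a <- make_textured(600)
  b <- rotate_bilinear(a, 0.2)  # up to ~1 px displacement at the corners
  ff <- block_flow(a, b, block = 100)
  raw_mag <- sqrt(ff$grid_dy^2 + ff$grid_dx^2)[ff$valid]
  res_mag <- sqrt(ff$residual_dy^2 + ff$residual_dx^2)[ff$valid]
  expect_gt(max(raw_mag), 0.3)             # the rotation is visible raw
  expect_lt(stats::median(res_mag), 0.1)   # and gone after compensation
})

test_that("a local defect stays localized in the residual field", {
  a <- make_textured(800, seed = 33)
  b <- a
  b[241:480, 241:480] <- roll2(a[241:480, 241:480], c(3, 0))
  ff <- block_flow(a, b, block = 80)  # defect spans blocks 4:6 of 10
  st <- flow_stats(ff, pixel_size = 1)
  mag <- sqrt(ff$residual_dy^2 + ff$residual_dx^2)
  inside <- mag[4:6, 4:6]
  outside <- mag[ff$valid & (row(mag) <= 2 | row(mag) >= 9 |
                             col(mag) <= 2 | col(mag) >= 9)]
  expect_gt(stats::median(inside, na.rm = TRUE), 2)       # ~3 px defect
  expect_lt(stats::median(outside, na.rm = TRUE), 0.5)    # leakage stays small
  expect_lt(st$summary$median_um, 1)                      # overall median ~ 0
})

test_that("flow statistics convert to micrometres with the block median", {
  grid0 <- matrix(0, 4, 4)
  mk <- function(dy, dx, valid) structure(
    list(grid_dy = dy, grid_dx = dx, residual_dy = dy, residual_dx = dx,
         valid = valid, centers_y = grid0, centers_x = grid0,
         affine = NULL, block = 200L), class = "flow_field")
  all1 <- mk(matrix(1, 4, 4), grid0, matrix(TRUE, 4, 4))
  expect_equal(flow_stats(all1, 0.65)$summary$median_um, 0.65)
  half <- mk(rbind(matrix(0, 2, 4), matrix(2, 2, 4)), grid0,
             matrix(TRUE, 4, 4))
  expect_equal(flow_stats(half, 1)$summary$median_um, 1)  # midpoint of 0 and 2
  none <- mk(grid0, grid0, matrix(FALSE, 4, 4))
  expect_equal(flow_stats(none, 1)$summary$n_valid, 0L)
  expect_true(is.na(flow_stats(none, 1)$summary$median_um))
})

test_that("the heatmap raster encodes magnitude as intensity", {
  dy <- matrix(c(0, 1), 2, 2)
  ff <- structure(list(grid_dy = dy, grid_dx = dy * 0, residual_dy = dy,
                       residual_dx = dy * 0, valid = matrix(TRUE, 2, 2),
                       centers_y = dy, centers_x = dy, affine = NULL,
                       block = 200L), class = "flow_field")
  st <- flow_stats(ff, 1, clip_um = 1)
  hm <- st$heatmap
  expect_equal(dim(hm), c(2, 2, 3))
  expect_equal(max(hm[1, 1, ]), 0)  # zero vector renders black
  expect_gt(max(hm[2, 1, ]), 0.9)   # magnitude 1 at the clip renders bright
})

test_that("mosaic self-comparison stays below the sub-pixel resolution", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  m <- render(f$sa$tilesets[[1L]], sr$positions)
  ev <- evaluate_registration(m$channels[[1L]], m$channels[[1L]],
                              pixel_size = 1, block = 100)
  expect_lte(ev$summary$median_um, 0.1)
})
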