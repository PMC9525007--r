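# Mosaic rendering, blending, sub-pixel placement and re-tiling.

test_that("a single tile renders to itself", {
  img <- blob_image(64, 30, seed = 1)
  ts <- tileset(list(img), rbind(c(0, 0)), pixel_size = 1)
  m <- render(ts, rbind(c(0, 0)),
              canvas = list(origin = c(0, 0), dim = c(64L, 64L)))
  expect_equal(m$channels[[1L]], img)
})

test_that("linear blending ramps monotonically across an overlap", {
  a <- matrix(0.4, 60, 60)  # two constant tiles overlapping 10 px in x
  ts <- tileset(list(a, a * 2), rbind(c(0, 0), c(0, 50)), pixel_size = 1)
  m <- render(ts, ts$positions, blend = "linear")
  ov <- m$channels[[1L]][30, 51:60]  # the 10 overlap columns
  expect_true(all(diff(ov) > 0))
  expect_equal(mean(ov[5:6]), 0.6, tolerance = 0.02)  # midline ~ (a+b)/2
  expect_equal(m$channels[[1L]][30, 20], 0.4)
  expect_equal(m$channels[[1L]][30, 90], 0.8)
})

test_that("linear blend weights conserve a constant input", {
  f <- fixture_acq()
  ts <- f$sa$tilesets[[1L]]
  const <- tileset(replicate(n_tiles(ts), matrix(0.5, 100, 100),
                             simplify = FALSE),
                   ts$positions, ts$pixel_size)
  m <- render(const, fixture_stitch()$positions, blend = "linear",
              subpixel = TRUE)
  covered <- m$channels[[1L]] != 0
  expect_gt(mean(covered), 0.9)
  expect_equal(range(m$channels[[1L]][covered]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("integer positions make subpixel and rounded placement identical", {
  f <- fixture_acq()
  ts <- f$sa$tilesets[[1L]]
  pos <- round(fixture_stitch()$positions)  # integer um = integer px here
  m1 <- render(ts, pos, subpixel = TRUE)
  m2 <- render(ts, pos, subpixel = FALSE)
  expect_identical(m1$channels, m2$channels)
})

test_that("non-integer positions round half-even when subpixel is off", {
  img <- matrix(1, 8, 8)
  ts <- tileset(list(img, img), rbind(c(0, 0), c(10.5, 20.25)), pixel_size = 1)
  m <- render(ts, ts$positions, subpixel = FALSE, blend = "maximum")
  # tile 2 lands at (10, 20) 0-based -> rows 11:18, cols 21:28
  expect_equal(m$channels[[1L]][11, 21], 1)
  expect_equal(m$channels[[1L]][11, 20], 0)
  expect_equal(m$channels[[1L]][10, 21], 0)
})

test_that("the rendered mosaic reproduces the uncut scene over tissue", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  ts <- f$sa$tilesets[[1L]]
  m <- render(ts, sr$positions, blend = "linear")
  # reference: the noiseless scene, cropped at the truth-table anchor and
  # aligned to the mosaic (the mosaic frame has an arbitrary sub-pixel
  # global offset that must not count against fidelity)
  clean <- stitchreg:::render_scene(f$scene$spec, f$scene$nuclei)
  tp <- truth_positions(f$sa, 1)
  sceneshift <- tp[1, ] / ts$pixel_size  # scene px of tile 1
  d <- dim(m$channels[[1L]])
  anchor <- round((sr$positions[1, ] - m$origin) / ts$pixel_size)
  scene_crop <- clean[
    (sceneshift[1] - anchor[1] + 1):(sceneshift[1] - anchor[1] + d[1]),
    (sceneshift[2] - anchor[2] + 1):(sceneshift[2] - anchor[2] + d[2])]
  res <- phase_correlate(whiten(scene_crop), whiten(m$channels[[1L]]))
  aligned <- fourier_shift(m$channels[[1L]], -res$shift)
  interior <- matrix(FALSE, d[1], d[2])
  interior[11:(d[1] - 10), 11:(d[2] - 10)] <- TRUE
  tissue <- interior & m$channels[[1L]] > 0
  cc <- stats::cor(aligned[tissue], scene_crop[tissue])
  expect_gt(cc, 0.99)
})

test_that("retile covers the canvas with the documented origins", {
  m <- mosaic_image(list(matrix(runif(100 * 100), 100, 100)), pixel_size = 1)
  b0 <- retile(m, block = 50, overlap = 0)
  expect_equal(length(b0), 4L)
  b1 <- retile(m, block = 60, overlap = 10)
  origins <- t(vapply(b1, function(b) b$origin_px, numeric(2)))
  expect_equal(origins, rbind(c(0, 0), c(0, 50), c(50, 0), c(50, 50)))
  big <- retile(m, block = 500, overlap = 10)
  expect_equal(length(big), 1L)
  expect_error(retile(m, block = 10, overlap = 10), "block > overlap")
})

test_that("reassembling blocks restores the mosaic bit-exactly", {
  set.seed(5)
  for (k in 1:5) {
    d <- sample(40:130, 2)
    m <- mosaic_image(list(matrix(runif(prod(d)), d[1], d[2]),
                           matrix(runif(prod(d)), d[1], d[2])),
                      pixel_size = 0.65)
    block <- sample(16:70, 1)
    overlap <- sample(0:min(10, block - 1), 1)
    blocks <- retile(m, block, overlap)
    r <- reassemble(blocks, pixel_size = m$pixel_size)
    expect_identical(r$channels, m$channels)
  }
})

test_that("channel selection is honored and out-of-range channels error", {
  img <- array(runif(32 * 32 * 2), dim = c(32, 32, 2))
  ts <- tileset(list(img), rbind(c(0, 0)), pixel_size = 1,
                channel_names = c("DNA", "CD3"))
  m <- render(ts, rbind(c(0, 0)), channels = 2L,
              canvas = list(origin = c(0, 0), dim = c(32L, 32L)))
  expect_equal(length(m$channels), 1L)
  expect_equal(m$channel_names, "CD3")
  expect_equal(m$channels[[1L]], img[, , 2])
  expect_error(render(ts, rbind(c(0, 0)), channels = 3L), "out of range")
})
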