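# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

# A small 2-cycle acquisition with ground truth: 4x4 grid of 100x100 px
# tiles, 20 px overlap, 1.5 px jitter, 1.004 systematic scale, 20 um drift,
# 12% tissue loss in cycle 2.
fixture_acq <- function() {
  if (is.null(.fixtures$acq)) {
    acq <- acquisition_spec(rows = 4L, cols = 4L, tile_px = c(100L, 100L),
                            overlap_px = 24L, pixel_size = 1,
                            jitter_px = 1.5, scale = 1.004, cycles = 2L,
                            drift_um = 20, loss_fraction = 0.05, seed = 11L)
    sc <- make_scene(scene_spec(size = scene_size_for(acq),
                                nuclei_density = 50,
                                tile_px = c(100L, 100L), seed = 11L))
    .fixtures$acq <- list(acq = acq, scene = sc,
                          sa = cut_acquisition(sc, acq))
  }
  .fixtures$acq
}

fixture_stitch <- function() {
  if (is.null(.fixtures$sr)) {
    f <- fixture_acq()
    .fixtures$sr <- stitch(f$sa$tilesets[[1L]], n_pairs = 200L, seed = 5L)
  }
  .fixtures$sr
}

# Blob-dense test image: Gaussian-smoothed disks on a dark background,
# deterministic under seed.
blob_image <- function(size = 96L, n = 60L, seed = 1L, radius = 3) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  img <- matrix(0, size, size)
  cy <- runif(n, 5, size - 4)
  cx <- runif(n, 5, size - 4)
  amp <- runif(n, 0.5, 1)
  for (k in seq_len(n)) {
    ys <- max(1, floor(cy[k] - 3 * radius)):min(size, ceiling(cy[k] + 3 * radius))
    xs <- max(1, floor(cx[k] - 3 * radius)):min(size, ceiling(cx[k] + 3 * radius))
    img[ys, xs] <- img[ys, xs] +
      amp[k] * outer(exp(-(ys - cy[k])^2 / (2 * radius^2)),
                     exp(-(xs - cx[k])^2 / (2 * radius^2)))
  }
  pmin(img, 1)
}

# Circular roll: content moves by +s with periodic wrap.
roll2 <- function(m, s) {
  d <- dim(m)
  m[((seq_len(d[1]) - 1L - s[1]) %% d[1]) + 1L,
    ((seq_len(d[2]) - 1L - s[2]) %% d[2]) + 1L]
}

# Noise tileset on a regular grid (for permutation-threshold tests).
noise_tileset <- function(rows = 6L, cols = 6L, tile = 100L,
                          overlap = 0.1, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pos <- grid_positions(rows, cols, c(tile, tile), 1, overlap)
  tiles <- replicate(rows * cols,
                     matrix(runif(tile * tile), tile, tile),
                     simplify = FALSE)
  tileset(tiles, pos, pixel_size = 1)
}

quantize_unit_16 <- function(m) stitchreg:::quantize_unit(m, 16L)
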