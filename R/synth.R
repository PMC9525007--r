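# Synthetic multi-cycle acquisitions with known ground truth. The generator
# emulates the statistical structure the stitching model assumes:
# nuclei-dense fields with sparse or empty regions, small fractional tile
# overlaps, uncorrelated per-tile stage jitter, a small systematic affine
# stage error, inter-cycle global drift, per-cycle stain variation, and
# optional tissue loss between cycles.

#' Scene specification for the synthetic generator
#'
#' @param size scene size in pixels (scalar or (rows, cols)).
#' @param nuclei_density expected nuclei per tile of `tile_px` area.
#' @param tile_px tile shape used to interpret `nuclei_density`.
#' @param radius_range nucleus radius range in pixels (default 4--8).
#' @param background_amplitude amplitude of the smooth background field in
#'   [0, 1] intensity units.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param poisson logical; add Poisson photon noise.
#' @param tissue one of `"full"`, `"tma"` (two separated circular cores with
#'   blank lanes), `"diagonal"` (diagonal strip).
#' @param seed RNG seed; fixes the scene exactly.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(size = 1400L, nuclei_density = 80,
                       tile_px = c(200L, 200L), radius_range = c(4, 8),
                       background_amplitude = 0.15, noise_sd = 0.01,
                       poisson = FALSE,
                       tissue = c("full", "tma", "diagonal"), seed = 1L) {
  tissue <- match.arg(tissue)
  if (nuclei_density < 0) stop("nuclei_density must be >= 0")
  size <- rep(as.integer(size), length.out = 2L)
  structure(list(size = size, nuclei_density = nuclei_density,
                 tile_px = rep(as.integer(tile_px), length.out = 2L),
                 radius_range = radius_range,
                 background_amplitude = background_amplitude,
                 noise_sd = noise_sd, poisson = poisson,
                 tissue = tissue, seed = as.integer(seed)),
            class = "scene_spec")
}

# 0/1 tissue mask for a scene spec.
tissue_mask <- function(spec) {
  s <- spec$size
  y <- matrix(seq_len(s[1]), s[1], s[2])
  x <- matrix(seq_len(s[2]), s[1], s[2], byrow = TRUE)
  switch(spec$tissue,
    full = matrix(1, s[1], s[2]),
    tma = {
      r <- min(s) / 5.5
      c1 <- c(s[1] / 2, s[2] * 0.27)
      c2 <- c(s[1] / 2, s[2] * 0.73)
      m <- ((y - c1[1])^2 + (x - c1[2])^2 <= r^2) |
           ((y - c2[1])^2 + (x - c2[2])^2 <= r^2)
      m * 1
    },
    diagonal = {
      w <- min(s) / 4
      (abs((y / s[1]) - (x / s[2])) * min(s) <= w / 2) * 1
    })
}

# Render nuclei + background (no noise). factors scales per-nucleus
# intensity; loss_mask (0/1) zeroes detached-tissue patches.
render_scene <- function(spec, nuclei, factors = NULL, loss_mask = NULL) {
  s <- spec$size
  img <- matrix(0, s[1], s[2])
  if (nrow(nuclei) > 0L) {
    if (is.null(factors)) factors <- rep(1, nrow(nuclei))
    for (k in seq_len(nrow(nuclei))) {
      cy <- nuclei$y[k]; cx <- nuclei$x[k]; r <- nuclei$r[k]
      amp <- min(1, nuclei$intensity[k] * factors[k])
      ys <- max(1L, floor(cy - r - 2)):min(s[1], ceiling(cy + r + 2))
      xs <- max(1L, floor(cx - r - 2)):min(s[2], ceiling(cx + r + 2))
      dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
      disk <- amp * pmin(pmax(r + 0.5 - dist, 0), 1)  # anti-aliased edge
      img[ys, xs] <- pmax(img[ys, xs], disk)
    }
  }
  img <- gaussian_blur(img, 1)
  mask <- tissue_mask(spec)
  bg <- spec$background_amplitude *
    (0.4 + 0.35 * outer(seq_len(s[1]) / s[1], rep(1, s[2])) +
       0.25 * sin(outer(rep(1, s[1]), seq_len(s[2]) / s[2]) * 3 * pi))
  img <- pmin(img + bg * mask, 1)
  if (!is.null(loss_mask)) img <- img * loss_mask
  img
}

add_noise <- function(spec, img) {
  if (spec$poisson) {
    q <- 5000
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * q) / q,
                  nrow(img), ncol(img))
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                        nrow(img), ncol(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic tissue scene
#'
#' Renders anti-aliased, Gaussian-smoothed nuclear disks at Poisson-sampled
#' positions inside the tissue mask, over a smooth background field, with
#' read (and optionally photon) noise. Identical seeds give identical
#' scenes.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `synth_scene`: `img` (matrix in [0, 1]),
#'   `nuclei` (data frame of centers, radii, intensities), `spec`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    mask <- tissue_mask(spec)
    tissue_area <- sum(mask)
    rate <- spec$nuclei_density / prod(spec$tile_px)  # nuclei per tissue px
    n <- stats::rpois(1L, rate * tissue_area)
    nuclei <- data.frame(y = numeric(0L), x = numeric(0L),
                         r = numeric(0L), intensity = numeric(0L))
    if (n > 0L) {
      # rejection-sample centers inside the tissue mask
      ys <- numeric(0L); xs <- numeric(0L)
      while (length(ys) < n) {
        m <- (n - length(ys)) * 2L + 10L
        cy <- stats::runif(m, 1, spec$size[1])
        cx <- stats::runif(m, 1, spec$size[2])
        keep <- mask[cbind(ceiling(cy), ceiling(cx))] > 0
        ys <- c(ys, cy[keep]); xs <- c(xs, cx[keep])
      }
      nuclei <- data.frame(
        y = ys[seq_len(n)], x = xs[seq_len(n)],
        r = stats::runif(n, spec$radius_range[1], spec$radius_range[2]),
        intensity = stats::runif(n, 0.45, 0.95))
    }
    img <- add_noise(spec, render_scene(spec, nuclei))
    structure(list(img = img, nuclei = nuclei, spec = spec),
              class = "synth_scene")
  })
}

#' Acquisition specification for the synthetic generator
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: a 6x6 grid of 200x200 px tiles overlapping by
#' 31 px, stage jitter of 2 px, a 1.005 systematic scale error, two cycles
#' with 50 um inter-cycle drift and 10% tissue loss, at 0.65 um/px.
#'
#' @param rows,cols acquisition grid shape.
#' @param tile_px tile shape (rows, cols) in pixels.
#' @param overlap_px nominal overlap between adjacent tiles, pixels.
#' @param pixel_size micrometres per pixel.
#' @param jitter_px i.i.d. per-tile stage jitter standard deviation, pixels.
#' @param scale,rotation_deg systematic affine stage error: recorded
#'   positions are the true nominal grid mapped through the inverse of
#'   `scale * rotation`.
#' @param cycles number of imaging cycles (>= 1).
#' @param drift_um per-cycle global stage drift (y, x micrometres) relative
#'   to cycle 1; a scalar `d` is expanded to `(d, d)/sqrt(2)` per later
#'   cycle, or supply a `cycles x 2` matrix.
#' @param loss_fraction fraction of tissue area lost (zeroed) in each cycle
#'   after the first.
#' @param channels number of channels per tile (channel 1 is the alignment
#'   reference; extra channels reuse the nuclei with independent
#'   intensities).
#' @param seed RNG seed; all randomness derives from it.
#' @return a list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(rows = 6L, cols = 6L, tile_px = c(200L, 200L),
                             overlap_px = 31L, pixel_size = 0.65,
                             jitter_px = 2, scale = 1.005,
                             rotation_deg = 0, cycles = 2L, drift_um = 50,
                             loss_fraction = 0.1, channels = 1L,
                             seed = 1L) {
  tile_px <- rep(as.integer(tile_px), length.out = 2L)
  if (overlap_px < 0L || any(overlap_px >= tile_px))
    stop("overlap_px must be >= 0 and smaller than the tile extent")
  cycles <- as.integer(cycles)
  if (is.matrix(drift_um)) {
    stopifnot(nrow(drift_um) == cycles, ncol(drift_um) == 2L)
    drift <- drift_um
  } else {
    drift <- matrix(0, cycles, 2L)
    if (cycles > 1L)
      for (c in 2L:cycles)
        drift[c, ] <- (c - 1L) * rep(drift_um / sqrt(2), 2L)
  }
  theta <- rotation_deg * pi / 180
  A <- scale * matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                      2L, 2L, byrow = TRUE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 tile_px = tile_px, overlap_px = as.integer(overlap_px),
                 pixel_size = pixel_size, jitter_px = jitter_px,
                 A = A, cycles = cycles, drift_um = drift,
                 loss_fraction = loss_fraction,
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Scene size (pixels) needed to hold an acquisition
#'
#' Accounts for the grid footprint, the margin consumed by drift and
#' jitter, and a safety border.
#'
#' @param acq an [acquisition_spec()].
#' @return integer (rows, cols) scene size.
#' @export
scene_size_for <- function(acq) {
  stride <- acq$tile_px - acq$overlap_px
  foot <- c((acq$rows - 1L) * stride[1], (acq$cols - 1L) * stride[2]) +
    acq$tile_px
  drift_px <- max(abs(acq$drift_um)) / acq$pixel_size
  margin <- ceiling(drift_px + 5 * max(acq$jitter_px, 1) + 8)
  as.integer(foot + 2L * margin)
}

#' Cut a multi-cycle acquisition out of a scene
#'
#' Tiles are cut at integer-pixel true positions
#' `nominal grid + cycle drift + per-tile jitter`; recorded positions are
#' the nominal grid mapped through the inverse systematic affine, so the
#' stitcher must recover both the uncorrelated jitter and the systematic
#' model. Cycles after the first re-render the scene with per-nucleus
#' intensity jitter (plus or minus 20%, emulating stain variation) and zero
#' out detached-tissue patches covering `loss_fraction` of the tissue.
#' Read (and optional photon) noise is applied per tile, not per scene, so
#' the overlap strips of neighboring tiles carry independent noise as in a
#' real acquisition -- blank overlaps must not correlate.
#'
#' @param scene a `synth_scene` from [make_scene()] (its spec's noise model
#'   is reused per cycle).
#' @param acq an [acquisition_spec()]; the grid footprint (after drift and
#'   jitter) must fit inside the scene, otherwise a hard error.
#' @return list of class `synth_acquisition`: `tilesets` (one [tileset()]
#'   per cycle), `truth` (data frame: cycle, tile, true/recorded positions
#'   in micrometres), `transforms` (`A`, `b`, per-cycle realized drift,
#'   margin).
#' @export
cut_acquisition <- function(scene, acq) {
  stopifnot(inherits(scene, "synth_scene"), inherits(acq, "acquisition_spec"))
  spec <- scene$spec
  psz <- acq$pixel_size
  stride <- acq$tile_px - acq$overlap_px
  grid_px <- as.matrix(expand.grid(
    y = (seq_len(acq$rows) - 1L) * stride[1],
    x = (seq_len(acq$cols) - 1L) * stride[2]))[, c("y", "x")]
  grid_px <- grid_px[order(grid_px[, 1], grid_px[, 2]), , drop = FALSE]
  n <- nrow(grid_px)
  drift_px <- round(acq$drift_um / psz)
  margin <- ceiling(max(abs(drift_px)) + 5 * max(acq$jitter_px, 1) + 8)
  tilesets <- vector("list", acq$cycles)
  truth <- list()
  Ainv <- solve(acq$A)
  nominal_um <- (grid_px + margin) * psz
  recorded_um <- t(Ainv %*% t(nominal_um))
  realized_drift <- matrix(0, acq$cycles, 2L)
  for (cyc in seq_len(acq$cycles)) {
    res <- with_seed(acq$seed * 1000L + cyc, {
      jit_px <- matrix(round(stats::rnorm(2L * n, sd = acq$jitter_px)), n, 2L)
      true_px <- sweep(grid_px + margin + jit_px, 2L, drift_px[cyc, ], "+")
      if (any(true_px < 0L) ||
          any(sweep(true_px, 2L, acq$tile_px, "+") >
              matrix(spec$size, n, 2L, byrow = TRUE)))
        stop("acquisition footprint exceeds the scene; enlarge the scene ",
             "(see scene_size_for())")
      base_imgs <- vector("list", acq$channels)
      loss <- NULL
      if (cyc > 1L && acq$loss_fraction > 0) {
        loss <- sample_loss_mask(spec, acq$loss_fraction)
      }
      factors <- if (cyc == 1L) NULL else
        1 + stats::runif(nrow(scene$nuclei), -0.2, 0.2)
      base_imgs[[1L]] <- render_scene(spec, scene$nuclei, factors, loss)
      if (acq$channels > 1L) {
        for (ch in 2L:acq$channels) {
          f2 <- stats::runif(nrow(scene$nuclei), 0.1, 1)
          base_imgs[[ch]] <- render_scene(spec, scene$nuclei, f2, loss)
        }
      }
      tiles <- vector("list", n)
      for (i in seq_len(n)) {
        r <- (true_px[i, 1] + 1L):(true_px[i, 1] + acq$tile_px[1])
        cc <- (true_px[i, 2] + 1L):(true_px[i, 2] + acq$tile_px[2])
        # noise is applied per tile, not per scene: overlap strips of
        # neighboring tiles carry independent read noise, as in a real
        # acquisition (each tile is a separate exposure)
        planes <- lapply(base_imgs, function(im) add_noise(spec, im[r, cc]))
        tiles[[i]] <- array(unlist(planes),
                            dim = c(acq$tile_px, acq$channels))
      }
      list(tiles = tiles, true_px = true_px)
    })
    tilesets[[cyc]] <- tileset(
      res$tiles, recorded_um, psz, cycle_index = cyc - 1L,
      channel_names = c("DNA", if (acq$channels > 1L)
        paste0("marker-", seq_len(acq$channels - 1L))))
    realized_drift[cyc, ] <- drift_px[cyc, ] * psz
    truth[[cyc]] <- data.frame(
      cycle = cyc, tile = seq_len(n),
      true_y_um = res$true_px[, 1] * psz, true_x_um = res$true_px[, 2] * psz,
      recorded_y_um = recorded_um[, 1], recorded_x_um = recorded_um[, 2])
  }
  structure(list(tilesets = tilesets, truth = do.call(rbind, truth),
                 transforms = list(A = acq$A, b = c(0, 0),
                                   drift_um = realized_drift,
                                   margin_px = margin),
                 acq = acq),
            class = "synth_acquisition")
}

# Disk-shaped detached-tissue patches covering >= `fraction` of the tissue.
sample_loss_mask <- function(spec, fraction) {
  mask <- tissue_mask(spec)
  target <- fraction * sum(mask)
  loss <- matrix(1, spec$size[1], spec$size[2])
  removed <- 0
  guard <- 0L
  while (removed < target && guard < 200L) {
    guard <- guard + 1L
    cy <- stats::runif(1, 1, spec$size[1])
    cx <- stats::runif(1, 1, spec$size[2])
    if (mask[ceiling(cy), ceiling(cx)] == 0) next
    r <- stats::runif(1, 25, 55)
    ys <- max(1L, floor(cy - r)):min(spec$size[1], ceiling(cy + r))
    xs <- max(1L, floor(cx - r)):min(spec$size[2], ceiling(cx + r))
    patch <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+")) <= r
    newly <- sum(patch & loss[ys, xs] == 1 & mask[ys, xs] == 1)
    loss[ys, xs][patch] <- 0
    removed <- removed + newly
  }
  loss
}

#' Ground-truth positions for one cycle, as a matrix
#' @param sa a `synth_acquisition`.
#' @param cycle cycle number (1-based).
#' @return n x 2 matrix of true (y, x) positions in micrometres.
#' @export
truth_positions <- function(sa, cycle = 1L) {
  t <- sa$truth[sa$truth$cycle == cycle, ]
  cbind(t$true_y_um, t$true_x_um)
}
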