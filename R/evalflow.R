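# Registration-consistency metric: block-based dense flow between two
# mosaics. Each pair of corresponding non-overlapping blocks is aligned by
# phase correlation; a compensating affine (fitted by multiple linear
# regression of block shifts on block centers) absorbs any global rotation,
# scale or shear, and the residual magnitude per block is the local
# registration error. Blocks are processed independently, so the metric
# streams over arbitrarily large mosaics.

#' Global pre-alignment of two mosaics at reduced resolution
#'
#' Both mosaics are block-mean downsampled, whitened and phase-correlated;
#' the shift is rescaled to full-resolution pixels. Applied before block
#' flow so residuals measure local, not global, misalignment.
#'
#' @param a,b numeric matrices (single-channel mosaics of identical shape,
#'   same pixel size).
#' @param downsample integer factor (default 10); 1 gives direct phase
#'   correlation.
#' @param upsample sub-pixel factor.
#' @return length-2 numeric (dy, dx) in full-resolution pixels: the
#'   displacement of `b`'s content relative to `a`.
#' @export
global_prealign <- function(a, b, downsample = 10L, upsample = 10L) {
  if (!identical(dim(a), dim(b))) stop("mosaics must have identical shape")
  da <- downsample_mean(a, downsample)
  db <- downsample_mean(b, downsample)
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    warning("blank mosaic; global pre-alignment set to (0, 0)")
    return(c(0, 0))
  }
  pc <- phase_correlate(whiten(da), whiten(db), upsample)
  pc$shift * downsample
}

#' Block-dense flow field between two mosaics
#'
#' The mosaics are divided into non-overlapping `block` x `block` pixel
#' blocks; each corresponding pair is whitened and phase-correlated. Blocks
#' whose overlap carries no information (variance below `var_floor` after
#' whitening, undefined NCC, or under 8 px a side) are marked invalid and
#' excluded from all statistics. A compensating affine is fitted by multiple
#' linear regression of the valid shift vectors on block centers and
#' subtracted, yielding the residual field; with fewer than three
#' non-collinear valid blocks only the mean shift is removed.
#'
#' @param a,b single-channel mosaic matrices of identical shape, already
#'   globally pre-aligned (see [global_prealign()] and `prealign`).
#' @param block block edge length in pixels (default 200).
#' @param upsample sub-pixel factor.
#' @param prealign optional (dy, dx) full-resolution shift from
#'   [global_prealign()] applied to `b` (Fourier shift) before block flow.
#' @param max_block_shift shifts larger than this magnitude (pixels,
#'   default `block/4`) are treated as failed alignments (invalid block).
#' @param var_floor variance threshold for declaring a block blank.
#' @param min_coverage fraction of non-zero (imaged) pixels both blocks must
#'   contain; blocks straddling unimaged canvas or blank glass are invalid.
#' @return an object of class `flow_field`: `grid_dy`, `grid_dx` (per-block
#'   raw shifts, px), `residual_dy`, `residual_dx` (affine-compensated),
#'   `valid` (logical matrix), `centers_y`, `centers_x` (block centers, px),
#'   `affine` (the compensating fit), `block`.
#' @export
block_flow <- function(a, b, block = 200L, upsample = 10L, prealign = NULL,
                       max_block_shift = NULL, var_floor = 1e-12,
                       min_coverage = 0.75) {
  if (!identical(dim(a), dim(b))) stop("mosaics must have identical shape")
  if (!is.null(prealign) && any(prealign != 0)) {
    b <- fourier_shift(b, -prealign)
  }
  if (is.null(max_block_shift)) max_block_shift <- block / 4
  d <- dim(a)
  nby <- ceiling(d[1] / block); nbx <- ceiling(d[2] / block)
  dy <- dx <- matrix(NA_real_, nby, nbx)
  valid <- matrix(FALSE, nby, nbx)
  cy <- cx <- matrix(NA_real_, nby, nbx)
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    r <- ((by - 1L) * block + 1L):min(d[1], by * block)
    cc <- ((bx - 1L) * block + 1L):min(d[2], bx * block)
    cy[by, bx] <- mean(r); cx[by, bx] <- mean(cc)
    if (length(r) < 8L || length(cc) < 8L) next
    ba <- a[r, cc, drop = FALSE]
    bb <- b[r, cc, drop = FALSE]
    if (mean(ba != 0) < min_coverage || mean(bb != 0) < min_coverage) next
    wa <- whiten(ba)
    wb <- whiten(bb)
    if (stats::var(as.vector(wa)) < var_floor ||
        stats::var(as.vector(wb)) < var_floor) next
    pc <- phase_correlate(wa, wb, upsample)
    if (!is.finite(pc$error)) next
    if (sqrt(sum(pc$shift^2)) > max_block_shift) next
    dy[by, bx] <- pc$shift[1]; dx[by, bx] <- pc$shift[2]
    valid[by, bx] <- TRUE
  }
  # compensating affine: shift ~ block center
  rdy <- dy; rdx <- dx
  aff <- NULL
  v <- which(valid)
  if (length(v) >= 1L) {
    X <- cbind(1, cy[v], cx[v])
    if (length(v) >= 3L && qr(X)$rank == 3L) {
      fit <- stats::lm.fit(X, cbind(dy[v], dx[v]))
      pred <- X %*% fit$coefficients
      aff <- fit$coefficients
    } else {
      pred <- cbind(rep(mean(dy[v]), length(v)), rep(mean(dx[v]), length(v)))
    }
    rdy[v] <- dy[v] - pred[, 1]
    rdx[v] <- dx[v] - pred[, 2]
  }
  structure(list(grid_dy = dy, grid_dx = dx,
                 residual_dy = rdy, residual_dx = rdx,
                 valid = valid, centers_y = cy, centers_x = cx,
                 affine = aff, block = as.integer(block)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %dx%d blocks of %d px, %d valid\n",
              nrow(x$valid), ncol(x$valid), x$block, sum(x$valid)))
  invisible(x)
}

#' Summary statistics and heatmap for a flow field
#'
#' Residual magnitudes of valid blocks are converted to micrometres and
#' summarized (median and percentiles). The heatmap raster encodes flow
#' direction as hue and magnitude as intensity, with magnitudes clipped at
#' `clip_um` (or, when `NULL`, at the `clip_percentile` of the valid
#' magnitudes).
#'
#' @param field a `flow_field`.
#' @param pixel_size micrometres per mosaic pixel.
#' @param clip_percentile percentile used for clipping (default 90).
#' @param clip_um optional fixed clip value in micrometres.
#' @return list: `summary` (n_valid, median_um, p90_um, p99_um, max_um) and
#'   `heatmap` (blocks-y x blocks-x x 3 RGB array in [0, 1]; invalid blocks
#'   are black). `summary` fields are `NA` when no block is valid.
#' @export
flow_stats <- function(field, pixel_size, clip_percentile = 90,
                       clip_um = NULL) {
  v <- field$valid
  mag_px <- sqrt(field$residual_dy^2 + field$residual_dx^2)
  mag_um <- mag_px * pixel_size
  vm <- mag_um[v]
  if (length(vm) == 0L) {
    return(list(summary = list(n_valid = 0L, median_um = NA_real_,
                               p90_um = NA_real_, p99_um = NA_real_,
                               max_um = NA_real_),
                heatmap = array(0, dim = c(dim(v), 3L))))
  }
  qs <- stats::quantile(vm, c(0.9, 0.99), names = FALSE)
  if (is.null(clip_um))
    clip_um <- stats::quantile(vm, clip_percentile / 100, names = FALSE)
  clip_um <- max(clip_um, .Machine$double.eps)
  ang <- atan2(field$residual_dx, -field$residual_dy)  # hue from direction
  hue <- (ang / (2 * pi)) %% 1
  val <- pmin(mag_um / clip_um, 1)
  hm <- array(0, dim = c(dim(v), 3L))
  idx <- which(v)
  cols <- grDevices::col2rgb(grDevices::hsv(hue[idx], 1, val[idx])) / 255
  for (k in 1:3) {
    plane <- hm[, , k]
    plane[idx] <- cols[k, ]
    hm[, , k] <- plane
  }
  list(summary = list(n_valid = length(vm), median_um = stats::median(vm),
                      p90_um = qs[1], p99_um = qs[2], max_um = max(vm)),
       heatmap = hm)
}

#' Compare two single-channel mosaics end to end
#'
#' Runs [global_prealign()] then [block_flow()] and [flow_stats()].
#'
#' @param a,b mosaic matrices of identical shape.
#' @param pixel_size micrometres per pixel.
#' @param block block size in pixels (default 200).
#' @param downsample pre-alignment downsample factor (default 10).
#' @param upsample sub-pixel factor.
#' @return list with `prealign_px`, `field` and the elements of
#'   [flow_stats()].
#' @export
evaluate_registration <- function(a, b, pixel_size, block = 200L,
                                  downsample = 10L, upsample = 10L) {
  pre <- global_prealign(a, b, downsample, upsample)
  field <- block_flow(a, b, block = block, upsample = upsample,
                      prealign = pre)
  st <- flow_stats(field, pixel_size)
  c(list(prealign_px = pre, field = field), st)
}
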