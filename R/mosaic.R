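# Mosaic rendering: place tiles at corrected positions on a common canvas
# with optional sub-pixel translation and user-selectable blending, plus
# pyramid downsampling and block re-tiling.

#' Construct a MosaicImage
#'
#' @param channels list of numeric matrices of common shape (one per
#'   channel), values in [0, 1].
#' @param origin (y, x) of pixel (1,1) in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param channel_names character labels, one per channel.
#' @return an object of class `mosaic_image`.
#' @export
mosaic_image <- function(channels, origin = c(0, 0), pixel_size = 1,
                         channel_names = NULL) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("channels must be a non-empty list of matrices")
  d0 <- dim(channels[[1L]])
  if (!all(vapply(channels, function(m) identical(dim(m), d0), logical(1L))))
    stop("all channels must share one shape")
  if (is.null(channel_names))
    channel_names <- paste0("channel-", seq_along(channels))
  structure(list(channels = channels, origin = as.numeric(origin),
                 pixel_size = pixel_size,
                 channel_names = as.character(channel_names)),
            class = "mosaic_image")
}

#' @export
print.mosaic_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("mosaic_image: %dx%d px, %d channel(s), %.3f um/px, origin (%.1f, %.1f) um\n",
              d[1], d[2], length(x$channels), x$pixel_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Block-mean downsampling by an integer factor
#'
#' Partial edge blocks are averaged over the pixels they actually contain,
#' so output dimensions are `ceiling(dim / f)`.
#'
#' @param m numeric matrix.
#' @param f integer factor >= 1.
#' @return downsampled matrix.
#' @export
downsample_mean <- function(m, f) {
  f <- as.integer(f)
  if (f <= 1L) return(m)
  gr <- ceiling(seq_len(nrow(m)) / f)
  gc <- ceiling(seq_len(ncol(m)) / f)
  s <- rowsum(m, gr, reorder = TRUE)
  s <- t(rowsum(t(s), gc, reorder = TRUE))
  unname(s / outer(tabulate(gr), tabulate(gc)))
}

# Translate image content by a fractional (dy, dx) in [0, 1)^2 using
# bilinear interpolation with replicate edges: out(x) = img(x - frac).
shift_bilinear <- function(img, frac) {
  fy <- frac[1]; fx <- frac[2]
  if (fy == 0 && fx == 0) return(img)
  p <- pad_replicate(img, 1L)
  n1 <- nrow(img); n2 <- ncol(img)
  c00 <- p[2:(n1 + 1L), 2:(n2 + 1L)]  # img[r, c]
  c10 <- p[1:n1,        2:(n2 + 1L)]  # img[r-1, c]
  c01 <- p[2:(n1 + 1L), 1:n2]         # img[r, c-1]
  c11 <- p[1:n1,        1:n2]         # img[r-1, c-1]
  (1 - fy) * (1 - fx) * c00 + fy * (1 - fx) * c10 +
    (1 - fy) * fx * c01 + fy * fx * c11
}

# Distance-ramp blending weights for a tile: per-axis ramps rising from 1 at
# the border, so in any overlap the weights of the two tiles cross linearly.
tile_weights <- function(h, w) {
  outer(pmin(seq_len(h), h + 1L - seq_len(h)),
        pmin(seq_len(w), w + 1L - seq_len(w)))
}

#' Render tiles at corrected positions into a mosaic
#'
#' Creates a canvas spanning the union of all tile footprints and copies
#' each tile in at its corrected position. With `subpixel = TRUE` the
#' fractional part of each position is applied by bilinear interpolation;
#' otherwise positions are rounded to the nearest pixel (round-half-even).
#' Overlapping tiles are combined by the chosen blend:
#' `"linear"` -- distance-ramp weighted average (weights sum to 1
#' everywhere, so a constant input renders to a constant mosaic);
#' `"maximum"` -- pixelwise maximum; `"nearest"` -- the tile with the
#' nearest center wins.
#'
#' @param tilesets a [tileset()] or list of tilesets (e.g. one per cycle).
#' @param positions corrected positions: an n x 2 matrix, or a list of such
#'   matrices matching `tilesets`.
#' @param channels channel indices to render from each tileset (default:
#'   all). Out-of-range indices are an error.
#' @param subpixel logical, apply fractional translations (default TRUE).
#' @param blend `"linear"`, `"maximum"` or `"nearest"`.
#' @param canvas optional list(origin=, dim=) fixing the output frame
#'   (origin in micrometres, dim in pixels); used to render several cycles
#'   onto identical canvases.
#' @return a [mosaic_image()] whose channels are the selected channels of
#'   each tileset in order, named `cycle<k>_<channel name>` when more than
#'   one tileset is given.
#' @export
render <- function(tilesets, positions, channels = NULL, subpixel = TRUE,
                   blend = c("linear", "maximum", "nearest"), canvas = NULL) {
  blend <- match.arg(blend)
  if (inherits(tilesets, "tileset")) {
    tilesets <- list(tilesets)
    positions <- list(positions)
  }
  psz <- tilesets[[1L]]$pixel_size
  td <- tile_shape(tilesets[[1L]])
  for (ts in tilesets) {
    if (ts$pixel_size != psz) stop("all tilesets must share one pixel size")
    if (!identical(tile_shape(ts), td)) stop("all tilesets must share one tile shape")
  }
  if (is.null(canvas)) canvas <- mosaic_canvas(positions, td, psz)
  origin <- canvas$origin; cdim <- canvas$dim
  out_channels <- list(); out_names <- character(0L)
  multi <- length(tilesets) > 1L
  for (k in seq_along(tilesets)) {
    ts <- tilesets[[k]]
    pos <- positions[[k]]
    chs <- if (is.null(channels)) seq_len(n_channels(ts)) else channels
    if (any(chs < 1L | chs > n_channels(ts)))
      stop("channel index out of range")
    pos_px <- sweep(pos, 2L, origin) / psz
    ip <- if (subpixel) floor(pos_px) else round(pos_px)
    fr <- if (subpixel) pos_px - ip else matrix(0, nrow(pos), 2L)
    wt <- switch(blend, linear = tile_weights(td[1], td[2]),
                 maximum = NULL, nearest = NULL)
    for (ch in chs) {
      acc <- matrix(0, cdim[1], cdim[2])
      wacc <- matrix(0, cdim[1], cdim[2])
      for (i in seq_len(n_tiles(ts))) {
        img <- get_tile(ts, i, ch)
        if (subpixel) img <- shift_bilinear(img, fr[i, ])
        r <- (ip[i, 1] + 1L):(ip[i, 1] + td[1])
        cc <- (ip[i, 2] + 1L):(ip[i, 2] + td[2])
        ok_r <- r >= 1L & r <= cdim[1]
        ok_c <- cc >= 1L & cc <= cdim[2]
        if (!any(ok_r) || !any(ok_c)) next
        r <- r[ok_r]; cc <- cc[ok_c]
        img <- img[ok_r, ok_c, drop = FALSE]
        if (blend == "linear") {
          w <- wt[ok_r, ok_c, drop = FALSE]
          acc[r, cc] <- acc[r, cc] + w * img
          wacc[r, cc] <- wacc[r, cc] + w
        } else if (blend == "maximum") {
          acc[r, cc] <- pmax(acc[r, cc], img)
          wacc[r, cc] <- 1
        } else {  # nearest tile center wins
          cen <- c(mean(range(r)), mean(range(cc)))
          dmat <- outer((r - cen[1])^2, (cc - cen[2])^2, "+")
          w <- 1 / (1 + dmat)
          upd <- w > wacc[r, cc]
          sub <- acc[r, cc]; sub[upd] <- img[upd]
          acc[r, cc] <- sub
          subw <- wacc[r, cc]; subw[upd] <- w[upd]
          wacc[r, cc] <- subw
        }
      }
      if (blend == "linear") {
        nz <- wacc > 0
        acc[nz] <- acc[nz] / wacc[nz]
      }
      out_channels <- c(out_channels, list(acc))
      nm <- ts$channel_names[ch]
      out_names <- c(out_names, if (multi) sprintf("cycle%d_%s", k, nm) else nm)
    }
  }
  mosaic_image(out_channels, origin = origin, pixel_size = psz,
               channel_names = out_names)
}

#' Canvas frame spanning a set of corrected tile positions
#'
#' @param positions list of n x 2 position matrices (micrometres).
#' @param tile_px tile shape (rows, cols) in pixels.
#' @param pixel_size micrometres per pixel.
#' @return list(origin = (y, x) um, dim = (rows, cols) px).
#' @export
mosaic_canvas <- function(positions, tile_px, pixel_size) {
  allpos <- do.call(rbind, positions)
  origin <- apply(allpos, 2L, min)
  ext <- apply(allpos, 2L, max) - origin
  dimpx <- ceiling(ext / pixel_size) + tile_px + 1L
  list(origin = origin, dim = as.integer(dimpx))
}

#' Split a mosaic into overlapping blocks for parallel downstream processing
#'
#' Block origins advance with stride `block - overlap`; trailing blocks are
#' clipped to the canvas, so adjacent blocks share exactly `overlap` pixels
#' and the union of blocks covers the mosaic. [reassemble()] restores the
#' mosaic bit-exactly.
#'
#' @param mosaic a [mosaic_image()].
#' @param block block edge length in pixels (> overlap).
#' @param overlap shared pixels between adjacent blocks (>= 0).
#' @return list of blocks, each `list(channels=, origin_px=, origin_um=)`
#'   with `origin_px` 0-based (y, x) canvas offsets; plus attribute `dim`
#'   holding the canvas dimensions.
#' @export
retile <- function(mosaic, block, overlap = 0L) {
  stopifnot(inherits(mosaic, "mosaic_image"))
  block <- as.integer(block); overlap <- as.integer(overlap)
  if (overlap < 0L || block <= overlap) stop("need block > overlap >= 0")
  d <- dim(mosaic$channels[[1L]])
  starts <- function(n) {
    if (block >= n) return(0L)
    seq.int(0L, n - 1L, by = block - overlap)
  }
  sy <- starts(d[1]); sx <- starts(d[2])
  out <- list()
  for (y0 in sy) for (x0 in sx) {
    r <- (y0 + 1L):min(d[1], y0 + block)
    cc <- (x0 + 1L):min(d[2], x0 + block)
    out[[length(out) + 1L]] <- list(
      channels = lapply(mosaic$channels, function(m) m[r, cc, drop = FALSE]),
      origin_px = c(y0, x0),
      origin_um = mosaic$origin + c(y0, x0) * mosaic$pixel_size)
  }
  attr(out, "canvas_dim") <- d
  attr(out, "block") <- block
  attr(out, "overlap") <- overlap
  out
}

#' Reassemble blocks produced by [retile()]
#'
#' @param blocks the list returned by [retile()].
#' @param pixel_size,origin,channel_names metadata for the rebuilt mosaic.
#' @return a [mosaic_image()] bit-identical to the retiled input.
#' @export
reassemble <- function(blocks, pixel_size = 1, origin = c(0, 0),
                       channel_names = NULL) {
  d <- attr(blocks, "canvas_dim")
  nc <- length(blocks[[1L]]$channels)
  chans <- lapply(seq_len(nc), function(ch) {
    m <- matrix(0, d[1], d[2])
    for (b in blocks) {
      bd <- dim(b$channels[[ch]])
      r <- (b$origin_px[1] + 1L):(b$origin_px[1] + bd[1])
      cc <- (b$origin_px[2] + 1L):(b$origin_px[2] + bd[2])
      m[r, cc] <- b$channels[[ch]]
    }
    m
  })
  mosaic_image(chans, origin = origin, pixel_size = pixel_size,
               channel_names = channel_names)
}
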