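# TileSet: one imaging cycle's tiles, recorded stage positions and physical
# pixel size. Positions are (y, x) in micrometres, y increasing downward,
# everywhere in the package; conversion to pixels happens only inside
# alignment operations.

#' Construct a TileSet
#'
#' @param tiles list of tiles; each tile is a numeric matrix (single channel)
#'   or an H x W x C array. All tiles must share one shape. Values are
#'   intensities in [0, 1] (the TIFF convention used throughout).
#' @param positions n x 2 numeric matrix of recorded stage positions
#'   (y, x) in micrometres.
#' @param pixel_size micrometres per pixel (scalar, isotropic, > 0).
#' @param cycle_index integer >= 0 identifying the acquisition cycle.
#' @param channel_names character vector, one per channel.
#' @param ref_channel index of the channel used for alignment (default 1).
#' @return an object of class `tileset`.
#' @export
tileset <- function(tiles, positions, pixel_size, cycle_index = 0L,
                    channel_names = NULL, ref_channel = 1L) {
  if (!is.list(tiles) || length(tiles) == 0L)
    stop("tiles must be a non-empty list")
  tiles <- lapply(tiles, function(t) {
    if (is.matrix(t)) t <- array(t, dim = c(dim(t), 1L))
    if (length(dim(t)) != 3L) stop("each tile must be a matrix or 3-D array")
    t
  })
  d0 <- dim(tiles[[1L]])
  if (!all(vapply(tiles, function(t) identical(dim(t), d0), logical(1L))))
    stop("all tiles must share one shape")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(tiles) || ncol(positions) != 2L)
    stop("positions must be an n x 2 matrix matching the tile count")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (micrometres per pixel)")
  if (anyDuplicated(positions))
    warning("duplicate recorded positions present")
  if (is.null(channel_names))
    channel_names <- paste0("channel-", seq_len(d0[3]))
  if (length(channel_names) != d0[3])
    stop("channel_names must match the channel count")
  ref_channel <- as.integer(ref_channel)
  if (ref_channel < 1L || ref_channel > d0[3])
    stop("ref_channel out of range")
  structure(list(
    tiles = tiles,
    positions = unname(positions),
    pixel_size = pixel_size,
    cycle_index = as.integer(cycle_index),
    channel_names = as.character(channel_names),
    ref_channel = ref_channel
  ), class = "tileset")
}

#' Number of tiles in a TileSet
#' @param ts a `tileset`.
#' @return integer tile count.
#' @export
n_tiles <- function(ts) length(ts$tiles)

#' Tile dimensions (rows, cols) in pixels
#' @param ts a `tileset`.
#' @return integer length-2 vector.
#' @export
tile_shape <- function(ts) dim(ts$tiles[[1L]])[1:2]

#' Number of channels
#' @param ts a `tileset`.
#' @return integer channel count.
#' @export
n_channels <- function(ts) dim(ts$tiles[[1L]])[3]

#' Extract one channel of one tile as a matrix
#' @param ts a `tileset`.
#' @param i tile index.
#' @param channel channel index; defaults to the alignment reference channel.
#' @return numeric matrix.
#' @export
get_tile <- function(ts, i, channel = ts$ref_channel) {
  ts$tiles[[i]][, , channel]
}

#' @export
print.tileset <- function(x, ...) {
  d <- tile_shape(x)
  cat(sprintf(
    "tileset: %d tiles of %dx%d px, %d channel(s), cycle %d, %.3f um/px\n",
    n_tiles(x), d[1], d[2], n_channels(x), x$cycle_index, x$pixel_size))
  invisible(x)
}

#' Compute nominal grid positions for a regular acquisition
#'
#' Positions are laid out row-major with stride
#' `tile_extent * (1 - overlap)` in micrometres, following raster
#' (left-to-right every row) or serpentine (alternate rows reversed)
#' acquisition order.
#'
#' @param rows,cols grid dimensions.
#' @param tile_px tile shape (rows, cols) in pixels.
#' @param pixel_size micrometres per pixel.
#' @param overlap fractional overlap between adjacent tiles in [0, 1).
#' @param order `"raster"` or `"serpentine"`.
#' @return n x 2 matrix of (y, x) positions in micrometres, in acquisition
#'   order.
#' @export
grid_positions <- function(rows, cols, tile_px, pixel_size,
                           overlap = 0.1, order = c("raster", "serpentine")) {
  order <- match.arg(order)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  tile_px <- rep(as.numeric(tile_px), length.out = 2L)
  stride <- tile_px * pixel_size * (1 - overlap)  # (y, x) um
  pos <- matrix(0, rows * cols, 2L)
  k <- 1L
  for (r in seq_len(rows)) {
    cs <- seq_len(cols)
    if (order == "serpentine" && r %% 2L == 0L) cs <- rev(cs)
    for (cc in cs) {
      pos[k, ] <- c((r - 1L) * stride[1], (cc - 1L) * stride[2])
      k <- k + 1L
    }
  }
  pos
}
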