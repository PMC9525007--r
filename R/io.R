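# Tile-set reading (TIFF files + position table or grid spec) and
# pyramidal OME-TIFF mosaic output.
#
# Pixel values follow the r-tiff convention: doubles in [0, 1], with integer
# sample formats stored as value / (2^bits - 1). uint8/uint16 data therefore
# round-trips bit-exactly; float32 at single precision.

# Expand a filename template such as "tile_{series:03d}.tif". Placeholders:
# {series} (required), {cycle}, {channel}; an optional ":0Nd" suffix gives
# printf-style zero padding.
expand_template <- function(pattern, series, cycle = NA, channel = NA) {
  out <- pattern
  sub1 <- function(s, name, value) {
    rx <- paste0("\\{", name, "(:0?([0-9]+)d)?\\}")
    m <- regmatches(s, regexec(rx, s))[[1]]
    while (length(m) > 0) {
      width <- if (m[3] == "") 0L else as.integer(m[3])
      rep_ <- if (width > 0L)
        formatC(value, width = width, flag = "0", format = "d")
      else as.character(as.integer(value))
      s <- sub(rx, rep_, s)
      m <- regmatches(s, regexec(rx, s))[[1]]
    }
    s
  }
  out <- sub1(out, "series", series)
  if (!is.na(cycle)) out <- sub1(out, "cycle", cycle)
  if (!is.na(channel)) out <- sub1(out, "channel", channel)
  out
}

read_tile_file <- function(path) {
  if (!file.exists(path)) stop("missing tile file: ", path)
  img <- tiff::readTIFF(path, all = TRUE)
  if (is.list(img)) img <- img[[1L]]
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # gray from RGB(A)
  img
}

#' Read a tile set from a directory of TIFF files
#'
#' Tiles are located by a filename template with a `{series}` placeholder
#' (printf-style zero padding via `{series:03d}`), plus optional `{cycle}`
#' and `{channel}` placeholders. Recorded stage positions come either from a
#' CSV position table with header `index,y_um,x_um` (the `index` column
#' supplies the `{series}` values) or from a regular-grid specification
#' `list(rows, cols, overlap, order)` with series numbered 1..rows*cols in
#' acquisition order (see [grid_positions()]).
#'
#' @param root_path directory containing the tile files.
#' @param pattern filename template, e.g. `"tile_{series:03d}.tif"`.
#' @param positions path to a position-table CSV, or a list
#'   `list(rows=, cols=, overlap=, order=)` describing a regular grid.
#' @param pixel_size micrometres per pixel; required, never guessed.
#' @param cycle_index cycle number substituted for `{cycle}` and recorded in
#'   the result.
#' @param channels number of channels to read when the pattern contains
#'   `{channel}` (numbered from 1); default 1.
#' @param channel_names optional channel labels.
#' @return a [tileset()].
#' @export
read_tileset <- function(root_path, pattern, positions, pixel_size,
                         cycle_index = 0L, channels = 1L,
                         channel_names = NULL) {
  if (missing(pixel_size) || is.null(pixel_size))
    stop("pixel_size is required (micrometres per pixel)")
  if (is.character(positions) && length(positions) == 1L) {
    tab <- utils::read.csv(positions)
    need <- c("index", "y_um", "x_um")
    if (!all(need %in% names(tab)))
      stop("position table must have columns index,y_um,x_um")
    series <- tab$index
    pos <- cbind(tab$y_um, tab$x_um)
  } else if (is.list(positions)) {
    probe <- file.path(root_path,
                       expand_template(pattern, 1, cycle_index,
                                       if (channels > 0) 1 else NA))
    if (!file.exists(probe)) stop("missing tile file: ", probe)
    d0 <- dim(read_tile_file(probe))
    ord <- if (is.null(positions$order)) "raster" else positions$order
    pos <- grid_positions(positions$rows, positions$cols, d0,
                          pixel_size, positions$overlap, ord)
    series <- seq_len(nrow(pos))
  } else stop("positions must be a CSV path or a grid spec list")
  has_channel <- grepl("\\{channel", pattern)
  tiles <- vector("list", length(series))
  for (k in seq_along(series)) {
    chs <- if (has_channel) seq_len(channels) else 1L
    planes <- lapply(chs, function(ch) {
      f <- file.path(root_path,
                     expand_template(pattern, series[k], cycle_index,
                                     if (has_channel) ch else NA))
      read_tile_file(f)
    })
    d <- dim(planes[[1L]])
    if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1L))))
      stop("non-uniform tile shapes within series ", series[k])
    tiles[[k]] <- array(unlist(planes), dim = c(d, length(planes)))
  }
  dims <- vapply(tiles, function(t) dim(t)[1:2], numeric(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("non-uniform tile shapes across the tile set")
  tileset(tiles, pos, pixel_size, cycle_index = cycle_index,
          channel_names = channel_names)
}

#' Write a tile set to a directory of TIFF files plus a position table
#'
#' The on-disk dialect is the one [read_tileset()] reads: one (multi-channel
#' via `{channel}`) TIFF per tile and a `positions.csv` with header
#' `index,y_um,x_um`.
#'
#' @param ts a [tileset()].
#' @param dir output directory (created if needed).
#' @param pattern filename template; must contain `{series}` and, for
#'   multi-channel sets, `{channel}`.
#' @param bits bits per sample (8, 16 or 32).
#' @return the directory path, invisibly.
#' @export
write_tileset <- function(ts, dir, pattern = "tile_{series:03d}_ch{channel}.tif",
                          bits = 16L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(n_tiles(ts))) {
    for (ch in seq_len(n_channels(ts))) {
      f <- file.path(dir, expand_template(pattern, k, ts$cycle_index, ch))
      img <- quantize_unit(get_tile(ts, k, ch), bits)
      tiff::writeTIFF(img, f, bits.per.sample = as.integer(bits),
                      compression = "none")
    }
  }
  utils::write.csv(
    data.frame(index = seq_len(n_tiles(ts)),
               y_um = ts$positions[, 1], x_um = ts$positions[, 2]),
    file.path(dir, "positions.csv"), row.names = FALSE)
  invisible(dir)
}

# Clamp to [0,1] and snap to the representable grid of the target bit depth
# so that write/read round-trips are exact.
quantize_unit <- function(m, bits) {
  m <- pmin(pmax(m, 0), 1)
  if (bits >= 32) return(m)
  mx <- 2^bits - 1
  round(m * mx) / mx
}

## ---- OME-TIFF mosaics -----------------------------------------------------

ome_dtype <- function(bits) {
  switch(as.character(bits), "8" = "uint8", "16" = "uint16", "32" = "float",
         stop("unsupported bit depth: ", bits))
}

build_ome_xml <- function(size_y, size_x, channel_names, pixel_size, bits,
                          n_levels) {
  ch <- paste0(vapply(seq_along(channel_names), function(i) sprintf(
    '<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
    i - 1L, channel_names[i]), character(1L)), collapse = "")
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06" ',
    'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
    'xsi:schemaLocation="http://www.openmicroscopy.org/Schemas/OME/2016-06 ',
    'http://www.openmicroscopy.org/Schemas/OME/2016-06/ome.xsd">',
    '<Image ID="Image:0" Name="mosaic">',
    '<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="%s" ',
    'SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="1" SizeT="1" ',
    'PhysicalSizeX="%g" PhysicalSizeXUnit="µm" ',
    'PhysicalSizeY="%g" PhysicalSizeYUnit="µm">',
    '%s<TiffData/></Pixels></Image>',
    '<StructuredAnnotations><XMLAnnotation ID="Annotation:PyramidLevels">',
    '<Value><PyramidLevels>%d</PyramidLevels></Value>',
    '</XMLAnnotation></StructuredAnnotations>',
    '</OME>'),
    ome_dtype(bits), size_x, size_y, length(channel_names),
    pixel_size, pixel_size, ch, n_levels)
}

# Rewrite the ImageDescription (tag 270) of the first IFD of a TIFF file in
# place: a new IFD (original entries minus any existing tag 270, plus the new
# one, sorted by tag) and the text are appended at the end of the file and
# the header's IFD pointer is redirected. r-tiff's writer cannot emit this
# tag itself.
tiff_set_description <- function(path, text) {
  sz <- file.info(path)$size
  con <- file(path, open = "r+b")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 8L)
  endian <- if (rawToChar(hdr[1:2]) == "II") "little" else "big"
  rint <- function(raw, size) readBin(raw, "integer", n = length(raw) %/% size,
                                      size = size, endian = endian,
                                      signed = size > 2)
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = endian)
  ifd0 <- rint(hdr[5:8], 4L)
  seek(con, ifd0)
  nent <- rint(readBin(con, "raw", n = 2L), 2L)
  entries <- readBin(con, "raw", n = 12L * nent)
  nxt <- readBin(con, "raw", n = 4L)
  tags <- vapply(seq_len(nent), function(i)
    rint(entries[(12L * (i - 1L) + 1L):(12L * (i - 1L) + 2L)], 2L), integer(1L))
  keep <- which(tags != 270L)
  desc <- c(charToRaw(text), as.raw(0L))
  # layout: [new IFD][desc bytes] appended at an even offset past EOF
  ifd_new <- sz + (sz %% 2L)
  n_new <- length(keep) + 1L
  desc_off <- ifd_new + 2L + 12L * n_new + 4L
  seek(con, ifd_new, rw = "write")
  wint(n_new, 2L)
  # entries sorted by tag; 270 inserted in order
  ord_tags <- c(tags[keep], 270L)
  ord <- order(ord_tags)
  for (i in ord) {
    if (i <= length(keep)) {
      k <- keep[i]
      writeBin(entries[(12L * (k - 1L) + 1L):(12L * k)], con)
    } else {
      wint(270L, 2L)           # tag
      wint(2L, 2L)             # type ASCII
      wint(length(desc), 4L)   # count
      wint(desc_off, 4L)       # value offset
    }
  }
  writeBin(nxt, con)
  seek(con, desc_off, rw = "write")
  writeBin(desc, con)
  seek(con, 4L, rw = "write")
  wint(ifd_new, 4L)
  invisible(path)
}

#' Write a multichannel mosaic as a pyramidal OME-TIFF
#'
#' Channels of the full-resolution image are written first, followed by the
#' channels of each pyramid level; levels are produced by 2x2 mean
#' downsampling (antialiased) until both dimensions are at most
#' `max_level_px`. OME-XML metadata (channel names, physical pixel size in
#' micrometres, pixel type, level count) is embedded in the ImageDescription
#' of the first page. Level-0 pixels round-trip bit-exactly for data on the
#' representable grid of the chosen bit depth.
#'
#' @param mosaic a [mosaic_image()].
#' @param path output file path (conventionally `.ome.tif`).
#' @param bits bits per sample: 8, 16 (default) or 32 (float).
#' @param pyramid logical; write downsampled levels (default TRUE).
#' @param max_level_px stop the pyramid when both dimensions are <= this.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(mosaic, path, bits = 16L, pyramid = TRUE,
                         max_level_px = 1024L) {
  stopifnot(inherits(mosaic, "mosaic_image"))
  chans <- lapply(mosaic$channels, quantize_unit, bits = bits)
  levels <- list(chans)
  if (pyramid) {
    cur <- chans
    while (any(dim(cur[[1L]]) > max_level_px) && all(dim(cur[[1L]]) > 1L)) {
      cur <- lapply(cur, downsample_mean, f = 2L)
      levels <- c(levels, list(cur))
    }
  }
  pages <- do.call(c, levels)
  n <- tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                       compression = "none", reduce = FALSE)
  if (n != length(pages)) stop("failed to write all pages to ", path)
  xml <- build_ome_xml(nrow(chans[[1L]]), ncol(chans[[1L]]),
                       mosaic$channel_names, mosaic$pixel_size, bits,
                       length(levels))
  tiff_set_description(path, xml)
  invisible(path)
}

#' Read a mosaic written by [write_mosaic()]
#'
#' @param path OME-TIFF file path.
#' @return a [mosaic_image()] holding the level-0 channels, with the pyramid
#'   (list of per-level channel lists) in `$pyramid` and the raw OME-XML in
#'   `$ome_xml`.
#' @export
read_mosaic <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  xml <- attr(pages[[1L]], "description")
  meta <- parse_ome_xml(xml)
  nc <- meta$size_c
  n_levels <- length(pages) %/% nc
  pyramid <- lapply(seq_len(n_levels), function(l) {
    lapply(seq_len(nc), function(ch) {
      m <- pages[[(l - 1L) * nc + ch]]
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      m[, , drop = FALSE][, ]  # strip attributes
    })
  })
  out <- mosaic_image(pyramid[[1L]], origin = c(0, 0),
                      pixel_size = meta$pixel_size,
                      channel_names = meta$channel_names)
  out$pyramid <- pyramid
  out$ome_xml <- xml
  out
}

parse_ome_xml <- function(xml) {
  if (is.null(xml) || !nzchar(xml)) stop("no OME-XML description present")
  grab <- function(attr) {
    m <- regmatches(xml, regexec(paste0(attr, '="([^"]*)"'), xml))[[1L]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  ch <- regmatches(xml, gregexec('<Channel [^>]*Name="([^"]*)"', xml))[[1L]]
  list(size_c = as.integer(grab("SizeC")),
       size_x = as.integer(grab("SizeX")),
       size_y = as.integer(grab("SizeY")),
       pixel_size = as.numeric(grab("PhysicalSizeX")),
       channel_names = if (is.matrix(ch)) ch[2L, ] else character(0L))
}
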