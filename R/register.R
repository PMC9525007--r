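# Registration of later imaging cycles against the stitched first cycle:
# coarse thumbnail alignment recovers inter-cycle stage drift, recorded
# positions establish tile correspondences, and each corresponding pair is
# aligned by phase correlation with an affine fallback for tiles whose
# tissue is uninformative.

#' Assemble a low-resolution thumbnail mosaic from recorded positions
#'
#' Each tile's reference channel is block-mean downsampled and placed at its
#' recorded position on a shared canvas; overlaps are averaged.
#'
#' @param ts a [tileset()].
#' @param downsample integer downsampling factor.
#' @param origin canvas origin (y, x micrometres); defaults to the minimum
#'   recorded position.
#' @param dim_px canvas size in thumbnail pixels; computed when `NULL`.
#' @return list(img = matrix, origin = , pixel_size = thumbnail um/px).
#' @export
build_thumbnail <- function(ts, downsample = 20L, origin = NULL,
                            dim_px = NULL) {
  tpsz <- ts$pixel_size * downsample
  td <- ceiling(tile_shape(ts) / downsample)
  if (is.null(origin)) origin <- apply(ts$positions, 2L, min)
  if (is.null(dim_px)) {
    ext <- apply(ts$positions, 2L, max) - origin
    dim_px <- as.integer(ceiling(ext / tpsz) + td + 1L)
  }
  acc <- matrix(0, dim_px[1], dim_px[2])
  cnt <- matrix(0, dim_px[1], dim_px[2])
  for (i in seq_len(n_tiles(ts))) {
    small <- downsample_mean(get_tile(ts, i), downsample)
    ip <- round((ts$positions[i, ] - origin) / tpsz)
    r <- (ip[1] + 1L):(ip[1] + nrow(small))
    cc <- (ip[2] + 1L):(ip[2] + ncol(small))
    ok_r <- r >= 1L & r <= dim_px[1]
    ok_c <- cc >= 1L & cc <= dim_px[2]
    r <- r[ok_r]; cc <- cc[ok_c]
    acc[r, cc] <- acc[r, cc] + small[ok_r, ok_c, drop = FALSE]
    cnt[r, cc] <- cnt[r, cc] + 1
  }
  nz <- cnt > 0
  acc[nz] <- acc[nz] / cnt[nz]
  list(img = acc, origin = origin, pixel_size = tpsz)
}

#' Coarse inter-cycle alignment on thumbnail mosaics
#'
#' Both cycles' thumbnails are assembled on a common canvas from recorded
#' positions, whitened, and phase-correlated with sub-pixel precision. The
#' returned `coarse_shift` is the inter-cycle stage drift in micrometres:
#' the displacement of the target cycle's recorded coordinates relative to
#' the reference cycle's recorded coordinates of the same physical location
#' (so the reference-frame position of a target tile is its recorded
#' position minus `coarse_shift`).
#'
#' @param ref,target [tileset()]s with the same pixel size.
#' @param downsample thumbnail factor (default 20).
#' @param upsample sub-pixel factor for the thumbnail correlation.
#' @return length-2 numeric (dy, dx) micrometres; (0, 0) with a warning when
#'   a thumbnail is blank.
#' @export
coarse_align <- function(ref, target, downsample = 20L, upsample = 10L) {
  if (ref$pixel_size != target$pixel_size)
    stop("tilesets must share one pixel size")
  origin <- pmin(apply(ref$positions, 2L, min),
                 apply(target$positions, 2L, min))
  ext <- pmax(apply(ref$positions, 2L, max),
              apply(target$positions, 2L, max)) - origin
  tpsz <- ref$pixel_size * downsample
  td <- ceiling(tile_shape(ref) / downsample)
  dim_px <- as.integer(ceiling(ext / tpsz) + td + 1L)
  ta <- build_thumbnail(ref, downsample, origin, dim_px)
  tb <- build_thumbnail(target, downsample, origin, dim_px)
  if (stats::sd(ta$img) == 0 || stats::sd(tb$img) == 0) {
    warning("blank thumbnail; coarse shift set to (0, 0)")
    return(c(0, 0))
  }
  pc <- phase_correlate(whiten(ta$img), whiten(tb$img), upsample)
  if (!is.finite(pc$error)) {
    warning("uninformative thumbnails; coarse shift set to (0, 0)")
    return(c(0, 0))
  }
  # target content displaced by d um appears in its thumbnail at -d/tpsz
  # relative to the reference thumbnail (recorded placement cancels it),
  # hence drift = -shift * tpsz... placement uses recorded positions, so a
  # pure recorded-coordinate offset moves the placement, not the content:
  # thumbnail B = translate(A, drift/tpsz) and drift = shift * tpsz.
  pc$shift * tpsz
}

#' Map each target-cycle tile to its corresponding reference-cycle tile
#'
#' Each target tile maps to the reference tile minimizing the distance
#' between the target's drift-corrected recorded position
#' (`recorded - coarse_shift`) and the reference recorded position. The
#' mapping may be many-to-one; ties resolve to the lowest reference index.
#'
#' @param ref,target [tileset()]s.
#' @param coarse_shift inter-cycle drift from [coarse_align()], micrometres.
#' @return integer vector: reference tile index per target tile.
#' @export
find_correspondences <- function(ref, target, coarse_shift = c(0, 0)) {
  adj <- sweep(target$positions, 2L, coarse_shift)
  vapply(seq_len(nrow(adj)), function(t) {
    d2 <- colSums((t(ref$positions) - adj[t, ])^2)
    which.min(d2)
  }, integer(1L))
}

#' Register a target cycle's tiles against the stitched first cycle
#'
#' Each corresponding tile pair is cropped to its mutual overlap (reference
#' tile at its corrected position, target tile at its drift-corrected
#' expected position), whitened and phase-correlated. When the measured
#' positional correction is within `max_shift` micrometres, the target tile
#' is placed at the reference tile's corrected position plus the measured
#' offset (`source = "aligned"`); otherwise -- including blank or
#' uninformative pairs -- it falls back to the first cycle's affine stage
#' model applied to the drift-corrected recorded position
#' (`source = "affine_fallback"`). No permutation threshold is applied in
#' this phase; the translation limit alone filters spurious alignments.
#'
#' @param ref_ts reference-cycle [tileset()].
#' @param sr first-cycle `stitch_result` (for corrected positions and the
#'   affine model).
#' @param target target-cycle [tileset()].
#' @param max_shift translation limit, micrometres (default 15).
#' @param downsample thumbnail factor for [coarse_align()].
#' @param upsample sub-pixel factor.
#' @param coarse_shift override the thumbnail drift estimate (micrometres).
#' @return an object of class `registration_result`: `positions` (n x 2
#'   micrometres), `source` (per-tile `"aligned"`/`"affine_fallback"`),
#'   `coarse_shift`, `correspondences`, `shift_um` (per-tile measured
#'   correction magnitude; `NA` for fallbacks).
#' @export
register_tiles <- function(ref_ts, sr, target, max_shift = 15,
                           downsample = 20L, upsample = 10L,
                           coarse_shift = NULL) {
  if (is.null(coarse_shift))
    coarse_shift <- coarse_align(ref_ts, target, downsample, upsample)
  corr <- find_correspondences(ref_ts, target, coarse_shift)
  n <- n_tiles(target)
  expected <- predict_affine(sr$affine,
                             sweep(target$positions, 2L, coarse_shift))
  positions <- expected
  source <- rep("affine_fallback", n)
  shift_um <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    r <- corr[t]
    al <- align_pair(get_tile(ref_ts, r), sr$positions[r, ],
                     get_tile(target, t), expected[t, ],
                     target$pixel_size, pad_um = max_shift,
                     upsample = upsample)
    if (is.null(al) || !is.finite(al$error)) next
    cand <- sr$positions[r, ] + al$offset_um
    mag <- sqrt(sum((cand - expected[t, ])^2))
    if (mag <= max_shift) {
      positions[t, ] <- cand
      source[t] <- "aligned"
      shift_um[t] <- mag
    }
  }
  structure(list(positions = positions, source = source,
                 coarse_shift = coarse_shift, correspondences = corr,
                 shift_um = shift_um),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: %d tiles (%d aligned, %d affine fallback), coarse drift (%.2f, %.2f) um\n",
    length(x$source), sum(x$source == "aligned"),
    sum(x$source == "affine_fallback"),
    x$coarse_shift[1], x$coarse_shift[2]))
  invisible(x)
}

#' Registration report as a plain list (JSON-ready)
#' @param rr a `registration_result`.
#' @return a list serializable with `jsonlite::write_json()`.
#' @export
register_report <- function(rr) {
  list(coarse_shift_um = rr$coarse_shift,
       n_aligned = sum(rr$source == "aligned"),
       n_fallback = sum(rr$source == "affine_fallback"),
       tiles = data.frame(tile = seq_along(rr$source),
                          reference_tile = rr$correspondences,
                          source = rr$source,
                          shift_um = rr$shift_um))
}
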