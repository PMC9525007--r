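# End-to-end pipeline: stitch cycle 1, register cycles 2..n against it,
# render all channels of all cycles into one mosaic, write OME-TIFF and
# JSON reports.

#' Run the full stitching + registration + mosaic pipeline
#'
#' Executes the three phases in order: (i) the first cycle's tiles are
#' stitched; (ii) each later cycle is registered against the first (never
#' chained through intermediate cycles); (iii) all tiles from all cycles
#' are rendered onto one canvas. Every tunable parameter of the underlying
#' stages is surfaced here.
#'
#' @param cycles list of [tileset()] objects (cycle 1 first), or a character
#'   vector of directories readable by [read_tileset()].
#' @param pattern,positions,pixel_size,channels_per_cycle passed to
#'   [read_tileset()] when `cycles` are directories; `positions` defaults to
#'   `positions.csv` inside each directory.
#' @param max_shift translation limit, micrometres (default 15).
#' @param upsample sub-pixel factor (default 10, i.e. 0.1 px).
#' @param n_pairs,percentile,perm_seed permutation-test parameters
#'   (defaults 1000, 99, 1).
#' @param downsample thumbnail factor for coarse inter-cycle alignment
#'   (default 20).
#' @param blend blending function for [render()].
#' @param subpixel apply fractional tile translations when rendering.
#' @param channels channel indices to render from each cycle (default all).
#' @param output optional OME-TIFF output path.
#' @param report optional JSON report path.
#' @param bits output bit depth.
#' @param quiet suppress per-phase progress messages.
#' @return list: `stitch` (`stitch_result`), `registrations` (list of
#'   `registration_result`, cycles 2..n), `positions` (per-cycle corrected
#'   position matrices), `mosaic` ([mosaic_image()]), `report` (list).
#' @export
run_pipeline <- function(cycles, pattern = "tile_{series:03d}_ch{channel}.tif",
                         positions = NULL, pixel_size = NULL,
                         channels_per_cycle = 1L,
                         max_shift = 15, upsample = 10L, n_pairs = 1000L,
                         percentile = 99, perm_seed = 1L, downsample = 20L,
                         blend = "linear", subpixel = TRUE, channels = NULL,
                         output = NULL, report = NULL, bits = 16L,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  phase <- function(label) {
    t1 <- proc.time()[["elapsed"]]
    say("[%6.1fs] %s", t1 - t0, label)
  }
  if (is.character(cycles)) {
    dirs <- cycles
    cycles <- lapply(seq_along(dirs), function(k) {
      pos <- if (is.null(positions)) file.path(dirs[k], "positions.csv")
             else positions[k]
      read_tileset(dirs[k], pattern, pos, pixel_size,
                   cycle_index = k - 1L, channels = channels_per_cycle)
    })
  }
  if (length(cycles) < 1L) stop("at least one cycle is required")
  phase("stitching cycle 1")
  sr <- stitch(cycles[[1L]], max_shift = max_shift, n_pairs = n_pairs,
               percentile = percentile, seed = perm_seed,
               upsample = upsample)
  registrations <- list()
  pos_list <- list(sr$positions)
  if (length(cycles) > 1L) {
    for (k in 2L:length(cycles)) {
      phase(sprintf("registering cycle %d against cycle 1", k))
      rr <- register_tiles(cycles[[1L]], sr, cycles[[k]],
                           max_shift = max_shift, downsample = downsample,
                           upsample = upsample)
      registrations[[k - 1L]] <- rr
      pos_list[[k]] <- rr$positions
    }
  } else {
    say("single cycle: registration phase skipped")
  }
  phase("rendering mosaic")
  mosaic <- render(cycles, pos_list, channels = channels,
                   subpixel = subpixel, blend = blend)
  rep_obj <- list(
    parameters = list(max_shift_um = max_shift, upsample = upsample,
                      n_pairs = n_pairs, percentile = percentile,
                      perm_seed = perm_seed, downsample = downsample,
                      blend = blend, subpixel = subpixel),
    stitch = stitch_report(sr),
    registrations = lapply(registrations, register_report))
  if (!is.null(output)) {
    phase(sprintf("writing %s", output))
    write_mosaic(mosaic, output, bits = bits)
  }
  if (!is.null(report)) {
    jsonlite::write_json(rep_obj, report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  phase("done")
  list(stitch = sr, registrations = registrations, positions = pos_list,
       mosaic = mosaic, report = rep_obj)
}
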