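# stitchreg

Coordinated stitching and registration of multi-cycle, multi-tile
whole-slide microscopy images, with seamless pyramidal OME-TIFF mosaic
output and a block-based metric for quantifying local registration error.

## The problem

Cyclic multiplexed imaging (CyCIF, CODEX, mxIF, ...) builds high-plex data
by re-staining one specimen and scanning it repeatedly. Each scan (cycle)
acquires a grid of slightly overlapping camera tiles at recorded stage
positions; mechanical tolerance and imperfect calibration make those
positions wrong by a few pixels — enough to corrupt single-cell
quantification if tiles are merged naively. Producing one coherent mosaic
requires *stitching* (aligning neighboring tiles within a cycle) and
*registration* (aligning every later cycle to the first), done jointly:
stitching each cycle independently and then rigidly aligning the mosaics
leaves locally varying inter-cycle error that no rigid transform can fix.

## The method

For tiles within the first cycle:

1. An adjacency graph connects tiles whose recorded footprints overlap.
2. Each edge's overlap strips are pre-filtered with the discrete Laplacian
   (or LoG) to remove autocorrelation, then aligned by phase correlation
   with sub-pixel (0.1 px) precision via local upsampled-DFT refinement.
   Alignment quality is `E_NCC = -log(NCC)` of the whitened overlap.
3. Spurious alignments are rejected by (a) an `E_NCC` threshold set at the
   99th percentile of a permutation null — 1000 random non-adjacent tile
   pairs aligned the same way (empirical one-sided P = 0.01) — and (b) a
   user translation limit (default 15 um).
4. Within each connected component of surviving edges, a minimum spanning
   tree on `E_NCC` weights picks one unambiguous path to every tile;
   corrected positions are path sums of pairwise shifts from the root.
5. Regressing corrected on recorded positions yields an affine stage model
   (pixel-size miscalibration, camera rotation) used to place isolated
   tiles and disconnected pieces (e.g. separated TMA cores).

Later cycles are registered tile-by-tile against the stitched first cycle
(a star, never a chain): 20x-downsampled thumbnail mosaics are
phase-correlated to recover inter-cycle stage drift, recorded positions
establish tile correspondences, each pair is aligned at full resolution,
and tiles failing the translation limit fall back to the affine stage
model. Corrected positions from all cycles are rendered with sub-pixel
placement and linear distance-ramp blending into one multichannel
pyramidal OME-TIFF.

Registration consistency between two mosaics is quantified by a
block-dense flow field: non-overlapping 200x200 px blocks are
phase-correlated, a compensating affine (fitted to the shift field) is
subtracted, and the residual magnitude per block is the local registration
error, summarized by its median and rendered as a direction/magnitude
heatmap.

A synthetic acquisition generator (`scene_spec()`, `make_scene()`,
`acquisition_spec()`, `cut_acquisition()`) emulates nuclei-dense tissue
with sparse regions, per-tile stage jitter, systematic affine stage error,
inter-cycle drift, stain variation and tissue loss — with an exact ground
truth table, so the whole pipeline is testable without any data download.

## Worked example

```r
library(stitchreg)

# a synthetic 2-cycle acquisition: 4x4 grid of 100x100 px tiles, 24 px
# overlap, 1.5 px stage jitter, 1.004 systematic scale, 20 um drift,
# 5% tissue loss in cycle 2
acq <- acquisition_spec(rows = 4, cols = 4, tile_px = c(100, 100),
                        overlap_px = 24, pixel_size = 1, jitter_px = 1.5,
                        scale = 1.004, cycles = 2, drift_um = 20,
                        loss_fraction = 0.05, seed = 11)
scene <- make_scene(scene_spec(size = scene_size_for(acq),
                               nuclei_density = 50, tile_px = c(100, 100),
                               seed = 11))
sa <- cut_acquisition(scene, acq)

sr <- stitch(sa$tilesets[[1]], n_pairs = 200, seed = 5)
#> stitch_result: 16 tiles, 37 accepted / 42 aligned edges,
#>   1 component tree(s), E_NCC threshold 0.5632

rr <- register_tiles(sa$tilesets[[1]], sr, sa$tilesets[[2]])
#> registration_result: 16 tiles (16 aligned, 0 affine fallback),
#>   coarse drift (-18.00, -18.00) um

round(sr$affine$A, 4)   # fitted stage model: the injected 1.004 scale
#>        [,1]    [,2]
#> [1,] 0.9943 -0.0003
#> [2,] 0.0072  1.0044

m <- render(sa$tilesets, list(sr$positions, rr$positions))
#> mosaic_image: 347x348 px, 2 channel(s), 1.000 um/px
write_mosaic(m, "mosaic.ome.tif")

ev <- evaluate_registration(m$channels[[1]], m$channels[[2]],
                            pixel_size = 1, block = 100)
ev$summary$median_um
#> 0.045
```

The stitch report shows 37 of 42 candidate alignments survived the
permutation threshold (0.5632) and translation limit; the five rejects are
sparse corner overlaps. All 16 cycle-2 tiles aligned (none needed the
affine fallback), the recovered inter-cycle drift is about (−18, −18) um,
and the final cross-cycle local registration error is 0.045 um median —
well below a pixel, which is what makes single-cell quantification across
cycles trustworthy.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/synth.R --preset colon-like --cycles 2 --seed 3 --out acq/
Rscript inst/cli/stitchreg.R run acq/cycle1 acq/cycle2 \
    --pixel-size 0.65 --max-shift 15 --output mosaic.ome.tif --report report.json
Rscript inst/cli/evalflow.R a.ome.tif b.ome.tif --block 200 \
    --report flow.json --heatmap flow.png
```

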