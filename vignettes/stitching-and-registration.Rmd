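---
title: "Coordinated stitching and registration of cyclic whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated stitching and registration of cyclic whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitchreg)
```

## The model

A cyclic whole-slide acquisition is a set of imaging cycles; each cycle is
a set of overlapping camera tiles with recorded stage positions (y, x, in
micrometres; y increases downward) and a shared isotropic pixel size. The
package assumes that essentially all discrepancy between recorded and true
tile positions is translational: modern stages and rigid samples do not
rotate or shear tiles relative to each other, and kinematic slide mounts
keep the slide angle constant across cycles. Two error components are
modeled explicitly:

* **uncorrelated jitter** — each tile's true position deviates from its
  recorded position by an independent, few-pixel error;
* **systematic stage error** — a single affine map (pixel-size
  miscalibration, camera/stage axis rotation) relates recorded to true
  coordinates across the whole grid.

Between cycles a single global **drift** (stage re-homing offset) is
added, and tissue may degrade (patches detach, staining intensity varies).

All alignment rests on two primitives. `whiten()` applies the discrete
5-point Laplacian (or Laplacian-of-Gaussian for noisy data) to remove the
strong low-frequency autocorrelation of tissue images; without this,
cross-correlation peaks reflect shared background structure rather than
feature alignment. `phase_correlate()` estimates translation from the
normalized cross-power spectrum, refining the integer peak to 1/`upsample`
pixels (default 10, i.e. 0.1 px) by sampling the cross-correlation on an
upsampled grid around the peak with a local matrix-multiply DFT. Alignment
quality is the Pearson correlation (NCC) of the whitened overlap at the
recovered shift, reported as `E_NCC = -log(NCC)` so that lower is better
and values compose naturally as spanning-tree weights.

## Stitching

The first cycle is stitched in five steps: build the adjacency graph from
recorded footprints; calibrate an `E_NCC` acceptance threshold by a
permutation test (1000 random non-adjacent tile pairs, cropped to the
modal true-overlap shape, aligned identically to real edges; the threshold
is the 99th percentile of the null NCC, an unadjusted empirical one-sided
P of 0.01); align and filter every edge (threshold plus a translation
limit); solve positions per connected component over the minimum spanning
tree of `E_NCC` weights, summing pairwise offsets from the root; and fit
the affine stage model by least squares of corrected on recorded
positions, which then places isolated tiles and repositions secondary
components without distorting their internal geometry.

Registration of a later cycle reuses the same machinery: thumbnail mosaics
(20x downsampled) are phase-correlated to recover drift, each target tile
is paired with the nearest reference tile, pairs are aligned at full
resolution, and the translation limit alone filters failures, which fall
back to the affine stage model. No permutation threshold is used in this
phase — a failed whole-tile alignment almost always produces an extreme
translation, which the limit catches. Cycles are always registered to the
first, never chained, so error does not accumulate across cycles.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `upsample` | 10 | — | sub-pixel resolution 1/upsample px; beyond ~10 returns diminish |
| `max_shift` | 15 | um | translation limit; not critical, spurious shifts are extreme |
| `n_pairs` / `percentile` | 1000 / 99 | — | permutation null size and cutoff (P = 0.01) |
| `perm_seed` | 1 | — | fixed so thresholds are reproducible |
| `downsample` (register) | 20 | — | thumbnail scale; precision ~ downsample x pixel size / upsample |
| `blend` | linear | — | distance-ramp weighted average; weights sum to 1 everywhere |
| `block` (evalflow) | 200 | px | flow-field block size |

## Numerical choices

* **Crop geometry and two-pass alignment.** Both members of a tile pair
  are cropped to the *same* recorded-frame rectangle (the mutual overlap,
  expanded toward the tile interiors but never past either footprint).
  Because the positioning error being measured displaces the shared
  content inside those windows, a border ring of non-shared content is
  unavoidable in the first pass and biases the upsampled-DFT peak by a few
  tenths of a pixel. A second pass therefore re-crops both tiles to the
  mutual overlap implied by the first-pass offset — windows that cover
  identical content up to noise — and re-measures; per-edge accuracy then
  reaches the 0.1 px quantization floor. An apodization window was
  evaluated instead and rejected: corner overlaps place the shared content
  at the window border, exactly where a taper destroys it.
* **NCC convention.** NCC is computed on whitened pixels with the shift
  rounded to whole pixels for overlap extraction; the permutation null
  uses the same convention, so edge scores and the threshold are
  commensurable. NCC ≤ 0 is clamped to 1e-10 before the negative log,
  keeping `E_NCC` finite and ordered for spanning-tree weights; an
  undefined NCC (blank or constant overlap) maps to `E_NCC = Inf`, which
  can never be accepted.
* **MST tie-break.** Kruskal's algorithm consumes edges in increasing
  (weight, i, j) order, so ties in `E_NCC` resolve by canonical edge index
  — positions are invariant to tile order up to this documented rule.
* **Root choice.** The tree root is the tile nearest the component
  centroid, minimizing worst-case path length and hence accumulated
  path-sum error.
* **Degenerate affine fits.** Fewer than three non-collinear fitted tiles
  degrade the stage model to translation-only (with a warning); none at
  all, to identity. A linear-part determinant outside (0.9, 1.1) warns.
* **Rounding.** With `subpixel = FALSE` rendering positions round
  half-even (base R `round`). Sub-pixel rendering translates tiles by
  bilinear interpolation rather than Fourier resampling: no ringing on
  16-bit data at the cost of at most ~0.5 px of blur worst case.
* **Flow-field validity.** Blocks are invalid when smaller than 8 px a
  side, when the whitened variance is below a floor, when NCC is
  undefined, when the measured shift exceeds `block/4` (a failed
  alignment), or when less than 75% of either block is imaged (exact
  zeros): unimaged canvas and blank glass must not pollute the median.
  The error statistic is the median over valid *blocks* (not pixels),
  matching the field's granularity.
* **Inter-cycle drift sign.** `coarse_align()` returns the displacement of
  the target cycle's recorded coordinates relative to the reference
  cycle's recorded coordinates of the same physical location, so the
  reference-frame position of a target tile is `recorded - coarse_shift`.

## The synthetic generator

`make_scene()` renders anti-aliased, Gaussian-smoothed nuclear disks
(radius 4–8 px — enough high-frequency texture for phase correlation at
~30 px overlaps) over a smooth background field inside a tissue mask
(full field, two TMA-like cores separated by blank glass, or a diagonal
strip). `cut_acquisition()` cuts tiles at integer-pixel true positions
(nominal grid + drift + jitter) and reports recorded positions passed
through the inverse systematic affine, so the stitcher must recover both
error components; the exact truth table drives every parameter-recovery
assertion in the test suite. Read and photon noise are applied **per
tile**, not per scene — neighboring tiles' overlap strips carry
independent noise, as separate camera exposures do. This matters: with
shared noise, blank overlaps would correlate perfectly and the permutation
threshold would be meaningless. Later cycles re-render with per-nucleus
intensity jitter of ±20% (stain variation) and zero out disk-shaped
detached-tissue patches covering the requested fraction of tissue.

The default `acquisition_spec()` encodes the reference validation
conditions used throughout: a 6x6 grid of 200x200 px tiles at
0.65 um/px overlapping by 31 px, 2 px jitter, a 1.005 systematic scale,
and two cycles separated by 50 um of drift with 10% tissue loss. Unit
tests run a reduced 4x4/100 px variant of the same structure for speed;
the acceptance suite runs the full reference conditions.

What the generator does **not** emulate: optics (PSF, vignetting, chromatic
aberration), illumination falloff needing flat-field correction,
autofluorescence spectra, tile rotation or scale differences, and
non-rigid tissue deformation. Passing tests therefore demonstrate correct
recovery under the translational error model the method assumes, not
robustness to modalities that violate it.

## Limitations

* Translation-only: rotation, scale or skew between tiles or cycles is
  out of scope by design; the affine stage model captures systematic
  position error but tiles themselves are never resampled by an affine.
* Spanning-tree path sums accumulate uncorrelated error along long paths;
  physically adjacent tiles far apart in the tree can disagree by more
  than a single edge's error. A global least-squares refinement over all
  accepted edges would reduce this and is deliberately not included.
* The permutation threshold assumes enough non-adjacent tile pairs exist
  to sample a null; tiny acquisitions fall back to `threshold = Inf`
  (every edge passes the score test and only the translation limit
  filters).
* OME-TIFF output is strip-organized (the layout the available TIFF
  writer produces) with pyramid levels as additional pages described by
  the embedded OME-XML; readers that require SubIFD pyramids will see
  only the full-resolution planes.
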