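Package: stitchreg
Title: Coordinated Stitching and Registration of Multi-Cycle Whole-Slide Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles seamless whole-slide mosaics from tiled, multi-cycle
    fluorescence microscopy acquisitions. Tiles within the first imaging cycle
    are stitched by sub-pixel phase correlation on Laplacian-whitened overlap
    regions, spurious alignments are rejected with a permutation-test threshold
    on the normalized cross-correlation error and a translation limit, and
    global tile positions are solved over a minimum spanning forest with an
    affine stage-error model reconciling disconnected pieces. Later cycles are
    registered tile-by-tile against the stitched first cycle after coarse
    thumbnail alignment. Corrected positions are rendered into a blended,
    pyramidal OME-TIFF mosaic. Includes a block-based dense flow-field metric
    for quantifying local registration error between mosaics, and a synthetic
    acquisition generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png
Config/testthat/edition: 3
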