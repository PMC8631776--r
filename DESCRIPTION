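Package: nvckit
Title: Neurovascular Reactivity Quantification from Laser Speckle and
    Two-Photon Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Investigator-independent quantification of neurovascular
    reactivity from wide-field laser speckle contrast imaging (LSCI)
    perfusion movies and two-photon microscopy (2-PM) vessel time series.
    For LSCI recordings during whisker stimulation or a CO2 challenge the
    package removes slow signal drift with a zero-phase Chebyshev Type I
    high-pass filter, detects stimulation epochs automatically by Otsu
    thresholding of the region-of-interest perfusion trace, computes
    baseline-normalized per-pixel response maps, standardizes them to a
    common 120 x 120 grid, and averages them within and across animals
    into group heat maps with peak, slope, and area-under-curve metrics.
    For 2-PM movies it measures vessel diameter over time along
    user-defined measurement lines in binarized frames by voxel counting
    with a 4-voxel line thickness, detects dilation events with a
    baseline-tracking peak detector, and exports per-peak slope and
    percent-change tables. A synthetic-data module generates perfusion
    stacks and vessel movies with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    pracma,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
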