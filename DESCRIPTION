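Package: treatscan
Title: Locating Forest Management Units from Paired-Year Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and maps forest fuel treatments (clearcuts, thinnings,
    prescribed fires) from pairs of co-registered multiband satellite rasters.
    Implements principal-component temporal change metrics, burn and vegetation
    spectral indices (NBR, dNBR, RBR, NDVI), Random Forests treatment-probability
    surfaces with out-of-bag error assessment, mean-shift segmentation of the
    vote surface, rule-based polygon extraction with sliver, wildfire-perimeter
    and non-forest filtering, prescribed-fire extraction from burned-area
    rasters, error-matrix accuracy statistics with ROC/AUC, and kernel-density
    treatment summaries. Includes a synthetic-scene generator with planted,
    georeferenced treatment truth so the full pipeline is testable end to end
    without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
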