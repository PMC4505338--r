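Package: stedclust
Title: Nanocluster Analysis for Dual-Color STED Membrane-Sheet Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and quantitative analysis of membrane-protein
    nanoclusters in dual-color super-resolution (STED) images of plasma
    membrane sheets. Provides a ground-truth-annotated synthetic sheet
    generator, intensity-threshold blob detection with FWHM sizing and
    shape measurements, nearest-neighbor distance distributions with the
    analytic two-dimensional Poisson null, Monte-Carlo mock-image null
    ensembles for cross-channel proximity testing, pixel-wise Pearson
    colocalization, and a molecules-per-cluster stoichiometry chain
    combining quantitative immunoblotting, flow cytometry and cell
    surface-area measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, EBImage, tiff, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
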