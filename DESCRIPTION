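Package: ginkgocos
Title: Two-Trace 2D Correlation Spectroscopy Screening of Ginkgo Supplements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Adulteration screening of Ginkgo biloba food supplements from
    UV-Vis extract spectra. Computes two-trace two-dimensional (2T2D)
    synchronous and asynchronous correlation maps from sample/reference
    spectrum pairs, assembles the three screening series (dual-solvent,
    reference-extract, averaged-adulterant), detects and reports cross
    peaks, and summarizes map stacks by multiway PCA with venetian-blinds
    cross-validation. Also clusters chromatographic flavonol peak-area
    tables (Ward linkage, Euclidean distance, mean centering) and ships a
    seeded synthetic spectrum generator emulating flavonol absorption
    bands and solvent-dependent aglycone solubility, so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
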