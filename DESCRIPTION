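Package: floquant
Title: Quantification of Flo11-Mediated Yeast Adhesion Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image and force-curve analytics for quantifying adhesin-mediated
    kin discrimination in budding yeast. Implements quantitative cell
    aggregation microscopy (QCAM: background correction, global-threshold
    segmentation, watershed dissection of touching aggregates and per-size-class
    area statistics normalised to 1 cm^2 of imaged field), competitive-biofilm
    genotype-segregation analysis from paired RFP/GFP colony images (channel
    fusion, iterative Otsu colony-edge detection, autofluorescence/gain
    normalisation, edge-ring and whole-colony genotype fractions, dominance
    ratios), and single-cell force spectroscopy analytics (force-distance curve
    parsing, linear baseline correction, maximum adhesion force extraction,
    contact-time kinetics). Ships seeded synthetic-data generators with known
    ground truth for all three assays and the accompanying statistical layer
    (Welch t-test, exact Wilcoxon rank sum, Spearman rank correlation,
    significance-star mapping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
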