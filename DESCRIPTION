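Package: pcpquant
Title: Quantification of Planar Cell Polarity in Epithelial Label Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of planar cell polarity (PCP) in
    segmented epithelia. Parses integer label masks (as produced by
    membrane-segmentation tools such as Tissue Analyzer) into a tissue graph of
    cells, adjacencies and junction segments; computes per-cell best-fit-ellipse
    geometry; measures per-cell axial polarity angle and magnitude by the
    principal-component (PCA) method on shape-normalised membrane intensities;
    estimates fluorescent-timer stable fractions from mKate2/sfGFP ratios;
    quantifies microtubule texture orientation from 5x5 Sobel gradients with
    weighted von Mises fits and the microtubule standard deviation (MTSD);
    assigns cell rows and junction orientation classes relative to an
    overexpression boundary; and provides axial circular statistics including
    Hotelling's T-squared tests on polarity vectors. A seeded synthetic-tissue
    generator produces label masks, junctional channel images, fluorescent-timer
    channels and filament textures with known ground truth for validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    igraph,
    knitr,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
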