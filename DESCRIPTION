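Package: srstain
Title: Virtual Histologic Staining of Stimulated Raman Scattering Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts label-free stimulated Raman scattering (SRS) images of
    thick fresh-frozen tissue into virtual H&E images and archival-quality
    (FFPE-like) renderings. Implements a seeded synthetic tissue-phantom
    generator with paired SRS cubes and H&E ground truth, discrete-frequency
    band selection by regression-based spectral reconstruction, registration
    and patch preparation, a compact convolutional GAN framework (two-phase
    virtual-staining generator and an unpaired cycle-consistent FFPE
    translator) with tiled whole-section inference and multi-depth virtual
    sectioning, lipid-droplet quantification from the 2847/2933 band ratio
    with group-comparison statistics, and interobserver-agreement analysis
    (Fleiss' kappa) for pathologist surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage,
    Rcpp,
    generics,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
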