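Package: octawound
Title: OCT Angiography Quantification of Cutaneous Wound Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs flow-contrast volumes from repeated complex OCT
    B-scans by eigen-decomposition clutter filtering (ED-OMAG), segments the
    skin surface, extracts surface-referenced vascular slabs, projects en face
    angiograms, and quantifies vessel area density (VAD) inside a circular
    wound mask, with longitudinal two-way ANOVA group statistics for
    wound-healing cohorts. Includes a digital flow phantom that emulates the
    layered skin of adult zebrafish, speckle-decorrelating vessels, a
    full-thickness punch wound, and group-specific angiogenesis time courses,
    so that every processing stage is testable end to end without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    rlang,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    car,
    EBImage,
    tiff,
    png,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
LinkingTo:
    Rcpp
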