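Package: msiannot
Title: FDR-Controlled Metabolite Annotation for Imaging Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates centroided imaging mass spectrometry data against
    molecular databases with false-discovery-rate control. Candidate ions
    are scored with five per-ion features (spatial isotope coherence,
    spectral isotope match, spatial chaos, and absolute and relative m/z
    error), ranked against implausible decoy adduct ions by a
    gradient-boosted pairwise ranking model, and assigned a continuous FDR
    from a single weighted target-decoy ranking with pseudocounts. Includes
    dataset quality-control filters for mistakenly submitted profile-mode
    data, an F-beta based reliability score for choosing the optimal FDR
    threshold, ranking-quality evaluation metrics, molecular-class
    enrichment analysis, context-based corpus selection, and a synthetic
    data generator with planted ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
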