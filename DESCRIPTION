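Package: mzatlas
Title: Metabolite Atlases and Targeted Feature Extraction for LC/MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of the metabolite-atlas workflow for
    liquid chromatography mass spectrometry (LC/MS) metabolomics. Centroided
    runs are ingested from mzML into a nine-attribute raw-point store that
    supports range slicing and histogram aggregation into chromatograms and
    spectra. Compound atlases (method- and sample-specific dictionaries of
    m/z and retention-time bounds) are managed with full-replacement and
    partial-update semantics, drive targeted extracted-ion-chromatogram
    computation, trapezoidal peak integration and Gaussian peak fitting, and
    yield compound-by-file feature tables for hierarchical clustering and
    per-compound group testing. A ground-truth LC/MS run simulator makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    xml2,
    jsonlite,
    minpack.lm,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
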