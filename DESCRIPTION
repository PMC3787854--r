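Package: hybridhsi
Title: Hybrid Unsupervised-Supervised Classification of Hyperspectral Endoscopic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hybrid-method classification of hyperspectral image
    cubes, aimed at pixel-level detection of mucosal lesions in narrow-band
    endoscopic image stacks. An unsupervised stage selects a hierarchy of
    endmember signatures by farthest-point sampling in spectral space,
    estimates linear-mixture-model abundances, and assigns pixels to
    clusters by maximum posterior probability. A supervised stage transfers
    cluster-mean endmembers to a second cube and classifies it with the
    spectral angle mapper, which is invariant to multiplicative illumination
    changes. Decision maps are reduced to binary lesion masks and validated
    against reference masks with confusion-matrix sensitivity, specificity,
    and detection bias. A synthetic phantom generator produces paired
    endoscopic-like cubes with known lesion geometry, smooth illumination
    fields, and sensor noise for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
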