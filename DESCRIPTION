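Package: archbar
Title: Full-Arch Scan Accuracy Metrology with a Cross-Arch Reference Bar
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates the accuracy (trueness and precision, ISO 5725-1) of
    full-arch surface scans against a cross-arch reference bar of certified
    length. Fits reference planes to the scanned bar-end surfaces, intersects
    them to obtain the bar edge vectors and reference points, and derives the
    vectorial error, the length deviation and three angular deviations per
    scan. Includes STL mesh input/output with declarative region selection, a
    synthetic scan-distortion generator with known ground truth for validating
    the pipeline, and nonparametric multi-group comparisons (Kruskal-Wallis,
    pairwise Mann-Whitney with Bonferroni correction, Brown-Forsythe
    dispersion tests) with compact letter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    nortest,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
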