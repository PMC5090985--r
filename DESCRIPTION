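Package: xlf
Title: X-Ray Lung Function Analysis from Cinematic Chest Radiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a background-normalized x-ray transmission function (XTF)
    from cinematic chest radiograph stacks of freely breathing mice, detects
    individual breathing events with a scan-line threshold, parameterizes each
    event with a shifted cubic polynomial (b1-b5, relative inspiration time
    t_in), and compares groups of scans (healthy, allergic airway inflammation,
    treated) with Welch t-tests, including methacholine dose-response analysis.
    A synthetic-data generator with exact ground truth makes the full pipeline
    testable without animal data, and a volume-of-interest module quantifies
    soft-tissue content of phase-contrast lung CT volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
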