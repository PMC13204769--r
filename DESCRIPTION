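Package: neglectscore
Title: Automated Scoring of Paper-and-Pencil Spatial Neglect Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic image-analysis pipeline for scoring scanned
    paper-and-pencil subtests used in the diagnosis of unilateral spatial
    neglect: three cancellation tasks (line crossing, letter cancellation,
    star cancellation), line bisection, and figure copying (four-pointed
    star and diamond). Raw subtest scores are converted to standard values,
    combined into weighted battery totals, and mapped to diagnostic
    categories. Includes a seeded synthetic sheet generator with exact
    ground truth, chance-corrected agreement statistics (Krippendorff's
    alpha, weighted Cohen's kappa, intraclass correlation), batch CSV
    reporting, and overlay visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
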