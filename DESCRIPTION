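Package: marginalia
Title: Mobilising Printed Plant Names and Handwritten Marginalia from
    Digitised Herbals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A data-mobilisation workflow for word-level OCR block output of
    digitised early-modern botanical volumes such as Sloane's annotated copy
    of Ray's Historia Plantarum.  Parses PAGE/LINE/WORD block JSON with
    fractional bounding boxes and printed/handwritten text types, detects
    page structure (running titles, header and footer bands, side-margin
    boundary, adjacent-page bleed), segments printed plant-name entries and
    handwritten specimen annotations, links each margin annotation to its
    plant name by minimal vertical distance of bounding-box tops, parses
    "H.S. [volume] [folio] [specimen]" herbarium references, and emits
    structured JSON page records.  Includes an evaluation protocol (character
    error rate, IoU-matched precision/recall/F1 for segments and
    relationships) and a seeded synthetic-page generator with exact ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
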