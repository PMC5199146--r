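Package: dwctraits
Title: Extract and Harmonize Vertebrate Trait Measurements from Darwin Core Text Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based extraction of vertebrate body length (five measurement
    conventions), body mass, sex, and life stage from the free-text Darwin Core
    fields of specimen occurrence records (dynamicProperties,
    occurrenceRemarks, fieldNotes). Standardizes values to millimetres and
    grams, flags inferred units, and emits a harmonized output schema
    (hasLength, lengthInMM, derivedSex, ...). Includes a synonym lexicon with
    descriptor categorization, confusion-matrix validation against gold
    standards (TPR, TNR, Matthews correlation), per-clade coverage summaries,
    and a seeded synthetic-corpus generator emulating the heterogeneity of
    digitized natural-history records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    stringr,
    readr,
    rlang,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
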