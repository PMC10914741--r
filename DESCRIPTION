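Package: gatherparse
Title: Parse Duplicated GBIF Plant Occurrence Records into Unique
    Collection Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reduce redundancy in occurrence downloads from the
    Global Biodiversity Information Facility (GBIF). Duplicate herbarium
    records derived from one field gathering are grouped under a
    collection-event key (family + primary-collector surname + collection
    number), the best-documented record is selected as the digital voucher
    using GBIF geospatial issue flags and a ten-field completeness score,
    a consensus taxon is chosen after reconciling determinations against a
    World Checklist of Vascular Plants (WCVP) names backbone, empty voucher
    fields are filled from duplicates, and the dataset is partitioned into
    useable, unusable and duplicate records. Includes a synthetic-data
    generator with known gathering structure for testing, and 1x1-degree
    taxon-richness grids for before/after comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
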