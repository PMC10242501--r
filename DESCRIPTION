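Package: radwarehouse
Title: Entity-Attribute-Value Data Warehouse for Radiology Operations Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Configuration-driven import of radiology information system (RIS)
    exports (CSV, Excel, JSON) into an entity-attribute-value warehouse,
    derivation of clinical-operations metrics (shift assignment, turnaround
    times, report-availability buckets, device vacancy, repeated-examination
    sequences, first-contact flags), a three-level query index over patients,
    appointments and examinations, an XML cross-tabulation query language with
    logical constraint trees, incremental updates that are provably equivalent
    to a full rebuild, report export to CSV/Excel, and a deterministic
    synthetic multi-hospital RIS export generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
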