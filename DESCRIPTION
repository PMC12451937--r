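Package: dicomop
Title: Integrate DICOM Standard Terminology into the OMOP Common Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a custom OMOP CDM vocabulary from the DICOM Standard's
    attribute dictionary (Part 6), context-group coded values (Part 16) and
    per-attribute Enumerated Values / Defined Terms (Part 3); harvests series
    metadata from DICOM Part-10 files with value-representation filtering;
    loads the result into the OMOP medical-imaging extension tables
    (Procedure_occurrence, Image_occurrence, Image_feature, Measurement); and
    evaluates imaging-phenotype cohort definitions (for example T1-weighted
    volumetric MRI by TR/TE/TI) over the loaded tables, in memory or through a
    file-backed SQLite store. Ships deterministic synthetic-data generators
    for normalized standard content, ADNI-like MR file trees and simulated
    EHR tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
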