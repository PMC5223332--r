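Package: didkit
Title: Building and Analyzing Integrated Drug-Indication Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing a drug-indication database (DID) from
    heterogeneous sources: ingestion adapters for controlled pair lists,
    ATC-style classification hierarchies, and free-text label records;
    normalization of drug and chemical names to CAS-style and CUI-style
    concept identifiers across ranked synonym dictionaries with match-quality
    typing; indication mapping with phenotypic semantic-type preference and
    remapping of therapeutic-class terms to disease concepts; indication
    subtype tagging; assembly of the deduplicated flat DID table; and
    integration metrics (terminological reduction, coverage, overlap with
    change scores, Zipf sharing distributions, richness). A synthetic-world
    generator with analytic expected metrics provides a ground-truth oracle
    for every pipeline stage.
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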