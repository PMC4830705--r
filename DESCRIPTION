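Package: casechar
Title: Terminology-Aware Case Series Characterization for Drug Safety
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for verifying drug-safety signals against
    heterogeneous electronic health record sources. Mediates
    document-based and relational source data into a common patient
    model via declarative conversion rules, represents terminology
    systems with cross-scheme mapping assertions and materializes
    their close-match transitive closure and level-targeted grouping
    links, localizes and evaluates eligibility queries with windowed
    temporal constraints, de-identifies records by coherent date
    shifting and rare-code removal, and characterizes foreground
    versus background case-series populations with comparative
    statistics boxes. Includes a synthetic-data generator producing
    terminologies, mappings and cohorts with known ground truth so
    every stage is testable without licensed vocabularies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
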