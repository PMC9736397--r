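Package: pdnet
Title: Phenotypic Disease Networks for Multimorbidity Analysis of
    Hospital Discharge Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multimorbidity analysis of ICD-10-coded hospital discharge
    records: chronic-comorbidity identification and comorbid burden,
    case-control enrichment odds ratios with Bonferroni adjustment,
    age-stratified comorbidity networks weighted by the Salton cosine
    index with PageRank/HITS node roles and power-law degree diagnostics,
    and Apriori association-rule mining targeted at a consequent disease.
    Includes a calibrated synthetic discharge-record generator so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
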