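Package: perilink
Title: Consistency Checking and Cleaning for Linked Perinatal Administrative Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a 22-step quality-assurance protocol
    for probabilistically linked perinatal administrative data. The package
    checks uniqueness of records, within-person perinatal consistency
    (pregnancy intervals, parity sequences, birth order and plurality),
    coherence of dates and demographics across birth, hospital, emergency
    department, death and congenital-condition sources, and resolves person
    identifiers across two jurisdictions linked through a national
    pharmaceutical-claims identifier space. All findings are recorded in an
    append-only flag ledger; source data are never modified. A seeded
    synthetic-cohort generator with labelled error injection is included for
    validating the checks end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
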