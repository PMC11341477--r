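Package: faersmine
Title: Disproportionality Signal Mining for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on FDA
    Adverse Event Reporting System (FAERS) quarterly ASCII files. Reads and
    joins DEMO/DRUG/REAC/THER tables, applies the FDA-recommended case
    deduplication rule, builds a target-drug cohort by synonym matching with
    primary-suspect filtering, and computes four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio with
    chi-square, BCPNN information component, and the observed/expected ratio
    EBGM) with interval estimates and signal-criteria flags at MedDRA
    preferred-term and system-organ-class level. Also summarises
    time-to-onset and cohort demographics, and ships a synthetic FAERS
    generator with a ground-truth ledger so every stage is testable without
    downloading FAERS data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
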