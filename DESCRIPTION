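Package: secscreen
Title: Screening-Campaign Statistics for Signal-Peptide Secretion Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics and data reduction for high-throughput screening of
    Sec signal-peptide (SP) expression libraries. Provides a binomial
    occupancy model for random clone picking with replacement (multiplicity
    probabilities, library coverage, oversampling design), a seeded
    Monte-Carlo simulator of clone-picking campaigns, reduction of kinetic
    p-nitrophenyl-palmitate (pNPP) plate-reader traces to volumetric enzyme
    activity, replicate aggregation with max-normalization, ranking and
    reference-panel classification of secretion phenotypes, cross-host
    comparison of per-SP relative activities, and a synthetic-campaign
    generator for end-to-end validation. Ships a transcription of a
    published two-host cutinase secretion activity table as a worked
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
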