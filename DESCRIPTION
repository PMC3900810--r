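Package: tfaintake
Title: Trans Fatty Acid Composition Database Construction and Dietary
    Intake Estimation from Multi-Day Diet Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a complete trans fatty acid (TFA) food composition
    database from a national food table, a corpus of analytic literature
    values, a foreign product database, and recipes, via a four-step
    hierarchical assignment with full provenance tracking (zero rule,
    sample-weighted literature pooling, nutrient-similarity transfer with a
    dedicated meat-cut cascade, cross-market product matching, and recipe
    imputation).  Converts multi-day semi-weighed diet records into
    per-subject mean intakes of energy, total fat, and TFA (g/day, % energy,
    % fat) with a venue rule for commercial versus restaurant foods and
    mean +/- k SD outlier exclusion, and produces stratified descriptive
    summaries: food-group contribution decomposition, urban/rural and
    age-group comparisons (t-test, one-way ANOVA with Tukey-Kramer), intake
    distribution tables, and with/without-added-foods database comparisons.
    Includes a synthetic-data generator emulating every input with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
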