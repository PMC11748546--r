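Package: niptr
Title: Interpretation Engine for Cell-Free DNA Prenatal Aneuploidy Screening Runs
Version: 0.1.0
Authors@R:
    person("NIPT", "Engineering", email = "nipt-eng@example.org", role = c("aut", "cre"))
Description: A headless interpretation engine for noninvasive prenatal testing
    (NIPT) sequencing runs. Parses per-run result files carrying normalized
    chromosome values (NCV), fetal fraction (FF), normalized chromosomal
    denominator (NCD) values and per-chromosome coverage; maintains an
    audit-traceable historical store; calibrates decision thresholds and the
    NCV(X)/NCV(Y) sex-chromosome regression with a 3-SD band; classifies and
    flags samples (autosomal trisomy, sex-chromosome deviation, QC failures);
    builds chart data and renders clinical PDF/HTML reports. A synthetic-cohort
    generator with known truth labels makes the whole pipeline testable without
    any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
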