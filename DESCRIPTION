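Package: picoscreen
Title: Two-Stage Systematic-Review Screening with Chained PICOS Eligibility Tasks
Version: 0.1.0
Authors@R: person("picoscreen", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An offline-testable pipeline for automating the two stages of
    systematic-review literature screening (title-abstract triage and
    full-text assessment) by decomposing the eligibility question into
    chained PICOS tasks, each rendered as a few-shot chain-of-thought
    prompt against a pluggable language-model backend. Includes
    bibliographic corpus ingestion (RIS, CSV, MEDLINE, internal XML) with
    cleaning and deduplication, plain-text page-stream segmentation into
    canonical IMRaD sections with an OCR contract, a deterministic mock
    backend for reproducible testing, PRISMA flow accounting, evaluation
    against a gold standard (accuracy, precision, recall,
    exclusion-reason concordance, chi-square model comparison), a
    synthetic labelled-corpus generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    stringi,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
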