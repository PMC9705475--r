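Package: mammotriage
Title: Counterfactual Evaluation of AI and Radiologist Reading Scenarios
    in Mammographic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective scenario evaluation for combining an AI
    suspicion score with radiologist double reading in population-based
    mammographic screening. Provides a declarative catalog of reading
    scenarios (AI as an independent reader, AI-based triage to no, single
    or double reading, and standalone AI recall), per-examination
    counterfactual accounting of consensus, recall, screen-detected and
    interval cancers, screen-reading volume reduction, sensitivity with
    logit-transformed confidence intervals, and a calibrated synthetic
    screening-cohort generator for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
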