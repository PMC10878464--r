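Package: resusdev
Title: Guideline-Deviation Scoring for Simulated Pediatric Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic scoring of timestamped resuscitation event logs
    from simulated nonshockable pediatric cardiac arrest scenarios. Implements
    the 15-item c-DEV15plus guideline-deviation checklist, a configurable
    Clinical-Performance-Tool-style rubric, CPR quality metrics (compression
    rate, depth, chest-wall recoil, no-flow fraction) with AHA-standard bands,
    and the accompanying statistical toolkit: exact Fisher tests by full
    enumeration, binomial confidence intervals for differences of proportions,
    Wilcoxon rank-sum with Hodges-Lehmann shift estimates, and Lin's
    concordance correlation coefficient with bootstrap confidence intervals.
    A seeded synthetic cohort generator emulates a 27-team study cohort so the
    entire pipeline is testable without access to recorded scenario data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
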