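Package: mcdaval
Title: Multicriteria Decision Analysis for Comprehensive Drug Value Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the comprehensive value of a medicine with
    multicriteria decision analysis (MCDA). Implements analytic hierarchy
    process (AHP) weighting from expert pairwise judgments with consistency
    diagnostics and group aggregation, evidence-matrix scoring and weighted
    aggregation of treatment strategies, domain-weight sensitivity analysis
    with rank-stability checks, pharmacovigilance disproportionality signal
    detection (proportional reporting ratio and reporting odds ratio with
    confidence intervals) for spontaneous adverse-event reports, and
    deterministic affordability and formulary-coverage calculators. Includes
    seeded simulators for expert judgments, score panels and adverse-event
    report tables so the full pipeline can be exercised end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
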