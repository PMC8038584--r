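Package: bloodgas
Title: Rule-Based Interpretation of Arterial Blood Gas Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic interpretation of arterial blood gas panels by four
    concurrent analysis approaches: the physiological (Boston, bicarbonate
    based) and chemical (Copenhagen, standard base excess based) approaches,
    each with and without an albumin-corrected anion gap. Implements the
    Henderson-Hasselbalch consistency screen with graded severity, van Slyke
    estimation of standard base excess, compensation-adequacy rules with a
    5 percent borderline ("probable") zone, anion-gap escalation thresholds,
    and delta-ratio banding for triple-disorder detection, and reports
    cross-approach compliance. Includes batch CSV/JSON processing, packaged
    literature cases, and a seedable synthetic panel generator for classifier
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
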