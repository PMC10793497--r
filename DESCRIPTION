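Package: tnddesign
Title: Hypothesis Tests, Sample Sizes and Power Simulation for Test-Negative Vaccine Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis tools for test-negative design (TND) and
    case-control vaccine-effectiveness studies. Implements one-sided Wald,
    continuity-corrected Wald and score tests of a vaccine-effectiveness
    margin on 2x2 vaccination-by-test-result tables; the matching
    closed-form sample sizes (Fleiss-type Wald with and without Yates'
    correction, and the logistic score sample size); a TND-specific score
    sample size that averages power over the random percent positivity with
    a binomial weight; a hazard-based event-time simulator of a source
    population under an all-or-none vaccine; and a Monte-Carlo harness for
    power, type-I error, zero-cell frequency and continuity-correction
    bias diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
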