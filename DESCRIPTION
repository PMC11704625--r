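Package: cogdx
Title: Rule-Based Cognitive Impairment Screening from Digital Behavior Markers
Version: 0.1.0
Authors@R: person("Avery", "Collins", email = "avery.collins@example.org",
    role = c("aut", "cre"))
Description: Tools for screening mild cognitive impairment (MCI) from
    free-living digital phenotyping data. Provides a seeded synthetic-cohort
    generator emulating a smartwatch study population (daily acceleration
    totals, location traces, ecological momentary assessment responses,
    daily n-back accuracies, journal texts and interview ratings), marker
    extraction with 0-10 integer rescaling, decision-tree induction of
    filtered if-then diagnosis rules in a plain-text DSL, a deterministic
    rule-application classifier behind a prompt/response contract,
    wrapper-based greedy fusion of marker-set rule groups, and an evaluation
    harness reporting accuracy, MCI precision/recall and the Matthews
    correlation coefficient over repeated runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
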