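Package: behavephen
Title: Behavioural Phenotyping Pipelines for Mouse Motor and Learning Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deep behavioural phenotyping of mouse cohorts from
    keypoint trajectories and operant event logs: open-field distance and
    habituation metrics with behaviour-label bout statistics, accelerating
    rotarod protocol semantics with paw-slip detection and weight-normalized
    latency, water T-maze trial scoring (time to platform, arm entries,
    decision-point dwell, acceleration events, probe-strategy classification,
    reversal eligibility), and a three-phase home-cage lever-pulling task
    state machine with daily performance summaries. Includes a fully seeded
    synthetic-data generator that emulates cohort structure (genotype, sex,
    age, weight) and plants ground truth for every detector, plus the
    statistics layer used to compare groups (two-way ANOVA with Sidak
    correction, t tests, Pearson correlations and Fisher z contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    car,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
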