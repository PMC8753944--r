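Package: frontflow
Title: Patient-Flow Simulation and Staffing Decision Support for Hospital
    Front-End Departments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of multi-class outpatient flow through
    the triage and medical-record stations of a hospital front-end department,
    with three medical-record routing policies (dedicated counters, a pooled
    one-stop bank, and partially shared counters with overflow to the least
    utilized counter type). Converts each patient's length of stay into a
    satisfaction score via expert-elicited triangular profiles, optimizes
    integer staffing schedules under a weighted max-min fuzzy bi-objective
    (operating cost vs. mean satisfaction) with a simulation-driven heuristic
    search, and provides the verification, validation, replication-sizing,
    blocked ANOVA, Tukey compact-letter, and decision-guideline machinery used
    to compare routing scenarios and recommend a staffing case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
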