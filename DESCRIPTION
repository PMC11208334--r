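Package: pspmarkov
Title: Markov Cohort Evaluation of Hospital Peer Support Programs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Economic evaluation of a hospital Peer Support Program for
    second victims using a three-state daily-cycle Markov chain of nurse
    sick leave and turnover. Provides the deterministic cohort engine and
    budget-impact report, individual trajectory simulation, a probabilistic
    sensitivity analysis with coupled parameter perturbations, a one-sided
    Wilcoxon signed-rank robustness test with an exact small-sample branch,
    and a break-even cost-shift search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
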