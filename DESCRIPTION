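Package: vforage
Title: Sequential Decision-Making Analysis for a Virtual Foraging Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing sequential decision-making in a
    finite-horizon virtual foraging task. Provides an exact solver for
    the underlying survival Markov decision process (backward induction
    over energy states, weather types and days), a battery of heuristic
    decision variables, a task simulator and synthetic-participant
    generator, maximum-likelihood logistic choice models with
    BIC-based evidence, fixed-effects log group Bayes factors and
    random-effects Bayesian model selection with protected exceedance
    probabilities, choice-uncertainty and policy-discrepancy metrics,
    and hierarchical reaction-time regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
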