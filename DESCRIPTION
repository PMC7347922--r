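Package: preyselect
Title: Prey-Selection Foraging Task Simulation and Reward-Rate Learning Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates serial-encounter prey-selection foraging tasks and fits
    reward-rate reinforcement-learning models to the resulting choice data.
    Provides the task designs (rich/poor/worst-only environments with forced
    attention-check trials), Symmetric and Asymmetric delta-rule models of the
    per-second average reward rate with a softmax accept/reject policy,
    synthetic cohort generation, hierarchical empirical-Bayes fitting by
    Expectation Maximization with Laplace approximations, leave-one-subject-out
    cross-validated model comparison, a learning-bias contrast, and the
    descriptive and inferential behavioural analyses (acceptance tables,
    difference scores, previous-offer effects, mixed-design ANOVA) together
    with order-effect, asymmetry-cost and parameter-recovery simulation
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
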