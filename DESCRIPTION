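Package: strainrl
Title: Multi-Agent Reinforcement Learning for Microbial Strain Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free, multi-agent reinforcement learning for optimizing
    metabolic enzyme expression levels in the Design-Build-Test-Learn cycle
    of microbial strain engineering. The policy is learned by Maximum Margin
    Regression (MMR), an SVM-like kernel learner over state-action-reward
    histories whose dual is a box-constrained quadratic program; exploration
    across parallel agents is driven by a Gram-Schmidt action perturbation
    that provably does not shrink the volume spanned by the agents' actions.
    Includes pluggable simulation environments (a smooth kinetic-model
    surrogate and a combinatorial promoter-library lookup), random-search and
    Bayesian-optimization baselines run under an identical experimental
    budget, and evaluation statistics (best-found trajectories, relative
    standard deviation stability, noise-degradation summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
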