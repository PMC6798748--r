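Package: icudce
Title: Design and Analysis of Choice Experiments on ICU Admission Decisions
Version: 0.1.0
Authors@R: person("ICU DCE", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for discrete choice experiments (DCEs) eliciting how
    intensive-care consultants weight patient factors in admission
    decisions: D-efficient paired-profile task generation with warm-up and
    quality-check tasks, simulation of respondents with latent preference
    classes, response-quality screening (desirability, stability, logical
    consistency, response time), pooled and conditional logit estimation
    with cluster-robust inference, range-based relative attribute
    importance, latent-class logit estimation by EM with covariate-driven
    class membership, comorbidity type-by-severity interaction contrasts,
    and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
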