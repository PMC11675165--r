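Package: aseCausal
Type: Package
Title: Causal Inference for the Allostatic Self-Efficacy Model of Fatigue and Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for testing the allostatic self-efficacy (ASE) account of
    fatigue and depression with methods from graphical causal inference. The
    package encodes the ASE structural causal model as a linear-Gaussian
    system over questionnaire variables (metacognition of allostatic control,
    fatigue, general self-efficacy, depression, plus age and gender as
    confounders), decides d-separation and backdoor adjustment on the induced
    directed acyclic graph, simulates observational and interventional
    cohorts, tests the graph's conditional-independence implications with
    three test families (conditional-Gaussian mutual information, the
    generalised covariance measure, and a kernel conditional-independence
    test), and estimates average causal effects by covariate-adjustment
    regression, generalised propensity-score weighting, and double/debiased
    machine learning. Single-edge graph revisions can be scored against
    observed test decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
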