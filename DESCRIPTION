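Package: netperm
Title: Permutation Inference for Ridge Partial-Correlation Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of ridge-regularized partial-correlation networks from
    parcellated resting-state time series, signed weighted graph summary
    metrics (positive/negative total clustering, global efficiency, node
    strength), permutation-based general linear model inference with
    Freedman-Lane nuisance handling, non-parametric combination (Fisher) joint
    tests, network-based statistics with component-level family-wise error
    control, and Benjamini-Hochberg false discovery rate control over
    comparison families. Includes a synthetic-cohort generator emulating a
    deep-brain-stimulation ON/OFF case-control design (healthy controls, two
    patient sessions, a psychiatric subgrouping, and nuisance covariates with
    missingness) so the full pipeline can be exercised and validated without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
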