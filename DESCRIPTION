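Package: y90ici
Title: Virtual Clinical Trials of Yttrium-90 Radioembolization Combined
    with Immune Checkpoint Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tumor-immune dynamics simulator for hepatocellular carcinoma
    treated with yttrium-90 radioembolization (Y90-RE) and immune checkpoint
    inhibitors (ICIs). Four ordinary differential equations track targeted
    tumor cells, non-targeted (out-of-field) tumor cells, radiation-inactivated
    antigen-releasing cells, and circulating lymphocytes; radiation kill is
    applied as discrete linear-quadratic survival events driven by the
    exponential decay of the Y90 source, and the checkpoint inhibitor acts as
    a transient multiplicative boost to immune-mediated kill. The package
    generates seeded virtual patient cohorts, calibrates the Y90 effectiveness
    distribution against RECIST response profiles, and runs five-arm in silico
    trials (monotherapies, concurrent and the two sequential orderings),
    reporting Kaplan-Meier progression-free survival, distant-metastasis
    incidence, and log-rank comparisons across dose grids and inter-drug
    interval sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
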