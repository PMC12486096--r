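Package: rimflow
Title: CSF and Blood Immune Profiling Pipeline for Paramagnetic Rim Lesion Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable implementation of the computational procedures used to
    relate cerebrospinal-fluid (CSF) and blood immune profiles to paramagnetic
    rim lesion (PRL) burden in multiple sclerosis: two-stage single-cell quality
    control and cluster pruning, erythrocyte/platelet "peripheral contribution"
    correction of CSF cell-type counts, permutation-based cell-composition
    testing with bootstrap confidence intervals, binned-control interferon
    module scoring, paired-chain T-cell receptor clonality analysis, and
    covariate-adjusted Olink NPX proteomics with CSF:serum compartmentalization
    ratios. A synthetic cohort generator with known ground truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    limma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
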