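Package: masct
Title: Multi-Atlas Synthetic CT Generation from Dixon MRI
Version: 0.1.0
Authors@R: person("MASCT", "Developers", role = c("aut", "cre"),
    email = "masct@example.org")
Description: Generates synthetic CT (pseudo-CT) volumes from Dixon
    water/fat MRI for MR-only radiotherapy planning of the pelvis.
    Conditions planning CT and MR images into a shared intensity frame
    (bias-field reduction, landmark histogram standardization, fuzzy
    c-means tissue clustering, bone/fat suppression), builds a
    co-registered CT-MR atlas via landmark-initialized rigid plus
    B-spline deformable registration with a mean-squared-error cost,
    propagates the atlas onto a new subject's fat-enhanced water image,
    and fuses atlas CT values with inverse generalized-registration-error
    (GRE) weighting after a 2-mm in-plane best-match search. Includes
    mean-absolute-error evaluation by tissue region, leave-one-out and
    train/test drivers, and a seeded pelvis phantom-cohort generator so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
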