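Package: ctnorm
Title: Weighted-Mean Pseudo-Control Normalization of RT-PCR CT Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalization of microRNA (and gene) RT-PCR Cycle-Threshold (CT)
    matrices using a weighted-mean pseudo endogenous control, in which every
    assay contributes to the per-sample reference CT0 with a weight determined
    by its empirical stability (inverse across-sample standard deviation raised
    to a tunable power). Includes the classical baselines it is compared
    against (mean/median/geometric-mean and top-k stable-gene pseudo-controls,
    quantile, median-shift, cyclic-loess and rank-invariant-set normalization),
    the delta-CT / delta-delta-CT / fold-change calculus, geNorm-style
    stability scoring and enumeration-based selection of the weighting power,
    diagnostics for the expression-level-dependent variance bias of CT data,
    RT-PCR vs microarray concordance statistics, and a synthetic CT-matrix
    generator with recorded ground truth for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), limma, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
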