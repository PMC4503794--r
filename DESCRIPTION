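Package: qmtbssfp
Title: Quantitative Magnetization Transfer Imaging with Balanced SSFP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward two-pool (binary spin bath) signal models for balanced
    steady-state free precession (bSSFP) and spoiled gradient echo (SPGR)
    acquisitions, variable flip angle T1 mapping, voxel-wise nonlinear
    least-squares estimation of the bound proton fraction, free-to-bound
    magnetization exchange rate and free-water T2, a synthetic two-session
    crossover cohort generator with an inflammation-like regional exchange-rate
    effect and correlated fatigue and interleukin-6 covariates, and group-level
    inference: Gaussian smoothing, paired t maps, Monte Carlo cluster-extent
    correction, small-volume family-wise error by sign-flip permutation,
    region-of-interest regression, repeated-measures interaction tests,
    grand-mean scaling and exclusive masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
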