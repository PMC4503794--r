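# qmtbssfp

Quantitative magnetization transfer (qMT) imaging with balanced
steady-state free precession (bSSFP), for studies of how systemic
inflammation changes brain microstructure. The package is aimed at
quantitative-MRI methodologists and neuroimaging statisticians who want a
fully synthetic, testable re-implementation of a two-session
(vaccine/placebo crossover) qMT pipeline: forward signal models, voxel-wise
parameter mapping, a cohort simulator with a known regional effect, and the
group-level inference used on such data.

## The model

Each voxel is a binary spin bath: a free water pool with Bloch dynamics and
a semisolid bound pool with longitudinal magnetization and an absorption
lineshape G (super-Lorentzian by default). The estimated parameters are the
bound proton fraction `F`, the free-to-bound exchange rate `k_f` (s⁻¹, with
reverse rate `k_f/F` by detailed balance) and the free-water `T2f`. During
a rectangular RF pulse of flip angle α and duration τ the bound pool is
saturated at rate `W = π ω₁² G(0)` with `ω₁ = α/τ`; the on-resonance,
alternating-phase bSSFP steady state of the coupled system is available in
closed form (exact 2×2 exchange-relaxation propagation between
instantaneous excitations) and, independently, from a brute-force
Bloch–McConnell time-stepping simulator that serves as the numerical ground
truth. T1 mapping uses the standard variable-flip-angle SPGR inversion
`S = M0 sinα (1−E1)/(1−E1 cosα)`, and the free-pool T1 is tied to the
observed T1 through the slowest eigenmode of the exchange-relaxation
matrix.

Group inference mirrors the field's standard pipeline: 8-mm FWHM masked
Gaussian smoothing, voxel-wise paired t maps, Monte Carlo cluster-extent
correction at a cluster-forming threshold of p = .001, sign-flip
permutation family-wise error within regions of interest, ROI-mean
regression of fatigue change on exchange-rate change, 2×2
repeated-measures interaction tests, grand-mean scaling (to 50) and
exclusive masking (p < .005) for uptake-like maps.

## Worked example

Forward-simulate one gray-matter-like voxel through the packaged 22-volume
bSSFP protocol, add Rician noise at SNR 100, and fit it back:

```r
library(qmtbssfp)

prot <- default_protocol()
bs <- subset(prot, kind == "bssfp")
truth <- two_pool_params(m0 = 1000, f = 0.12, kf = 3.0,
                         t1f = 1.05, t2f = 0.07)
signals <- bssfp_two_pool_signal(truth, bs)

set.seed(42)
sigma <- mean(signals) / 100
noisy <- sqrt((signals + rnorm(22, 0, sigma))^2 + rnorm(22, 0, sigma)^2)
fit <- fit_qmt_voxel(noisy, bs, t1_observed = observed_t1(truth))
round(unlist(fit[c("f", "kf", "t2f", "m0")]), 4)
#>         f        kf       t2f        m0
#>    0.1141    2.7332    0.0685 1003.9407
```

The fitted bound proton fraction (0.114 vs. true 0.12), exchange rate
(2.73 s⁻¹ vs. 3.0) and free-water T2 (68.5 ms vs. 70) show one noisy
voxel's scatter; across 500 such replicates the relative RMSE of `k_f` is
about 9%. The closed form and the Bloch–McConnell oracle agree to about
one part in 10⁵ at a typical protocol point:

```r
seqr <- acquisition_spec("bssfp", flip_deg = 35, tr_ms = 4.81, trf_ms = 1.38)
bssfp_two_pool_signal(truth, seqr)       #> 123.4047
bloch_mcconnell_steady_state(truth, seqr) #> 123.4036
```

A complete synthetic study — phantom, two sessions per subject, Rician
noise, fitted maps, cluster statistics, behavioral table — runs from the
command line:

```sh
Rscript inst/cli/qmtbssfp.R simulate --config config.yaml --out cohort/
Rscript inst/cli/qmtbssfp.R fit-t1  --data cohort/
Rscript inst/cli/qmtbssfp.R fit-qmt --data cohort/
Rscript inst/cli/qmtbssfp.R group   --data cohort/
Rscript inst/cli/qmtbssfp.R behave  --data cohort/
```

See the methods vignette (`vignettes/qmt-inflammation-pipeline.Rmd`) for
the model assumptions, parameter defaults, calibration of the synthetic
generator, and known limitations.

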