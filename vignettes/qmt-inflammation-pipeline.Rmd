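---
title: "Quantitative magnetization transfer with balanced SSFP: models, fitting and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative magnetization transfer with balanced SSFP: models, fitting and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmtbssfp)
```

## The problem

Peripheral inflammation changes the brain's microstructural environment on
a time scale of hours. Quantitative magnetization transfer (qMT) imaging is
sensitive to such changes: it models the exchange of longitudinal
magnetization between free water protons and protons bound to
macromolecules, and estimates physical parameters of that exchange rather
than a semi-quantitative contrast ratio. This package implements, end to
end and fully synthetically testable, a qMT analysis of a two-session
(inflammatory challenge vs. placebo) crossover study: forward signal
models, voxel-wise parameter estimation, a cohort generator with a known
regional effect, and the group-level statistical machinery (smoothing,
paired t maps, Monte Carlo cluster-extent correction, small-volume
family-wise error, region-of-interest regression against fatigue, and
grand-mean-scaled exclusively-masked contrasts for uptake-like maps).

## The two-pool signal model

Each voxel is a binary spin bath: a free (liquid) pool with full Bloch
dynamics, and a semisolid bound pool represented by its longitudinal
magnetization and an absorption lineshape. The parameters are the free-pool
equilibrium magnetization $M_0$, the bound proton fraction
$F = M_0^b / M_0^f$, the pseudo-first-order forward exchange rate $k_f$
(s$^{-1}$; detailed balance fixes the reverse rate $k_b = k_f / F$), the
free-pool relaxation times $T_1^f, T_2^f$, and the conventionally fixed
bound-pool constants $T_1^b = 1$ s and $T_2^b = 12\,\mu$s.

During a rectangular radiofrequency (RF) pulse of flip angle $\alpha$ and
duration $\tau$, the bound pool is saturated at the mean rate
$W = \pi\,\omega_1^2\,G(0)$ with $\omega_1 = \alpha/\tau$ and $G$ the
absorption lineshape evaluated on resonance. The super-Lorentzian lineshape
(default for brain tissue) diverges on resonance; its on-resonance value is
obtained by quadratic extrapolation from 1 kHz, a documented convention
(`lineshape_value()`).

The balanced SSFP (bSSFP) steady state is computed in closed form for the
hybrid excitation model: an instantaneous rotation $\pm\alpha$ of the free
pool with alternating phase, a bound-pool saturation factor $e^{-W\tau}$
per pulse, and exact inter-pulse relaxation/exchange through the
$2\times 2$ longitudinal exchange-relaxation matrix (analytic
eigendecomposition). The reported amplitude is referenced to TE = 0; for
$F = 0$ the expression reduces exactly to the textbook single-pool bSSFP
formula, and the spoiled gradient echo (SPGR) model
$S = M_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$ covers the variable flip
angle (VFA) series.

**Ground truth.** `bloch_mcconnell_steady_state()` is the package's
numerical authority: it time-steps the coupled magnetization equations
through repeated TRs (RK4 inside the saturation window, matrix exponential
elsewhere, via an independent code path) until a periodic steady state is
reached. It shares the instantaneous-rotation convention — finite-RF
transverse dynamics are outside the model for both routes, which is the
package's declared scope — so the comparison isolates the closed form's
lumped-saturation and propagation algebra. Agreement on a 108-point
physiological grid across all 22 protocol volumes is a tested invariant
(worst case $\sim 2\times10^{-4}$ relative).

## The acquisition protocol

The default protocol (`default_protocol()`) has 22 bSSFP volumes spanning
flip angles 5°–40°, repetition times 3.66–5.96 ms and pulse durations
0.23–2.53 ms, plus a 3-point SPGR VFA series (5°/15°/25°, TR 30 ms). Only
these ranges are fixed by the acquisition design; the grid within them is a
package convention. It was chosen by a Cramér–Rao bound analysis of the
two-pool model at a gray-matter operating point: allocating 8 volumes to a
flip-angle series at the shortest TR and 14 volumes to a pulse-duration
series at the largest flip angle puts the $k_f$ CRLB near 8% relative at a
signal-to-noise ratio (SNR) of 100, roughly 40% tighter than a uniform
split. Saturation scales as $W\tau \propto \alpha^2/\tau$, so short pulses
at large flip angles carry most of the exchange information.

## Parameter estimation

**T1.** The VFA series is inverted by the standard linearization
($y = S/\sin\alpha$ on $x = S/\tan\alpha$; slope $E_1$), with an optional
nonlinear polish. The observed $T_1$ of the coupled system is the slowest
longitudinal eigenmode of the exchange-relaxation matrix; `derive_t1f()`
inverts that relation in closed form so the fit can hold the free-pool
$T_1^f$ consistent with the measured value at the current $(F, k_f)$
iterate (`t1_mode = "eigen_corrected"`, the default; the observed value can
also be used directly).

**qMT.** `fit_qmt_voxel()` minimizes the residual between measured and
modeled bSSFP signals over $(M_0, F, k_f, T_2^f)$ with Levenberg–Marquardt
under box bounds ($F \in [0.001, 0.5]$, $k_f \in [0.1, 20]$ s$^{-1}$,
$T_2^f \in [10, 300]$ ms — physiological brain ranges), from a single
deterministic start ($F = 0.1$, $k_f = 2$, $T_2^f = 80$ ms, $M_0$
scale-matched to the data). Noiseless forward-simulated voxels are
recovered to well below 0.1% from jittered starts, so the criterion surface
is benign in the physiological box. Degenerate voxels (all-zero signals,
invalid T1) are flagged, never interpolated; non-convergent voxels retain
their last iterate with `converged = FALSE` so downstream statistics can
exclude them explicitly.

## The synthetic cohort

`build_phantom()` constructs a procedural (not anatomical) digital brain on
a 32×32×8 grid of 3 mm voxels by default: an ellipsoidal gray-matter
mantle, white-matter core, small CSF compartment, deep gray "basal
ganglia" blobs, and insula-like ellipsoidal ROIs in the lateral gray matter
of each hemisphere (ROIs are intersected with the gray label, so
containment holds by construction). Tissue parameters are literature-style
1.5 T values (gray: $F=0.08$, $k_f=2.6$, $T_1=1.15$ s, $T_2^f=85$ ms;
white: $F=0.14$, $k_f=4.2$, $T_1=0.65$ s, $T_2^f=55$ ms). The grid is a
deliberate size compromise: large enough for realistic smoothing and
clustering geometry, small enough that replicate studies run in minutes on
one CPU (a demonstration grid of 64×64×16 works unchanged).

The condition effect is a mean $\Delta k_f = 0.5$ s$^{-1}$ increase
(between-subject SD 0.2 s$^{-1}$) inside the left insula-like ROI under
the vaccine condition — roughly a 20% regional increase over the
gray-matter baseline, a deliberately robust effect consistent with a study
that detected it at whole-brain corrected thresholds with n = 20. Raw
volumes add Rician noise: magnitude of a complex signal with Gaussian
channel noise $\sigma$ = (gray-matter mean bSSFP signal)/SNR, SNR = 100 by
default.

The behavioral table echoes the study's printed group statistics as
generator settings: fatigue (visual analog scale) baselines 16.18 ± 12.57
(vaccine) and 22.08 ± 17.72 (placebo); mean changes of +26.22 and +7.52
with change-score SDs 19.38 and 17.42 recovered from the printed paired t
statistics ($\mathrm{sd} = \bar d \sqrt{n}/t$ at n = 20); interleukin-6
drawn log-normally per condition and timepoint, moment-matched to
1.29 → 3.74 pmol/L (vaccine) and 0.97 → 0.90 pmol/L (placebo) with SDs
from the printed standard errors (× $\sqrt{20}$). The vaccine fatigue
change is linear in the subject's regional $\Delta k_f$ with residual noise
set so the *expected sample* $R^2$ across n subjects equals the 0.24
target: the sample $R^2$ is upward-biased at small n, so the generator
inverts the exact bivariate-normal expectation
$E[R^2] = 1 - \frac{n-2}{n-1}(1-\rho^2)\,{}_2F_1(1,1;\tfrac{n+1}{2};\rho^2)$
(series implementation, verified against brute-force simulation). When the
cohort is too small for the target to be reachable (the null expectation
already exceeds it), the population $\rho^2$ is used directly.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: anatomy, registration and segmentation error,
motion, B0/B1 field inhomogeneity (the model assumes uniform B1 and
on-resonance bSSFP, reasonable at 1.5 T with body-coil transmission),
physiological noise correlations, within-subject IL-6 correlation across
timepoints, and scanner drift between sessions. Uptake-like maps for the
contrast-logic operations are plain smoothed Gaussian fields with ROI
offsets, not a physical PET simulation.

## Group inference

Parameter maps are smoothed with a renormalized masked Gaussian kernel
(8 mm FWHM on 3 mm voxels by default; a constant map is exactly preserved
inside the mask), and the vaccine–placebo contrast is tested per voxel with
a paired t statistic. Cluster-extent correction follows the Monte Carlo
logic: noise fields are smoothed inside the mask, standardized,
thresholded at the cluster-forming level ($p = .001$ one-sided by default,
matching a directional increase contrast; 26-connectivity), and the
critical extent $k^*$ is the smallest integer whose null max-cluster
exceedance is at most $\alpha = .05$.

Two numerical details matter for calibration. First, re-standardization is
per voxel: the variance of renormalized masked smoothing,
$\mathrm{Var}_i = \sum_j K_{ij}^2 / (\sum_j K_{ij})^2$, is computed
analytically (the squared Gaussian kernel is a Gaussian at
$\sigma/\sqrt2$), so mask-boundary voxels — most of a thin-slab grid — are
standardized exactly like interior ones, mirroring the per-voxel
self-normalization of the t map the threshold is applied to. Second, the
null field can be degrees-of-freedom matched (`df` argument): each
iteration draws $df+1$ smoothed noise maps and forms the actual one-sample
t field. A single Gaussian field (the procedure's classic form, and the
function's default) is slightly conservative at small n because a t field
is rougher than its underlying Gaussian; the pipeline (`run_group()`)
therefore passes `df = n - 1`. With the df-matched null, 5000 calibration
iterations and 300 replicate null cohorts, the measured whole-pipeline
family-wise false-positive rate sits within the binomial 95% interval
around 0.05 (residual slack reflects the discreteness of integer cluster
extents).

Region-of-interest inference uses distribution-free sign-flip permutation
of the paired differences with the max-t statistic over ROI voxels (exact
enumeration of all $2^n$ patterns when feasible) — a deliberate,
desk-testable substitution for parametric small-volume FWE. ROI mean
changes are computed on *unsmoothed* difference maps so the regional
effect-size estimate is not shrunk by kernel dilution, then regressed
against the fatigue change (ordinary least squares; two-sided slope p from
$t_{n-2}$). The 2×2 within-subject interaction is computed through the
exact identity $F = t^2$ on the per-subject difference-of-differences
(df 1, n−1); a full repeated-measures ANOVA serves as the test oracle, not
the implementation. Uptake-like maps are grand-mean scaled to 50 inside
the mask and exclusively masked: voxels exceeding the control contrast's
one-sided threshold at $p = .005$ are invalidated.

## Replication-study design

The signal models, T1 and qMT fits are exercised on raw signals
(inverse-crime recovery; Rician Monte Carlo at SNR 50/100/200 with 250–1000
replicates). Group-level calibration and power studies run at the
parameter-map level: subject maps are truth plus Gaussian voxel noise whose
SD is itself calibrated by a 200-replicate Monte Carlo of the complete
per-voxel pipeline (Rician noise → VFA T1 fit → qMT fit) at the phantom
SNR (`estimate_kf_sigma()`). This keeps 300-cohort null studies and
100-cohort power studies within minutes on one CPU while preserving the
empirically measured fit-noise scale; the raw-image route is run end to end
by the pipeline tests at small n. Determinism is scoped: every seeded
helper restores the caller's RNG stream on exit, so replicate loops remain
independent while individual calls stay reproducible.

## Known limitations

- Finite-RF transverse dynamics during the pulse are outside the model; at
  large pulse-duty cycles real bSSFP signals deviate by several percent
  from any instantaneous-rotation treatment, which would bias absolute
  parameter values (though much less their paired within-subject change).
- Bound-pool constants $T_1^b$, $T_2^b$ and the lineshape are fixed, not
  fitted; misspecification propagates into $F$ and $k_f$.
- The sign-flip ROI test assumes symmetric paired differences under the
  null; the cluster machinery assumes stationary smoothness inside the
  mask.
- IL-6 draws are independent across cells, so generator interaction
  statistics for IL-6 understate a design with strong within-subject
  correlation.
- No registration, segmentation or B1/B0 mapping: phantoms are born
  co-registered on a common grid.
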