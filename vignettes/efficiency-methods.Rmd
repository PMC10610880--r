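---
title: "T2* contrast efficiency at mid-field: models, phantom, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{T2* contrast efficiency at mid-field: models, phantom, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epieff)
```

## The problem

At mid-field (~0.5 T) gray matter relaxes with a short T1 (≈ 717 ms) and a
long effective T2\* (≈ 86 ms). BOLD contrast in a spoiled gradient-echo
image is proportional to TE·e^(−TE/T2\*) and peaks at TE = T2\*, which
suggests very long echo times. But a single-shot EPI readout at fMRI
resolution is short — an echo train of 70 lines at ~0.46 ms spacing lasts
only ~32 ms — so placing the k-space center at TE = 86 ms forces tens of
milliseconds of dead time per slice, which multiplies across the slice
stack into seconds of extra TR. Fewer images then fit into a fixed scan
duration, and the time-series SNR suffers. `epieff` makes this trade-off
explicit and optimizes it.

## Models

### Sequence timing

A single-shot 2-D multi-slice GRE-EPI acquisition is described by
`epi_protocol()`. With a linearly ordered echo train the center line is
reached ETL/2 echo spacings after the train starts, so

- minimum TE = prep_time + esp·ETL/2,
- dead time = TE − prep_time − esp·ETL/2 (non-negative by construction),
- TAD = ETL·esp, and the phase-encode pixel bandwidth is 1/TAD; geometric
  distortion along the phase-encode axis scales with its reciprocal.

`prep_time` (excitation, slice rewinder, phase-encode prephaser) defaults
to 3 ms. It is not separately measurable from protocol tables and shifts
only the absolute dead time, never the efficiency optimum.

When the echo spacing is not given it is derived as
`matrix_readout / acq_bandwidth × (1 + ramp_fraction)` with
`ramp_fraction = 0.035`: flat-top sampling of one readout line at the
total acquisition bandwidth plus a small gradient-ramp overhead. For the
4 mm reference family (60 readout points at 160 kHz) this gives
esp ≈ 0.388 ms and a phase-encode bandwidth of ≈ 43 Hz/pixel, matching
the timing of the acquired protocols; a high-performance gradient set
keeps ramp overhead in the few-percent range at these bandwidths.

Multi-slice TR follows TR = n_slices × (TE + c). The per-slice overhead
`c` is calibrated from a (TE, TR) table by least squares under a unit
slope constraint (`calibrate_overhead()`); on both reference tables the
model holds with residuals under 1 ms (c ≈ 20.76 ms for the 38-slice
3.4 mm family, 18.31 ms for the 32-slice 4 mm family).

### Efficiency

The single-image BOLD SNR model is

$$\mathrm{SNR}_{BOLD} \propto \Delta x\,\Delta y\,\Delta z \cdot
TE\,\sqrt{T_{AD}} \cdot
\frac{(1-E)\sin\alpha}{1-E\cos\alpha}\,e^{-TE/T_2^*},
\qquad E = e^{-TR/T_1},$$

with proportionality constant 1 (arbitrary units; only ratios between
protocols are meaningful). The TE factor is the linear BOLD sensitivity,
√TAD the noise-averaging benefit of a longer readout, and the bracket the
spoiled steady state, maximized by the Ernst angle
α_E = arccos(e^(−TR/T1)). TE multiplies the expression linearly while TAD
enters under a square root; TAD is constant within each protocol family,
so the location of the TE optimum does not depend on the TAD exponent.

For N images in a time series with uncorrelated noise the effective SNR is
√N times the single-image value, and at fixed total scan time TS = N·TR

$$\widetilde{\mathrm{SNR}} = \sqrt{TS}\cdot\eta_{T_2^*},\qquad
\eta_{T_2^*} = \mathrm{SNR}_{BOLD}/\sqrt{TR}.$$

`optimize_te()` maximizes η. In grid mode (a measured protocol family)
the flip angles default to the exact Ernst angle but a table of prescribed
integer angles can be supplied; the difference is below 0.1 % of η. Exact
ties break toward the smaller TE, which also minimizes dead time and TR.
In continuous mode with TR decoupled from TE the steady-state and 1/√TR
factors are constants, the optimum of TE·e^(−TE/T2\*) is TE = T2\*
exactly, and that closed form is returned rather than a numerical
maximizer; with a supplied TR(TE) the curve is maximized numerically
(`stats::optimize`, tolerance 1e-8), and any strictly increasing TR(TE)
pulls the optimum below T2\*.

### Relaxometry

`fit_monoexp()` fits S(TE) = S0·e^(−TE/T2\*). The default estimator is a
weighted log-linear fit with weights ∝ S², which makes log-domain least
squares equivalent to first-order signal-domain least squares and removes
most of the low-SNR log-bias; `method = "nonlin"` refines with
Levenberg–Marquardt (`minpack.lm`). Magnitude data are treated as
Gaussian, appropriate at echo SNR ≥ 10; no Rician bias correction is
applied, and echoes below 3× a supplied background noise SD are excluded.
Fits are flagged invalid (never silently zeroed) when fewer than 3 echoes
survive, the decay is non-negative, r² < 0.8, or T2\* falls outside
[1, 2000] ms — wide brackets that only reject numerical nonsense.
Goodness of fit is reported in the signal domain.

### Noise decomposition

`pseudo_replica_snr()` adds correlated complex Gaussian noise to one
k-space acquisition many times (default 128 replicas), reconstructs each
(centered unitary inverse FFT per slice per coil, root-sum-of-squares coil
combination), and reports voxel-wise mean/SD across replicas. The
covariance convention: the coil matrix Ψ is the covariance of each noise
quadrature, so a diagonal value σ² produces a high-SNR magnitude-image
noise SD of σ for a single coil — which makes the closed-form oracle
(signal 100, σ = 5 → SNR 20) hold exactly and keeps pSNR on the same
footing as tSNR. Coloring uses an eigendecomposition square root of Ψ
(base `chol()` does not handle complex Hermitian matrices). The unitary
FFT convention means Parseval holds with no extra factors and k-space
noise maps to image noise at the same SD.

`temporal_snr()` is voxel mean / temporal SD over repeated acquisitions
(≥ 8; default study condition 64), optionally linearly detrended (off by
default — the phantom's fluctuations are stochastic, not drifts). The
physiological-to-thermal ratio is σ_P/σ_T = √((pSNR/tSNR)² − 1); where
sampling noise makes pSNR < tSNR the ratio is undefined and returned as
`NA`, never imaginary. σ_P/σ_T < 1 means thermal-noise dominance.

`summarize_snr()` reports the ratio per ROI in two labeled variants:
the ROI mean of the voxel-wise ratio map, and the ratio recomputed from
ROI-mean SNRs. The voxel-wise variant inherits a noticeable negative
Jensen bias at realistic replica/repeat counts (the square root is
concave in (pSNR/tSNR)²), so quantitative recovery checks use the
ratio-of-means variant; both are returned.

## The digital phantom

`phantom_spec()` / `make_tissue_phantom()` build a brain-like object:
a white-matter ellipsoidal core (55 % of the grid half-width), a
gray-matter shell out to the brain surface (85 %), and a visual-cortex
patch (the posterior sector of the shell), mutually disjoint, with
T1 = 717.2 ms everywhere and T2\* of 86.3 / 77.9 / 78.5 ms for GM / WM /
VC by default, optionally with voxel-wise Gaussian T2\* spread. Coil
sensitivities are smooth complex Gaussian lobes on a ring with linear
phase ramps (`synthesize_coils()`); the unit noise covariance is identity
plus uniform off-diagonal coupling ρ (default 0.1).

`simulate_epi_timeseries()` forms, per repetition,

$$I_t(x) = S(x)\,\bigl(1 + \lambda_c\,g_t +
\lambda_b\,\tfrac{TE}{T_2^*(x)}\,h_t\bigr),$$

multiplies by the coil maps, transforms to k-space, and adds correlated
thermal noise. The two-term physiological model follows the standard
decomposition into a signal-proportional non-BOLD term and a BOLD-like
term; writing the BOLD weight as TE/T2\* (the relative sensitivity of
e^(−TE/T2\*) to a T2\* fluctuation) makes the injected σ_P/σ_T grow as
TE·e^(−TE/T2\*), i.e. monotonically up to TE = T2\*, reproducing the
qualitative TE-dependence seen in vivo; it also grows with voxel volume
at fixed thermal noise, reproducing the voxel-size dependence.

`g_t` and `h_t` are AR(1) processes (coefficient 0.9, a low-frequency
drift-like spectrum). Each realization is standardized to zero mean and
unit sample SD and `h` is orthogonalized against `g`. This is deliberate:
a 64-sample AR(1) with coefficient 0.9 has ~3 effective degrees of
freedom, so without in-sample standardization the realized physiological
variance would fluctuate by tens of percent from run to run and no
finite-length recovery check could be quantitative. Only the variance
enters the decomposition, so standardization costs no generality.

Thermal noise is set either directly (k-space SD) or via a target
gray-matter SNR; a target gray-matter σ_P/σ_T can be requested, in which
case λ_c is calibrated against the analytic ground-truth maps
(`uniroot`, tolerance 1e-10). The simulator returns those ground-truth
maps (signal, σ_T, σ_P, ratio) alongside the k-space, so recovery is
checked against what was actually injected.

What the phantom does *not* emulate: real anatomy and atlas geometry,
susceptibility-induced B0 inhomogeneity and the resulting distortion or
T2\* dispersion, motion and spin-history effects, T2\* decay across the
echo train (readout blurring), ghosting, ramp sampling, and low-SNR
Rician statistics. Tests passing on the phantom therefore validate the
estimators and their statistical calibration — not robustness to
artifacts of in-vivo acquisition, which require measured data.

## Problem sizes and tolerances

The test suite runs the simulation chain at reduced sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances: grids of
32×32×6 or smaller with 2–4 coils for property checks, and the full
default phantom (40×40×10, 8 coils) with the study conditions of 64
repeats and 128 replicas for the quantitative recovery check, where the
ROI-level ratio-of-means estimator has relative error of a few percent
against a 10 % acceptance band. The per-voxel SNR estimator's relative
SD, 1/√(2(n_replicas − 1)), is itself verified across seeds at 32 / 128 /
512 replicas. Timing-model and efficiency checks are deterministic and
exact to printed precision (TRs within 1 ms; noiseless T2\* recovery to
at least six significant figures).

## Known limitations

- The TR model is linear in TE with unit slope; sequences with
  TE-dependent per-slice overhead (e.g. variable fat-saturation timing)
  would need a different calibration.
- The efficiency metric compares protocols within a family at fixed TAD
  and resolution; it does not model parallel-imaging g-factor noise,
  partial Fourier, or multi-echo readouts.
- Magnitude statistics are Gaussian approximations valid at SNR ≥ ~10;
  the pseudo-replica and temporal estimators are both biased in the
  Rayleigh regime (e.g. background air), where the noise-ratio map is
  not meaningful.
- The 4 mm family's efficiency optimum is a near-tie (TE 55 vs 65 ms
  differ by < 0.1 %), inside any realistic measurement error; only the
  3.4 mm optimum is a sharp prediction.
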