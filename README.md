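# epieff

Protocol optimization for BOLD fMRI with gradient-echo EPI at mid-field
(~0.5 T), where gray matter has a short T1 (≈ 717 ms) and a long T2\*
(≈ 86 ms). Long T2\* is usually taken to favor long echo times — the
classic result is that BOLD contrast peaks at TE = T2\* — but at the modest
matrix sizes used for fMRI a single-shot echo train is much shorter than
T2\*, so pushing TE out to T2\* inserts dead time between excitation and
readout and inflates TR. `epieff` quantifies this trade-off and finds the
echo time that maximizes BOLD sensitivity per unit scan time.

The package is for MR physicists and fMRI methodologists designing EPI
protocols on mid-field systems, and implements four connected pieces:

1. **Sequence timing model** — echo spacing, acquisition duration
   TAD = ETL × esp, minimum TE, dead time, phase-encode pixel bandwidth
   (whose reciprocal scales geometric distortion), and a calibrated
   per-slice TR model TR = n_slices × (TE + c).
2. **T2\* contrast efficiency** — the single-image BOLD SNR model

   SNR_BOLD ∝ ΔxΔyΔz · TE · √TAD · [(1 − E) sin α / (1 − E cos α)] ·
   e^(−TE/T2\*),  E = e^(−TR/T1),

   and the efficiency η_T2\* = SNR_BOLD / √TR. At fixed total scan time TS
   the achievable time-series SNR is √TS · η, so maximizing η — not
   SNR_BOLD — is the right criterion; flip angles follow the Ernst angle
   arccos(e^(−TR/T1)).
3. **Relaxometry** — voxel-wise mono-exponential T2\* mapping
   (S(TE) = S0·e^(−TE/T2\*)) from multi-echo GRE data with ROI summaries,
   NIfTI in/out.
4. **Noise decomposition** — pseudo-multiple-replica SNR (thermal only,
   from one k-space acquisition plus correlated noise replicas), temporal
   SNR (thermal + physiological, from repeated acquisitions), and the
   physiological-to-thermal noise ratio
   σ_P/σ_T = √((pSNR/tSNR)² − 1), with a digital multi-coil brain phantom
   that forward-simulates EPI k-space time series with known injected
   noise so the whole chain can be validated end-to-end.

## Worked example

Efficiency optimization over the 3.4 mm reference protocol family (nine
echo times from 25 to 105 ms with their acquired TRs and Ernst-angle flip
angles), for gray matter at 0.5 T:

```r
library(epieff)
g  <- reference_protocol_grid("3.4mm")
ec <- optimize_te(relaxation_params(717.2, 86, "GM"),
                  g$te, g$tr, g$fa, voxel_volume = 3.4^3)
ec
#> T2* contrast-efficiency curve (grid mode; T1 = 717.2 ms, T2* = 86 ms)
#>   TE range 25-105 ms over 9 points
#>   optimal TE = 55 ms (eta = 20.87 a.u.); TE - T2* = -31 ms
```

Raw single-image SNR keeps rising out to TE = 85 ms (`ec$snr_bold` peaks
there), but each 10 ms of TE costs 380 ms of TR across the 38-slice stack,
and per square root of scan time the optimum lands at **TE = 55 ms** —
31 ms below the contrast-optimal TE = T2\*. The units of `eta` are
arbitrary; only ratios between protocols matter.

The full comparison report adds the timing consequences:

```r
compare_protocols()
#> Protocol comparison (T1 = 717.2 ms, T2* = 86 ms):
#>  family te_opt te_minus_t2star dead_time_opt tr_saved pe_bandwidth
#>   3.4mm     55             -31         35.93     1178        31.10
#>     4mm     65             -21         50.36      672        42.94
#>  distortion_factor
#>              5.350
#>              7.386
```

`tr_saved` is the TR reduction (ms) from running at the efficiency optimum
instead of TE = T2\*; `distortion_factor` is the geometric-distortion
advantage over the low-bandwidth protocol that would reach TE = T2\* with
zero dead time (the 4 mm family near-tie between TE 55 and 65 ms is
decided by < 0.1 % of η).

The synthetic validation loop — phantom, k-space simulation, RSS
reconstruction, pSNR/tSNR, noise decomposition — runs end-to-end with:

```r
rep <- validate_pipeline(phantom_spec(target_ratio = 0.5), seed = 1)
```

A thin command-line interface over these functions is installed at
`system.file("cli", "epieff.R", package = "epieff")` with subcommands
`timing`, `optimize`, `t2star-fit`, `snr`, `simulate`, `report`; see
`inst/extdata/protocols.yaml` for the annotated configuration format.

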