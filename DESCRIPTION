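Package: epieff
Title: T2* Contrast-Efficiency Optimization for Gradient-Echo EPI at Mid-Field
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing single-shot gradient-echo echo-planar imaging
    (GRE-EPI) protocols for BOLD functional MRI at mid-field strengths (around
    0.5 T), where gray-matter T2* is long and T1 is short. Implements a
    deterministic EPI timing model (echo spacing, acquisition duration, dead
    time, per-slice TR calibration, phase-encode bandwidth and geometric
    distortion comparison), the T2* contrast-efficiency metric (BOLD SNR per
    square root of repetition time) with Ernst-angle flip-angle selection and
    echo-time optimization, voxel-wise mono-exponential T2* relaxometry from
    multi-echo gradient-echo data, pseudo-multiple-replica and temporal SNR
    estimation with the physiological-to-thermal noise decomposition, and a
    digital brain-like phantom that forward-simulates multi-coil EPI k-space
    time series with controllable thermal and physiological noise for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
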