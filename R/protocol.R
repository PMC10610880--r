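#' Reference EPI protocol families
#'
#' The two single-shot GRE-EPI protocol families used throughout the package:
#' 3.4 mm and 4.0 mm isotropic acquisitions at 0.5 T, each a nine-point grid
#' of echo times from 25 to 105 ms with the repetition times and Ernst-angle
#' flip angles (for gray matter, T1 = 717.2 ms) acquired at each TE.
#' Both grids share an in-plane FOV of 240 mm and a total acquisition
#' bandwidth of 160 kHz.
#'
#' @param resolution `"3.4mm"` or `"4mm"`.
#' @return A data.frame with columns `te`, `tr`, `fa` (ms, ms, degrees) and
#'   attributes `etl`, `n_slices`, `voxel_mm`, `fov_mm`, `acq_bandwidth_hz`,
#'   `slice_fov_mm`.
#' @examples
#' reference_protocol_grid("3.4mm")
#' @export
reference_protocol_grid <- function(resolution = c("3.4mm", "4mm")) {
  resolution <- match.arg(resolution)
  te <- seq(25, 105, by = 10)
  if (resolution == "3.4mm") {
    out <- data.frame(
      te = te,
      tr = c(1738, 2119, 2499, 2879, 3259, 3639, 4019, 4399, 4779),
      fa = c(85, 87, 88, 89, 89, 90, 90, 90, 90)
    )
    attr(out, "etl") <- 70L
    attr(out, "n_slices") <- 38L
    attr(out, "voxel_mm") <- 3.4
    attr(out, "slice_fov_mm") <- 129.2
  } else {
    out <- data.frame(
      te = te,
      tr = c(1386, 1706, 2026, 2346, 2666, 2986, 3306, 3626, 3946),
      fa = c(82, 85, 87, 88, 89, 89, 89, 90, 90)
    )
    attr(out, "etl") <- 60L
    attr(out, "n_slices") <- 32L
    attr(out, "voxel_mm") <- 4.0
    attr(out, "slice_fov_mm") <- 128
  }
  attr(out, "fov_mm") <- 240
  attr(out, "acq_bandwidth_hz") <- 160e3
  attr(out, "resolution") <- resolution
  out
}

#' Construct a single-shot GRE-EPI protocol
#'
#' Builds a validated timing description of one single-shot 2-D multi-slice
#' GRE-EPI acquisition. Echo spacing may be given directly or derived from the
#' readout matrix and total acquisition bandwidth as
#' `esp = matrix_readout / acq_bandwidth * (1 + ramp_fraction)`, i.e. the
#' flat-top sampling time per line plus a small gradient-ramp overhead.
#' The echo train is assumed linearly (top-down) ordered so the k-space
#' center line is reached `etl/2` echo spacings into the train; the minimum
#' achievable echo time is therefore `prep_time + echo_spacing * etl / 2`,
#' and any excess TE beyond that is sequence dead time.
#'
#' All times are in milliseconds.
#'
#' @param voxel_dims Numeric length 1 or 3: voxel dimensions in mm
#'   (a scalar means isotropic).
#' @param fov_inplane In-plane field of view in mm (length 1 or 2).
#' @param matrix_inplane Integer pair (readout, phase-encode); derived from
#'   `fov_inplane / voxel_dims` when missing.
#' @param etl Echo train length (number of phase-encode lines acquired).
#' @param n_slices Number of slices.
#' @param acq_bandwidth Total readout bandwidth in Hz.
#' @param te Echo time, ms.
#' @param tr Repetition time, ms; derived via [tr_for_te()] when
#'   `per_slice_overhead` is given and `tr` is `NULL`.
#' @param flip_angle Flip angle in degrees, or `NULL`.
#' @param echo_spacing Echo spacing in ms; derived from the bandwidth when
#'   `NULL`.
#' @param prep_time Excitation-to-readout-start minimum (excitation, slice
#'   rewinder, phase-encode prephaser), ms; excludes dead time.
#' @param per_slice_overhead Calibrated per-slice overhead constant `c` in
#'   `TR = n_slices * (TE + c)`, ms, or `NULL` (see [calibrate_overhead()]).
#' @param ramp_fraction Fractional gradient-ramp overhead added to the
#'   flat-top line time when deriving `echo_spacing`.
#' @return An object of class `epi_protocol`: a list with the fields above
#'   plus derived `tad` (acquisition duration `etl * echo_spacing`), `min_te`,
#'   and `dead_time`.
#' @examples
#' p <- epi_protocol(voxel_dims = 3.4, fov_inplane = 240, etl = 70,
#'                   n_slices = 38, acq_bandwidth = 160e3, te = 25,
#'                   per_slice_overhead = 20.76)
#' p$tad
#' dead_time(p)
#' @export
epi_protocol <- function(voxel_dims, fov_inplane = 240, matrix_inplane = NULL,
                         etl, n_slices, acq_bandwidth = 160e3,
                         te, tr = NULL, flip_angle = NULL,
                         echo_spacing = NULL, prep_time = 3,
                         per_slice_overhead = NULL, ramp_fraction = 0.035) {
  if (length(voxel_dims) == 1L) voxel_dims <- rep(voxel_dims, 3L)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("voxel_dims must be 1 or 3 positive values (mm)")
  if (length(fov_inplane) == 1L) fov_inplane <- rep(fov_inplane, 2L)
  if (is.null(matrix_inplane)) {
    matrix_inplane <- round(fov_inplane / voxel_dims[1:2])
  } else {
    matrix_inplane <- as.integer(matrix_inplane)
    if (length(matrix_inplane) == 1L) matrix_inplane <- rep(matrix_inplane, 2L)
    # FOV / matrix must agree with the nominal voxel size to ~half a voxel
    implied <- fov_inplane / matrix_inplane
    if (any(abs(implied - voxel_dims[1:2]) > 0.5 * voxel_dims[1:2]))
      stop("inconsistent FOV/matrix/voxel size: FOV/matrix = ",
           paste(signif(implied, 3), collapse = " x "),
           " mm but voxel_dims = ",
           paste(voxel_dims[1:2], collapse = " x "), " mm")
  }
  etl <- as.integer(etl)
  n_slices <- as.integer(n_slices)
  stopifnot(etl >= 1L, n_slices >= 1L, acq_bandwidth > 0, prep_time >= 0)
  if (etl > matrix_inplane[2])
    stop("echo train length (", etl, ") exceeds the phase-encode matrix (",
         matrix_inplane[2], ")")
  if (is.null(echo_spacing))
    echo_spacing <- matrix_inplane[1] / acq_bandwidth * (1 + ramp_fraction) * 1e3
  if (echo_spacing <= 0) stop("echo_spacing must be positive")
  tad <- etl * echo_spacing
  min_te <- prep_time + echo_spacing * etl / 2
  if (te < min_te)
    stop(sprintf(paste0(
      "TE = %.2f ms is below the minimum achievable %.2f ms for this ",
      "readout; increase TE by at least %.2f ms"), te, min_te, min_te - te))
  if (is.null(tr)) {
    if (!is.null(per_slice_overhead)) {
      tr <- tr_for_te(te, n_slices, per_slice_overhead)
    } else {
      stop("either tr or per_slice_overhead must be supplied")
    }
  }
  if (tr <= 0) stop("tr must be positive")
  if (!is.null(per_slice_overhead) &&
      tr < n_slices * (te + per_slice_overhead) - 1)
    stop(sprintf("TR = %.0f ms is shorter than n_slices*(TE + c) = %.0f ms",
                 tr, n_slices * (te + per_slice_overhead)))
  p <- structure(list(
    voxel_dims = voxel_dims, fov_inplane = fov_inplane,
    matrix_inplane = matrix_inplane, etl = etl, n_slices = n_slices,
    acq_bandwidth = acq_bandwidth, echo_spacing = echo_spacing,
    te = te, tr = tr, flip_angle = flip_angle, prep_time = prep_time,
    per_slice_overhead = per_slice_overhead, tad = tad, min_te = min_te
  ), class = "epi_protocol")
  p$dead_time <- dead_time(p)
  p
}

#' @export
print.epi_protocol <- function(x, ...) {
  cat("Single-shot GRE-EPI protocol\n")
  cat(sprintf("  voxel: %s mm, matrix %d x %d, FOV %g x %g mm, %d slices\n",
              paste(signif(x$voxel_dims, 3), collapse = " x "),
              x$matrix_inplane[1], x$matrix_inplane[2],
              x$fov_inplane[1], x$fov_inplane[2], x$n_slices))
  cat(sprintf("  ETL %d, echo spacing %.3f ms, TAD %.1f ms, bandwidth %g kHz\n",
              x$etl, x$echo_spacing, x$tad, x$acq_bandwidth / 1e3))
  cat(sprintf("  TE %.1f ms (min %.2f), TR %.0f ms%s, dead time %.2f ms\n",
              x$te, x$min_te, x$tr,
              if (is.null(x$flip_angle)) "" else
                sprintf(", FA %.0f deg", x$flip_angle),
              x$dead_time))
  cat(sprintf("  PE bandwidth %.1f Hz/pixel\n",
              pe_bandwidth(x$etl, x$echo_spacing)))
  invisible(x)
}

#' Calibrate the per-slice TR overhead from a TE/TR table
#'
#' Multi-slice 2-D EPI spends `TE + c` per slice, where `c` is a
#' sequence-dependent constant (readout second half, spoiling, slice
#' bookkeeping), so `TR = n_slices * (TE + c)`. Given matched TE and TR
#' lists this fits `c` by least squares under the unit-slope constraint,
#' i.e. `c = mean(TR / n_slices - TE)`.
#'
#' @param te_list,tr_list Matched echo and repetition times, ms.
#' @param n_slices Number of slices.
#' @return Numeric scalar `c` (ms) of class `overhead_fit`, with attributes
#'   `residuals` (per-entry `TR - n_slices*(TE + c)`, ms) and `max_resid`.
#' @examples
#' g <- reference_protocol_grid("3.4mm")
#' calibrate_overhead(g$te, g$tr, attr(g, "n_slices"))
#' @export
calibrate_overhead <- function(te_list, tr_list, n_slices) {
  if (length(te_list) != length(tr_list))
    stop("te_list and tr_list must have equal length")
  if (length(te_list) < 2L) stop("need at least 2 (TE, TR) pairs")
  stopifnot(n_slices >= 1)
  cc <- mean(tr_list / n_slices - te_list)
  if (cc < 0) stop("fitted per-slice overhead is negative (", signif(cc, 4),
                   " ms); TE/TR table inconsistent with the timing model")
  resid <- tr_list - n_slices * (te_list + cc)
  structure(cc, residuals = resid, max_resid = max(abs(resid)),
            n_slices = n_slices, class = "overhead_fit")
}

#' @export
print.overhead_fit <- function(x, ...) {
  cat(sprintf(
    "Per-slice overhead c = %.3f ms (%d slices), max |residual| = %.3f ms\n",
    unclass(x)[1], attr(x, "n_slices"), attr(x, "max_resid")))
  invisible(x)
}

#' Repetition time as a function of echo time
#'
#' `TR = n_slices * (te + c)` for a multi-slice 2-D acquisition with
#' per-slice overhead `c` (see [calibrate_overhead()]).
#'
#' @param te Echo time(s), ms.
#' @param n_slices Number of slices.
#' @param per_slice_overhead Overhead constant `c`, ms.
#' @return TR in ms (vectorized over `te`).
#' @export
tr_for_te <- function(te, n_slices, per_slice_overhead) {
  if (any(te <= 0)) stop("te must be positive")
  n_slices * (te + per_slice_overhead)
}

#' Sequence dead time
#'
#' Idle time between the end of the excitation/preparation block and the
#' start of the echo train needed to place the center echo at the prescribed
#' TE: `dead = te - prep_time - echo_spacing * etl / 2` for a linearly
#' ordered train.
#'
#' @param protocol An [epi_protocol()].
#' @return Dead time in ms (non-negative; a protocol with negative dead time
#'   cannot be constructed).
#' @export
dead_time <- function(protocol) {
  stopifnot(inherits(protocol, "epi_protocol"))
  d <- protocol$te - protocol$prep_time -
    protocol$echo_spacing * protocol$etl / 2
  if (d < -1e-9)
    stop(sprintf(
      "TE = %.2f ms infeasible: shorter than prep + half echo train (%.2f ms)",
      protocol$te, protocol$te - d))
  max(d, 0)
}

#' Echo spacing for a zero-dead-time echo train
#'
#' The echo spacing at which a linearly ordered echo train of length `etl`,
#' started immediately after excitation (preparation time neglected), places
#' its center line exactly at the prescribed TE: `esp = 2 * te / etl`.
#' Long echo times with short trains force low echo spacings, i.e. low
#' phase-encode bandwidth and large geometric distortion.
#'
#' @param te Echo time, ms.
#' @param etl Echo train length (>= 2).
#' @return Echo spacing in ms.
#' @examples
#' esp_for_zero_dead_time(90, 60)  # 3 ms
#' @export
esp_for_zero_dead_time <- function(te, etl) {
  stopifnot(te > 0, etl >= 2)
  2 * te / etl
}

#' Phase-encode pixel bandwidth
#'
#' Reciprocal of the total echo-train duration, `1 / (etl * echo_spacing)`,
#' in Hz per pixel. Susceptibility-induced geometric distortion along the
#' phase-encode direction scales inversely with this bandwidth.
#'
#' @param etl Echo train length.
#' @param echo_spacing Echo spacing, ms.
#' @return Bandwidth in Hz/pixel.
#' @examples
#' pe_bandwidth(60, 3)      # ~5.6 Hz/pixel
#' pe_bandwidth(60, 0.388)  # ~43 Hz/pixel
#' @export
pe_bandwidth <- function(etl, echo_spacing) {
  stopifnot(etl > 0, echo_spacing > 0)
  1 / (etl * echo_spacing * 1e-3)
}

#' Geometric distortion improvement factor
#'
#' Ratio of two phase-encode pixel bandwidths. Distortion scales as
#' `1 / bandwidth`, so `distortion_factor(bw_a, bw_b)` is the factor by which
#' protocol A improves on protocol B.
#'
#' @param bw_a,bw_b Phase-encode bandwidths, Hz/pixel.
#' @return `bw_a / bw_b`.
#' @export
distortion_factor <- function(bw_a, bw_b) {
  stopifnot(bw_a > 0)
  if (any(bw_b <= 0)) stop("reference bandwidth must be positive")
  bw_a / bw_b
}
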