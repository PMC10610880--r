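#' Tissue relaxation parameters
#'
#' Per-tissue longitudinal (T1) and effective transverse (T2*) relaxation
#' times in ms. Defaults for the common brain compartments at 0.5 T are
#' available through `default_relaxation()`: gray matter T1 = 717.2 ms with
#' T2* = 86.3 ms, white matter 77.9 ms, visual cortex 78.5 ms.
#'
#' @param t1 T1 in ms.
#' @param t2star T2* in ms.
#' @param tissue_label Free-text tissue label.
#' @return An object of class `relaxation_params`.
#' @examples
#' relaxation_params(717.2, 86.3, "GM")
#' default_relaxation("WM")
#' @export
relaxation_params <- function(t1, t2star, tissue_label = "") {
  stopifnot(t1 > 0, t2star > 0)
  structure(list(t1 = t1, t2star = t2star, tissue_label = tissue_label),
            class = "relaxation_params")
}

#' @rdname relaxation_params
#' @param tissue `"GM"`, `"WM"` or `"VC"` (visual cortex).
#' @export
default_relaxation <- function(tissue = c("GM", "WM", "VC")) {
  tissue <- match.arg(tissue)
  t2 <- switch(tissue, GM = 86.3, WM = 77.9, VC = 78.5)
  relaxation_params(t1 = 717.2, t2star = t2, tissue_label = tissue)
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf("Relaxation%s: T1 = %g ms, T2* = %g ms\n",
              if (nzchar(x$tissue_label)) paste0(" (", x$tissue_label, ")")
              else "", x$t1, x$t2star))
  invisible(x)
}

#' Ernst angle
#'
#' Flip angle maximizing the spoiled steady-state signal for a given TR and
#' T1: `acos(exp(-tr / t1))`, in degrees. `ernst_angle_deg()` rounds to the
#' nearest whole degree, as protocols are usually prescribed.
#'
#' @param tr Repetition time(s), ms.
#' @param t1 Longitudinal relaxation time, ms.
#' @return Angle(s) in degrees.
#' @examples
#' ernst_angle(1738, 717.2)      # 84.9
#' ernst_angle_deg(1738, 717.2)  # 85
#' @export
ernst_angle <- function(tr, t1) {
  if (any(tr <= 0) || any(t1 <= 0)) stop("tr and t1 must be positive")
  acos(exp(-tr / t1)) * 180 / pi
}

#' @rdname ernst_angle
#' @export
ernst_angle_deg <- function(tr, t1) round(ernst_angle(tr, t1))

# Spoiled GRE steady-state amplitude (1-E)sin(a) / (1 - E cos(a)), E=exp(-TR/T1)
steady_state <- function(tr, t1, flip_deg) {
  e1 <- exp(-tr / t1)
  a <- flip_deg * pi / 180
  (1 - e1) * sin(a) / (1 - e1 * cos(a))
}

# Vectorized core of the BOLD SNR model (arbitrary units, K = 1):
# V * TE * sqrt(TAD) * steady_state * exp(-TE/T2*)
snr_bold_core <- function(te, tr, flip_deg, tad, voxel_volume, t1, t2star) {
  voxel_volume * te * sqrt(tad) * steady_state(tr, t1, flip_deg) *
    exp(-te / t2star)
}

#' BOLD signal-to-noise ratio of a GRE-EPI acquisition
#'
#' Single-image BOLD SNR model for spoiled GRE-EPI,
#' \deqn{SNR_{BOLD} \propto \Delta x \Delta y \Delta z \; TE \sqrt{TAD}\;
#'   \frac{(1 - E)\sin\alpha}{1 - E\cos\alpha}\; e^{-TE/T_2^*},
#'   \quad E = e^{-TR/T_1}.}
#' The voxel volume sets the available magnetization, `TE` weights the BOLD
#' sensitivity, `sqrt(TAD)` is the noise-averaging benefit of a longer
#' readout, the bracket is the spoiled steady state, and `exp(-TE/T2*)` is
#' the signal remaining at the echo. The proportionality constant is 1, so
#' values are arbitrary units and only ratios are meaningful.
#'
#' @param protocol An [epi_protocol()] with a flip angle set.
#' @param relaxation A [relaxation_params()].
#' @return SNR in arbitrary units.
#' @export
snr_bold <- function(protocol, relaxation) {
  stopifnot(inherits(protocol, "epi_protocol"),
            inherits(relaxation, "relaxation_params"))
  if (is.null(protocol$flip_angle))
    stop("protocol has no flip angle; set flip_angle or use ernst_angle()")
  if (protocol$flip_angle <= 0 || protocol$flip_angle > 90)
    stop("flip angle must be in (0, 90] degrees")
  snr_bold_core(protocol$te, protocol$tr, protocol$flip_angle, protocol$tad,
                prod(protocol$voxel_dims), relaxation$t1, relaxation$t2star)
}

#' Time-series SNR from image averaging
#'
#' With `n` images of uncorrelated noise in a time series, the effective
#' SNR grows as `sqrt(n) * snr`. At fixed total scan time `TS = n * TR`
#' this equals `sqrt(TS) * contrast_efficiency(snr, tr)`.
#'
#' @param snr Single-image SNR (arbitrary units).
#' @param n_images Number of images in the series (>= 1).
#' @return Time-series SNR.
#' @export
timeseries_snr <- function(snr, n_images) {
  if (any(n_images < 1)) stop("n_images must be >= 1")
  sqrt(n_images) * snr
}

#' T2* contrast efficiency
#'
#' BOLD SNR per square root of repetition time, `snr / sqrt(tr)`: the figure
#' of merit for protocols compared at a fixed total scan duration, since the
#' achievable time-series SNR is `sqrt(TS)` times this quantity.
#'
#' @param snr Single-image SNR (arbitrary units).
#' @param tr Repetition time, ms.
#' @return Efficiency in arbitrary units.
#' @export
contrast_efficiency <- function(snr, tr) {
  if (any(tr <= 0)) stop("tr must be positive")
  snr / sqrt(tr)
}

#' Optimize the echo time for T2* contrast efficiency
#'
#' Evaluates the contrast-efficiency metric over a family of protocols that
#' differ in echo time and returns the efficiency-optimal TE.
#'
#' In `"grid"` mode each TE comes with its own TR (longer echoes force
#' longer repetition times in multi-slice EPI) and flip angle. TR may be
#' given per TE (e.g. a printed protocol table), or derived as
#' `n_slices * (te + per_slice_overhead)`; flip angles default to the exact
#' Ernst angle for each TR. Ties in the maximum break toward the smaller TE.
#'
#' In `"continuous"` mode the efficiency is maximized over a TE interval
#' with `tr_fun(te)` supplying the repetition time. When TR is decoupled
#' from TE (`tr_fun = NULL`, fixed `tr`), the steady-state and `1/sqrt(TR)`
#' factors are constant and the optimum of `TE * exp(-TE/T2*)` is exactly
#' `TE = T2*`, which is returned in closed form.
#'
#' @param relaxation A [relaxation_params()].
#' @param te_grid Echo-time grid, ms (grid mode; must be strictly
#'   increasing).
#' @param tr_grid Optional per-TE repetition times, ms.
#' @param flip_grid Optional per-TE flip angles, degrees.
#' @param n_slices,per_slice_overhead Used to derive `tr_grid` when absent.
#' @param tad Acquisition duration, ms (constant across the family).
#' @param voxel_volume Voxel volume, mm^3.
#' @param mode `"grid"` or `"continuous"`.
#' @param tr_fun For continuous mode, a function `te -> tr` (ms), or `NULL`
#'   for a TR decoupled from TE.
#' @param tr For continuous mode with `tr_fun = NULL`: the fixed TR, ms.
#' @param interval TE search interval for continuous mode, ms.
#' @return An object of class `efficiency_curve`: a data.frame with columns
#'   `te`, `tr`, `fa`, `snr_bold`, `eta`, and attributes `te_opt`,
#'   `eta_max`, `relaxation`. In continuous mode the data.frame samples the
#'   interval finely for plotting.
#' @examples
#' g <- reference_protocol_grid("3.4mm")
#' ec <- optimize_te(default_relaxation("GM"), g$te, g$tr, g$fa)
#' attr(ec, "te_opt")  # 55
#' @export
optimize_te <- function(relaxation, te_grid = NULL, tr_grid = NULL,
                        flip_grid = NULL, n_slices = NULL,
                        per_slice_overhead = NULL, tad = 1, voxel_volume = 1,
                        mode = c("grid", "continuous"), tr_fun = NULL,
                        tr = NULL, interval = NULL) {
  stopifnot(inherits(relaxation, "relaxation_params"))
  mode <- match.arg(mode)
  t1 <- relaxation$t1; t2s <- relaxation$t2star

  if (mode == "grid") {
    if (is.null(te_grid) || length(te_grid) == 0L) stop("empty TE grid")
    if (is.unsorted(te_grid, strictly = TRUE))
      stop("TE grid must be strictly increasing")
    if (is.null(tr_grid)) {
      if (is.null(n_slices) || is.null(per_slice_overhead))
        stop("supply tr_grid, or n_slices and per_slice_overhead")
      tr_grid <- tr_for_te(te_grid, n_slices, per_slice_overhead)
    }
    if (length(tr_grid) != length(te_grid))
      stop("te_grid and tr_grid must have equal length")
    if (is.null(flip_grid)) flip_grid <- ernst_angle(tr_grid, t1)
    if (length(flip_grid) != length(te_grid))
      stop("flip_grid length must match te_grid")
    snr <- snr_bold_core(te_grid, tr_grid, flip_grid, tad, voxel_volume,
                         t1, t2s)
    eta <- contrast_efficiency(snr, tr_grid)
    i <- which.max(eta)  # first index wins: ties break toward smaller TE
    curve <- data.frame(te = te_grid, tr = tr_grid, fa = flip_grid,
                        snr_bold = snr, eta = eta)
    te_opt <- te_grid[i]
    eta_max <- eta[i]
  } else {
    if (is.null(interval)) {
      interval <- if (!is.null(te_grid)) range(te_grid) else c(1, 4 * t2s)
    }
    if (is.null(tr_fun)) {
      # TR decoupled from TE: argmax of TE*exp(-TE/T2*) is TE = T2*
      if (is.null(tr)) stop("continuous mode with tr_fun = NULL needs tr")
      te_opt <- t2s
      tr_of <- function(te) rep(tr, length(te))
    } else {
      tr_of <- function(te) vapply(te, tr_fun, numeric(1))
      eta_of <- function(te) {
        trv <- tr_of(te)
        contrast_efficiency(
          snr_bold_core(te, trv, ernst_angle(trv, t1), tad, voxel_volume,
                        t1, t2s), trv)
      }
      te_opt <- stats::optimize(eta_of, interval, maximum = TRUE,
                                tol = 1e-8)$maximum
    }
    te_s <- seq(interval[1], interval[2], length.out = 201)
    trv <- tr_of(te_s)
    fav <- ernst_angle(trv, t1)
    snr <- snr_bold_core(te_s, trv, fav, tad, voxel_volume, t1, t2s)
    eta <- contrast_efficiency(snr, trv)
    curve <- data.frame(te = te_s, tr = trv, fa = fav, snr_bold = snr,
                        eta = eta)
    tro <- tr_of(te_opt)
    eta_max <- contrast_efficiency(
      snr_bold_core(te_opt, tro, ernst_angle(tro, t1), tad, voxel_volume,
                    t1, t2s), tro)
  }
  structure(curve, te_opt = te_opt, eta_max = eta_max,
            relaxation = relaxation, mode = mode,
            class = c("efficiency_curve", "data.frame"))
}

#' @export
print.efficiency_curve <- function(x, ...) {
  r <- attr(x, "relaxation")
  cat(sprintf(
    "T2* contrast-efficiency curve (%s mode; T1 = %g ms, T2* = %g ms)\n",
    attr(x, "mode"), r$t1, r$t2star))
  cat(sprintf("  TE range %g-%g ms over %d points\n",
              min(x$te), max(x$te), nrow(x)))
  cat(sprintf("  optimal TE = %g ms (eta = %.4g a.u.); TE - T2* = %g ms\n",
              attr(x, "te_opt"), attr(x, "eta_max"),
              attr(x, "te_opt") - r$t2star))
  invisible(x)
}

#' @export
plot.efficiency_curve <- function(x, ...) {
  graphics::plot(x$te, x$eta, type = "b", xlab = "TE (ms)",
                 ylab = expression(eta[T2^"*"] ~ "(a.u.)"), ...)
  graphics::abline(v = attr(x, "te_opt"), lty = 2)
  graphics::abline(v = attr(x, "relaxation")$t2star, lty = 3)
  invisible(x)
}
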