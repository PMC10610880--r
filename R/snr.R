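#' Pseudo-multiple-replica SNR
#'
#' Estimates the thermal-noise SNR of a single acquisition by the pseudo
#' multiple replica method: many synthetic replicas are formed by adding
#' properly scaled and correlated complex Gaussian noise (colored across
#' coils by a factor of the coil noise covariance) to the measured k-space,
#' each replica is reconstructed (centered inverse FFT + root-sum-of-squares
#' coil combination), and the voxel-wise SNR is the mean over replicas
#' divided by the standard deviation over replicas. Images in the pseudo
#' time series differ only through thermal noise, so unlike temporal SNR
#' this estimate contains no physiological component.
#'
#' @param kspace A [kspace_series()] holding a single acquisition
#'   (`(coil, kx, ky, slice)`; a 5-D series uses its first repetition).
#' @param n_replicas Number of noise replicas (default 128). Fewer than 8
#'   triggers a warning: the SD estimate is unstable.
#' @param seed Integer seed for the replica noise.
#' @return 3-D SNR map `(x, y, slice)` with attribute `n_replicas`.
#' @export
pseudo_replica_snr <- function(kspace, n_replicas = 128, seed = 1) {
  stopifnot(inherits(kspace, "kspace_series"))
  k <- kspace$data
  if (length(dim(k)) == 5L) k <- k[, , , , 1, drop = FALSE]
  dim(k) <- dim(k)[1:4]
  if (n_replicas < 8)
    warning("fewer than 8 replicas: SNR standard deviation is unstable")
  L <- psd_factor(kspace$noise_cov)
  d <- dim(k)
  n_coils <- d[1]; n_samp <- prod(d[2:4])
  set.seed(seed)
  s1 <- s2 <- array(0, d[2:4])
  for (r in seq_len(n_replicas)) {
    noise <- draw_coil_noise(L, n_coils, n_samp)
    dim(noise) <- d
    img <- recon_rss(k + noise)
    s1 <- s1 + img
    s2 <- s2 + img^2
  }
  mu <- s1 / n_replicas
  va <- pmax(s2 / n_replicas - mu^2, 0) * n_replicas / (n_replicas - 1)
  snr <- mu / sqrt(va)
  snr[va == 0] <- Inf
  structure(snr, n_replicas = n_replicas)
}

#' Temporal SNR
#'
#' Voxel-wise mean over the repetition axis divided by the temporal standard
#' deviation, the standard stability measure of an fMRI time series. The
#' temporal SD contains both thermal noise and physiological signal
#' fluctuation, so tSNR is at most the thermal-only pseudo-replica SNR.
#'
#' @param timeseries 4-D magnitude array `(x, y, slice, rep)` with at least
#'   8 repetitions.
#' @param detrend Remove a voxel-wise linear trend before computing the
#'   temporal SD (off by default; the phantom drifts are stochastic, not
#'   linear).
#' @return 3-D tSNR map; voxels with zero temporal variance are flagged
#'   `Inf`.
#' @export
temporal_snr <- function(timeseries, detrend = FALSE) {
  d <- dim(timeseries)
  if (length(d) != 4L) stop("timeseries must be 4-D (x, y, slice, rep)")
  n <- d[4]
  if (n < 8) stop("need at least 8 repetitions, got ", n)
  flat <- matrix(timeseries, ncol = n)
  mu <- rowMeans(flat)
  if (detrend) {
    tt <- seq_len(n) - (n + 1) / 2
    beta <- (flat %*% tt) / sum(tt^2)
    flat <- flat - beta %*% t(tt)
  }
  sdv <- sqrt(rowSums((flat - mu)^2) / (n - 1))
  snr <- mu / sdv
  snr[sdv == 0] <- Inf
  array(snr, d[1:3])
}

#' Physiological-to-thermal noise ratio
#'
#' Decomposes the temporal noise into thermal and physiological parts via
#' \deqn{\sigma_P/\sigma_T = \sqrt{(pSNR/tSNR)^2 - 1}.}
#' Values below 1 indicate thermal-noise dominance. Where sampling noise
#' makes `psnr < tsnr` the ratio is undefined and returned as `NA` (never
#' an imaginary number).
#'
#' @param psnr,tsnr Scalars or arrays of matching shape.
#' @return The ratio, same shape as the inputs.
#' @export
noise_ratio <- function(psnr, tsnr) {
  if (any(tsnr <= 0, na.rm = TRUE)) stop("tsnr must be positive")
  q2 <- (psnr / tsnr)^2 - 1
  out <- sqrt(pmax(q2, 0))
  out[q2 < 0] <- NA_real_
  if (!is.null(dim(psnr))) dim(out) <- dim(psnr)
  out
}

#' ROI summary of pSNR, tSNR and the noise ratio
#'
#' Per-ROI means and standard deviations of the pseudo-replica and temporal
#' SNR maps, plus the physiological-to-thermal noise ratio in two labeled
#' variants: `ratio_voxelwise` averages the voxel-wise ratio map over the
#' ROI (voxels where the ratio is undefined are dropped), and `ratio_of_means`
#' applies the decomposition to the ROI-mean SNRs. The second variant is far
#' less sensitive to voxel-level estimation noise and is the one used for
#' quantitative recovery checks.
#'
#' @param psnr_map,tsnr_map 3-D maps on a common grid.
#' @param roi_masks Named list of 3-D logical masks.
#' @return An object of class `snr_summary`: a data.frame with one row per
#'   ROI and columns `roi`, `n_voxels`, `psnr_mean`, `psnr_sd`, `tsnr_mean`,
#'   `tsnr_sd`, `ratio_voxelwise`, `ratio_of_means`.
#' @export
summarize_snr <- function(psnr_map, tsnr_map, roi_masks) {
  if (!all(dim(psnr_map) == dim(tsnr_map)))
    stop("pSNR and tSNR maps must share a grid")
  if (is.null(names(roi_masks)) || any(!nzchar(names(roi_masks))))
    stop("roi_masks must be a named list")
  ratio_map <- noise_ratio(psnr_map, tsnr_map)
  rows <- lapply(names(roi_masks), function(nm) {
    m <- roi_masks[[nm]]
    if (!all(dim(m) == dim(psnr_map)))
      stop("ROI '", nm, "' shape does not match the maps")
    sel <- which(m & is.finite(psnr_map) & is.finite(tsnr_map))
    if (!length(sel)) stop("ROI '", nm, "' is empty")
    p <- psnr_map[sel]; t <- tsnr_map[sel]; r <- ratio_map[sel]
    data.frame(
      roi = nm, n_voxels = length(sel),
      psnr_mean = mean(p), psnr_sd = stats::sd(p),
      tsnr_mean = mean(t), tsnr_sd = stats::sd(t),
      ratio_voxelwise = mean(r, na.rm = TRUE),
      ratio_of_means = noise_ratio(mean(p), mean(t))
    )
  })
  structure(do.call(rbind, rows), class = c("snr_summary", "data.frame"))
}

#' @export
print.snr_summary <- function(x, ...) {
  cat("SNR summary (pseudo-replica vs temporal):\n")
  print.data.frame(
    cbind(x[, "roi", drop = FALSE],
          round(x[, setdiff(names(x), "roi")], 3)),
    row.names = FALSE)
  invisible(x)
}
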