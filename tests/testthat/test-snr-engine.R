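# one-slice single-coil k-space of a uniform object
uniform_kspace <- function(n = 16, level = 100, psi = 25) {
  k <- array(fft2c(matrix(level, n, n)), c(1, n, n, 1))
  kspace_series(k, matrix(psi, 1, 1))
}

test_that("pseudo-replica SNR matches the closed-form mean/sigma oracle", {
  ps <- pseudo_replica_snr(uniform_kspace(), n_replicas = 128, seed = 3)
  # signal 100, per-quadrature noise SD 5 -> SNR 20, MC tolerance
  # 2*20/sqrt(2*127) on the map mean
  expect_equal(mean(ps), 20, tolerance = 2 / sqrt(2 * 127))
  expect_equal(attr(ps, "n_replicas"), 128)

  # zero-signal k-space: SNR collapses to the noise floor, far below 20
  k0 <- kspace_series(array(0i, c(1, 16, 16, 1)), matrix(25, 1, 1))
  ps0 <- pseudo_replica_snr(k0, n_replicas = 128, seed = 3)
  expect_lt(max(ps0), 4)

  # scaling the covariance by 4 halves the SNR
  ps4 <- pseudo_replica_snr(uniform_kspace(psi = 100), n_replicas = 128,
                            seed = 3)
  expect_equal(mean(ps) / mean(ps4), 2, tolerance = 0.03)

  # linearity: scaling k-space and noise SD together leaves SNR unchanged
  psc <- pseudo_replica_snr(uniform_kspace(level = 300, psi = 9 * 25),
                            n_replicas = 128, seed = 3)
  expect_equal(mean(psc), mean(ps), tolerance = 1e-9)

  expect_warning(pseudo_replica_snr(uniform_kspace(), n_replicas = 4),
                 "unstable")
  expect_error(kspace_series(array(0i, c(2, 8, 8, 1)),
                             matrix(c(1, 2, 2, 1), 2)), "indefinite")
  # a singular (but PSD) covariance is allowed in the container yet refused
  # by the replica engine, which must whiten it
  sing <- kspace_series(array(0i, c(2, 8, 8, 1)), matrix(1, 2, 2))
  expect_error(pseudo_replica_snr(sing, n_replicas = 16, seed = 1),
               "positive-definite")
})

test_that("temporal SNR: closed form, physiological inflation, flags", {
  n <- 64
  set.seed(31)
  ts <- array(100 + rnorm(12 * 12 * 2 * n, sd = 5), c(12, 12, 2, n))
  tsnr <- temporal_snr(ts)
  expect_equal(mean(tsnr), 20, tolerance = 2 / sqrt(2 * (n - 1)))

  # a 1%-of-signal fluctuation lowers tSNR to ~100/sqrt(25 + 1)
  set.seed(32)
  g <- as.numeric(scale(arima.sim(list(ar = 0.9), n)))
  tsp <- array(0, c(12, 12, 1, n))
  for (t in seq_len(n)) tsp[, , , t] <- 100 * (1 + 0.01 * g[t]) +
    rnorm(144, sd = 5)
  tsnr_p <- temporal_snr(tsp)
  expect_equal(mean(tsnr_p), 100 / sqrt(26), tolerance = 0.03)
  expect_lt(mean(tsnr_p), 20)

  # noiseless constant series is flagged infinite, short series errors
  expect_true(all(is.infinite(temporal_snr(array(7, c(2, 2, 1, 8))))))
  expect_error(temporal_snr(array(1, c(2, 2, 1, 4))), "at least 8")

  # linear detrend removes a drift
  drift <- array(0, c(4, 4, 1, n))
  for (t in seq_len(n)) drift[, , , t] <- 100 + 0.5 * t
  expect_true(all(temporal_snr(drift, detrend = TRUE) >
                    temporal_snr(drift)))
})

test_that("noise-ratio decomposition algebra and undefined region", {
  expect_equal(noise_ratio(50, 50), 0)
  expect_equal(noise_ratio(sqrt(2) * 60, 60), 1)
  expect_equal(noise_ratio(100, 60), 4 / 3, tolerance = 1e-12)
  expect_true(is.na(noise_ratio(55, 60)))
  expect_error(noise_ratio(10, 0), "positive")
  m <- noise_ratio(array(c(100, 55), c(2, 1, 1)), array(60, c(2, 1, 1)))
  expect_equal(dim(m), c(2, 1, 1))
  expect_equal(m[1, 1, 1], 4 / 3)
  expect_true(is.na(m[2, 1, 1]))
})

test_that("ROI summary reports both labeled ratio variants and conserves counts", {
  d <- c(6, 6, 2)
  set.seed(8)
  psnr <- array(100 + rnorm(prod(d)), d)
  rois <- list(A = array(FALSE, d), B = array(FALSE, d))
  rois$A[1:3, , ] <- TRUE; rois$B[4:6, , ] <- TRUE

  # identical maps -> both ratio summaries are zero
  s0 <- summarize_snr(psnr, psnr, rois)
  expect_equal(s0$ratio_of_means, c(0, 0))
  expect_true(all(s0$ratio_voxelwise %in% 0 | is.nan(s0$ratio_voxelwise)))

  # disjoint ROIs partition the grid: counts sum to the total
  expect_equal(sum(s0$n_voxels), prod(d))

  # a known uniform inflation is recovered by the ratio of ROI means
  tsnr <- psnr / sqrt(1 + 0.5^2)
  s1 <- summarize_snr(psnr, tsnr, rois)
  expect_equal(s1$ratio_of_means, c(0.5, 0.5), tolerance = 1e-6)

  expect_error(summarize_snr(psnr, tsnr, list(array(TRUE, d))), "named")
  empty <- list(E = array(FALSE, d))
  expect_error(summarize_snr(psnr, tsnr, empty), "empty")
})

test_that("pSNR estimator variability across seeds follows 1/sqrt(2(n-1))", {
  n_seeds <- 16
  ks <- uniform_kspace(n = 12)
  rel_sd <- vapply(c(32, 128, 512), function(nr) {
    maps <- sapply(seq_len(n_seeds), function(s)
      as.numeric(pseudo_replica_snr(ks, n_replicas = nr, seed = 1000 + s)))
    mean(apply(maps, 1, sd) / apply(maps, 1, mean))
  }, numeric(1))
  pred <- 1 / sqrt(2 * (c(32, 128, 512) - 1))
  expect_true(all(diff(rel_sd) < 0))
  expect_equal(rel_sd, pred, tolerance = 0.25)
})

test_that("unitary FFT conventions: inversion and Parseval", {
  set.seed(5)
  x <- matrix(rnorm(16 * 12), 16, 12) + 1i * matrix(rnorm(16 * 12), 16, 12)
  k <- fft2c(x)
  expect_equal(ifft2c(k), x, tolerance = 1e-12)
  expect_equal(sum(Mod(k)^2), sum(Mod(x)^2), tolerance = 1e-12)
})
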