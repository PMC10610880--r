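test_that("tissue phantom geometry: disjoint non-empty compartments", {
  ph <- make_tissue_phantom(phantom_spec())
  m <- ph$masks
  expect_named(m, c("WM", "GM", "VC"))
  expect_true(all(vapply(m, any, logical(1))))
  # pairwise disjoint
  expect_equal(sum(m$WM & m$GM), 0)
  expect_equal(sum(m$WM & m$VC), 0)
  expect_equal(sum(m$GM & m$VC), 0)
  # parameter volumes carry the compartment values
  expect_true(all(ph$t2star[m$GM] == 86.3))
  expect_true(all(ph$t2star[m$WM] == 77.9))
  expect_true(all(ph$t2star[m$VC] == 78.5))
  expect_true(all(ph$t1[ph$labels > 0] == 717.2))

  # zero-thickness shell is an error
  expect_error(make_tissue_phantom(phantom_spec(), wm_radius = 0.85,
                                   brain_radius = 0.85), "zero-thickness")

  # determinism: same spec -> bit-identical volumes
  spec <- phantom_spec(t2star_sd = c(WM = 5, GM = 10, VC = 5), seed = 9)
  expect_identical(make_tissue_phantom(spec), make_tissue_phantom(spec))
})

test_that("synthetic coil arrays are smooth, positive, and well-conditioned", {
  one <- synthesize_coils(1, c(16, 16))
  expect_equal(dim(one$sens), c(1, 16, 16))
  expect_true(all(one$sens == 1))
  expect_equal(one$psi_unit, matrix(1, 1, 1))

  c8 <- synthesize_coils(8, c(16, 16), rho = 0)
  expect_equal(c8$psi_unit, diag(8))
  c8r <- synthesize_coils(8, c(16, 16), rho = 0.1)
  expect_true(all(c8r$psi_unit[upper.tri(c8r$psi_unit)] == 0.1))
  rss <- sqrt(apply(Mod(c8r$sens)^2, c(2, 3), sum))
  expect_true(all(rss > 0))

  expect_error(synthesize_coils(4, c(16, 16), rho = 1), "rho")
})

test_that("meGRE simulation is exactly mono-exponential without noise", {
  ph <- make_tissue_phantom(phantom_spec(grid_dim = c(16, 16, 4)))
  me <- simulate_megre(ph, snr = Inf)
  expect_s3_class(me, "multi_echo_series")
  vx <- which(ph$masks$GM, arr.ind = TRUE)[1, ]
  sig <- me$data[vx[1], vx[2], vx[3], ]
  f <- fit_monoexp(sig, me$echo_times)
  expect_true(f$valid)
  expect_equal(f$t2star, 86.3, tolerance = 1e-8)
  # two echoes are not enough for the downstream fit
  expect_error(fit_monoexp(sig[1:2], me$echo_times[1:2]), "at least 3")
})

test_that("relaxometry round trip on simulated meGRE recovers compartments", {
  ph <- make_tissue_phantom(phantom_spec(grid_dim = c(24, 24, 8), seed = 5))
  me <- simulate_megre(ph, snr = 100)
  map <- map_t2star(me, ph$labels > 0)
  for (nm in names(ph$masks)) {
    truth <- ph$spec$relaxation[[nm]]$t2star
    got <- median(map$t2star[ph$masks[[nm]] & map$valid])
    expect_equal(got, truth, tolerance = 0.01)
  }
})

test_that("EPI forward model conserves energy and is reproducible", {
  spec <- phantom_spec(grid_dim = c(16, 16, 4), n_coils = 3, seed = 14,
                       thermal_sigma = 0)  # noiseless forward model
  ph <- make_tissue_phantom(spec)
  p <- small_protocol(55)
  sim <- simulate_epi_timeseries(ph, p, n_repeats = 1, seed = 14)
  # Parseval per coil/slice between image and k-space domains
  coils <- sim$coils
  rss <- sqrt(apply(Mod(coils$sens)^2, c(2, 3), sum))
  S <- sim$truth$signal / array(rep(rss, 4), dim(sim$truth$signal))
  for (cl in 1:3) {
    img <- S[, , 1] * coils$sens[cl, , ]
    expect_equal(sum(Mod(sim$kspace$data[cl, , , 1, 1])^2),
                 sum(Mod(img)^2), tolerance = 1e-10)
  }
  # determinism at fixed seed
  spec2 <- phantom_spec(grid_dim = c(16, 16, 4), n_coils = 3, seed = 14)
  ph2 <- make_tissue_phantom(spec2)
  a <- simulate_epi_timeseries(ph2, p, n_repeats = 4, seed = 3)
  b <- simulate_epi_timeseries(ph2, p, n_repeats = 4, seed = 3)
  expect_identical(a$kspace$data, b$kspace$data)
})

test_that("thermal-only phantom: pSNR and tSNR agree across echo times", {
  spec <- phantom_spec(grid_dim = c(24, 24, 4), n_coils = 2, seed = 41)
  ph <- make_tissue_phantom(spec)
  coils <- synthesize_coils(2, c(24, 24), 0.1)
  for (te in c(25, 85)) {
    sim <- simulate_epi_timeseries(ph, small_protocol(te), n_repeats = 64,
                                   coils = coils, seed = 300 + te)
    tsnr <- temporal_snr(recon_timeseries(sim$kspace))
    psnr <- pseudo_replica_snr(
      kspace_series(sim$kspace$data[, , , , 1, drop = FALSE],
                    sim$kspace$noise_cov), n_replicas = 128,
      seed = 400 + te)
    s <- summarize_snr(psnr, tsnr, ph$masks)
    # ROI means agree within Monte-Carlo tolerance ...
    expect_equal(s$psnr_mean, s$tsnr_mean, tolerance = 0.05)
    # ... so the decomposition reports thermal dominance in every ROI
    rom <- ifelse(is.na(s$ratio_of_means), 0, s$ratio_of_means)
    expect_true(all(rom < 1))
  }
})

test_that("injected physiological noise: TE dependence and voxel-size scaling", {
  # ground-truth ratio grows monotonically with TE under the BOLD-like term
  spec <- phantom_spec(grid_dim = c(20, 20, 4), n_coils = 2,
                       lambda_bold = 0.02, thermal_sigma = 0.05, seed = 51)
  ph <- make_tissue_phantom(spec)
  ratios <- vapply(c(25, 45, 65, 85), function(te) {
    sim <- simulate_epi_timeseries(ph, small_protocol(te), n_repeats = 1,
                                   seed = 52)
    truth_roi_ratio(sim, ph$masks$GM)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))

  # equal lambda and equal thermal noise: the larger voxel (higher baseline
  # SNR) carries the larger physiological-to-thermal ratio
  r_by_vox <- vapply(c(3.4, 4.0), function(v) {
    sp <- phantom_spec(grid_dim = c(20, 20, 4), voxel_dims = v, n_coils = 2,
                       lambda_const = 0.01, thermal_sigma = 0.05, seed = 53)
    phv <- make_tissue_phantom(sp)
    pr <- epi_protocol(voxel_dims = v, etl = 60, n_slices = 32, te = 55,
                       tr = tr_for_te(55, 32, 18.31),
                       flip_angle = 88)
    sim <- simulate_epi_timeseries(phv, pr, n_repeats = 1, seed = 54)
    truth_roi_ratio(sim, phv$masks$GM)
  }, numeric(1))
  expect_gt(r_by_vox[2], r_by_vox[1])
})

test_that("target-ratio calibration injects the requested gray-matter ratio", {
  spec <- phantom_spec(grid_dim = c(24, 24, 4), n_coils = 2,
                       target_ratio = 0.5, seed = 61)
  ph <- make_tissue_phantom(spec)
  sim <- simulate_epi_timeseries(ph, small_protocol(55), n_repeats = 1,
                                 seed = 62)
  expect_gt(sim$truth$lambda_const, 0)
  # the voxel-wise ground-truth ratio averages to the target over GM
  expect_equal(mean(sim$truth$ratio[ph$masks$GM]), 0.5, tolerance = 1e-6)
})
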