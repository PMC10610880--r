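# Shared fixtures for the simulation tests. Everything is generated in code;
# expensive simulations are built lazily and cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# small EPI protocol of the 3.4 mm family at a given TE
small_protocol <- function(te, flip = NULL) {
  tr <- tr_for_te(te, 38, 20.76)
  if (is.null(flip)) flip <- ernst_angle_deg(tr, 717.2)
  epi_protocol(voxel_dims = 3.4, fov_inplane = 240, etl = 70, n_slices = 38,
               acq_bandwidth = 160e3, te = te, tr = tr, flip_angle = flip)
}

# thermal-noise-only phantom simulation at TE 55 on a reduced grid
sim_lambda0 <- function() cached("sim_lambda0", {
  spec <- phantom_spec(grid_dim = c(32, 32, 6), n_coils = 4, seed = 11)
  ph <- make_tissue_phantom(spec)
  sim <- simulate_epi_timeseries(ph, small_protocol(55), n_repeats = 64,
                                 seed = 12)
  tsnr <- temporal_snr(recon_timeseries(sim$kspace))
  one <- kspace_series(sim$kspace$data[, , , , 1, drop = FALSE],
                       sim$kspace$noise_cov)
  psnr <- pseudo_replica_snr(one, n_replicas = 128, seed = 13)
  list(phantom = ph, sim = sim, tsnr = tsnr, psnr = psnr)
})

# BOLD-like physiological noise across a TE grid (reduced grid)
sim_bold_vs_te <- function() cached("sim_bold_vs_te", {
  spec <- phantom_spec(grid_dim = c(32, 32, 6), n_coils = 4,
                       lambda_bold = 0.02, lambda_const = 0.002, seed = 21)
  ph <- make_tissue_phantom(spec)
  coils <- synthesize_coils(4, c(32, 32), 0.1)
  te_grid <- c(25, 55, 85)
  res <- lapply(seq_along(te_grid), function(i) {
    sim <- simulate_epi_timeseries(ph, small_protocol(te_grid[i]),
                                   n_repeats = 64, coils = coils,
                                   seed = 100 + i)
    tsnr <- temporal_snr(recon_timeseries(sim$kspace))
    psnr <- pseudo_replica_snr(
      kspace_series(sim$kspace$data[, , , , 1, drop = FALSE],
                    sim$kspace$noise_cov),
      n_replicas = 128, seed = 200 + i)
    list(sim = sim, summary = summarize_snr(psnr, tsnr, ph$masks))
  })
  list(phantom = ph, te_grid = te_grid, res = res)
})

# ground-truth ROI noise ratio (averaged-then-ratio variant of the
# decomposition, computed from the analytic truth maps)
truth_roi_ratio <- function(sim, mask) {
  p <- sim$truth$signal / sim$truth$sigma_t
  t <- sim$truth$signal / sqrt(sim$truth$sigma_t^2 + sim$truth$sigma_p^2)
  noise_ratio(mean(p[mask]), mean(t[mask]))
}
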