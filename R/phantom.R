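#' Digital brain-like phantom specification
#'
#' Describes the synthetic object used for end-to-end validation: concentric
#' ellipsoidal tissue compartments (white-matter core, gray-matter shell,
#' and a posterior visual-cortex patch carved out of the gray matter), each
#' with its own relaxation parameters and proton-density weight, imaged by a
#' synthetic multi-coil array with correlated thermal noise and, optionally,
#' spatially coherent physiological signal fluctuation.
#'
#' Default relaxation values are the 0.5 T brain values used throughout the
#' package (T1 = 717.2 ms; T2* = 86.3 / 77.9 / 78.5 ms for GM / WM / VC).
#' Thermal noise is set either directly (`thermal_sigma`, k-space units) or
#' through a target baseline SNR (`target_snr`, the gray-matter
#' pseudo-replica SNR of the simulated protocol). Physiological fluctuation
#' follows a two-term model (see [simulate_epi_timeseries()]) controlled by
#' `lambda_const` and `lambda_bold`, or calibrated from a target gray-matter
#' physiological-to-thermal noise ratio (`target_ratio`).
#'
#' @param grid_dim Integer length 3: simulation grid `(nx, ny, n_slices)`.
#' @param voxel_dims Nominal voxel size, mm (length 1 or 3).
#' @param relaxation Named list of [relaxation_params()] for `WM`, `GM`,
#'   `VC`.
#' @param proton_density Named numeric: PD weight per compartment.
#' @param t2star_sd Named numeric: optional voxel-wise Gaussian spread of
#'   T2* (ms) within each compartment (0 = homogeneous).
#' @param n_coils Number of receive coils.
#' @param coil_rho Off-diagonal coil noise coupling, `|rho| < 1`.
#' @param target_snr Target gray-matter thermal SNR (used when
#'   `thermal_sigma` is `NULL`).
#' @param thermal_sigma Per-quadrature k-space noise SD, or `NULL`.
#' @param lambda_const Signal-proportional (non-BOLD) physiological
#'   fluctuation amplitude, unitless.
#' @param lambda_bold BOLD-like physiological fluctuation amplitude,
#'   unitless (weighted by `TE/T2*`, see [simulate_epi_timeseries()]).
#' @param target_ratio Target gray-matter sigma_P/sigma_T; when set it
#'   overrides `lambda_const` (with `lambda_bold` kept as given and the
#'   constant term calibrated to reach the target at the protocol's TE).
#' @param seed Integer seed controlling all randomness of the simulators.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(40, 40, 10), voxel_dims = 3.4,
                         relaxation = list(
                           WM = default_relaxation("WM"),
                           GM = default_relaxation("GM"),
                           VC = default_relaxation("VC")),
                         proton_density = c(WM = 0.7, GM = 0.85, VC = 0.85),
                         t2star_sd = c(WM = 0, GM = 0, VC = 0),
                         n_coils = 8, coil_rho = 0.1,
                         target_snr = 100, thermal_sigma = NULL,
                         lambda_const = 0, lambda_bold = 0,
                         target_ratio = NULL, seed = 42) {
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 4L))
  if (length(voxel_dims) == 1L) voxel_dims <- rep(voxel_dims, 3L)
  stopifnot(all(c("WM", "GM", "VC") %in% names(relaxation)),
            all(c("WM", "GM", "VC") %in% names(proton_density)),
            n_coils >= 1, target_snr > 0,
            lambda_const >= 0, lambda_bold >= 0)
  if (abs(coil_rho) >= 1) stop("|coil_rho| must be < 1")
  structure(list(grid_dim = grid_dim, voxel_dims = voxel_dims,
                 relaxation = relaxation, proton_density = proton_density,
                 t2star_sd = t2star_sd, n_coils = as.integer(n_coils),
                 coil_rho = coil_rho, target_snr = target_snr,
                 thermal_sigma = thermal_sigma,
                 lambda_const = lambda_const, lambda_bold = lambda_bold,
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the tissue phantom
#'
#' Realizes the geometry of a [phantom_spec()]: an outer brain ellipsoid
#' (85% of the grid half-width) holding a white-matter ellipsoidal core
#' (55%), a gray-matter shell between the two, and a visual-cortex patch
#' (the posterior sector of the shell). Compartment masks are pairwise
#' disjoint. Returns per-voxel T1, T2* and proton-density volumes; when a
#' compartment has a nonzero `t2star_sd`, voxel T2* values are drawn
#' `Normal(mean, sd)` (truncated at 1 ms) under the spec seed, so the same
#' spec always yields bit-identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @param wm_radius,brain_radius Relative ellipsoid semi-axes (fractions of
#'   the grid half-width) of the WM core and the outer brain surface.
#' @return A list of class `tissue_phantom`: `masks` (named list of 3-D
#'   logicals `WM`, `GM`, `VC`), `labels` (integer array; 0 = background),
#'   `t1`, `t2star`, `pd` volumes, and the `spec`.
#' @export
make_tissue_phantom <- function(spec, wm_radius = 0.55, brain_radius = 0.85) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (wm_radius >= brain_radius)
    stop("zero-thickness gray-matter shell: wm_radius must be < brain_radius")
  d <- spec$grid_dim
  u <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  v <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  w <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  U <- array(rep(u, times = d[2] * d[3]), d)
  V <- array(rep(rep(v, each = d[1]), times = d[3]), d)
  W <- array(rep(w, each = d[1] * d[2]), d)
  r2 <- U^2 + V^2 + W^2
  brain <- r2 <= brain_radius^2
  wm <- r2 <= wm_radius^2
  shell <- brain & !wm
  vc <- shell & (V < -0.45)   # posterior sector of the shell
  gm <- shell & !vc
  masks <- list(WM = wm, GM = gm, VC = vc)
  if (any(!vapply(masks, any, logical(1))))
    stop("empty compartment mask: ",
         paste(names(masks)[!vapply(masks, any, logical(1))], collapse = ", "),
         " (geometry exceeds or degenerates on this grid)")
  labels <- array(0L, d)
  labels[wm] <- 1L; labels[gm] <- 2L; labels[vc] <- 3L
  t1 <- t2s <- pd <- array(0, d)
  set.seed(spec$seed)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    rp <- spec$relaxation[[nm]]
    t1[m] <- rp$t1
    pd[m] <- spec$proton_density[[nm]]
    sdv <- spec$t2star_sd[[nm]]
    t2s[m] <- if (is.null(sdv) || sdv == 0) rp$t2star else
      pmax(stats::rnorm(sum(m), rp$t2star, sdv), 1)
  }
  structure(list(masks = masks, labels = labels, t1 = t1, t2star = t2s,
                 pd = pd, spec = spec),
            class = "tissue_phantom")
}

#' Synthetic coil sensitivities and noise covariance
#'
#' Smooth complex receive sensitivities for an `n_coils`-element array:
#' Gaussian lobes centered on a ring around the object, each with a mild
#' linear phase ramp. The root-sum-of-squares of the array is strictly
#' positive everywhere. The unit-scale noise covariance is
#' `I + rho * (J - I)` (identity plus uniform off-diagonal coupling).
#'
#' @param n_coils Number of coils (`1` gives a uniform sensitivity and
#'   `Psi = 1`).
#' @param grid_dim Integer length 2: in-plane grid.
#' @param rho Off-diagonal coupling, `|rho| < 1`.
#' @return A list: `sens` (complex array `(coil, nx, ny)`), `psi_unit`
#'   (unit-scale covariance matrix).
#' @export
synthesize_coils <- function(n_coils, grid_dim, rho = 0.1) {
  stopifnot(n_coils >= 1, length(grid_dim) == 2L)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  nx <- grid_dim[1]; ny <- grid_dim[2]
  if (n_coils == 1L) {
    sens <- array(1 + 0i, c(1L, nx, ny))
    return(list(sens = sens, psi_unit = matrix(1, 1, 1)))
  }
  u <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  v <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  U <- outer(u, rep(1, ny)); V <- outer(rep(1, nx), v)
  sens <- array(0i, c(n_coils, nx, ny))
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  for (cl in seq_len(n_coils)) {
    cx <- 1.15 * cos(ang[cl]); cy <- 1.15 * sin(ang[cl])
    mag <- exp(-((U - cx)^2 + (V - cy)^2) / (2 * 0.9^2))
    phase <- 0.7 * (U * cos(ang[cl] + pi / 4) + V * sin(ang[cl] + pi / 4)) +
      ang[cl] / 3
    sens[cl, , ] <- mag * exp(1i * phase)
  }
  psi <- matrix(rho, n_coils, n_coils); diag(psi) <- 1
  list(sens = sens, psi_unit = psi)
}

# AR(1) realization standardized to zero mean and unit sample SD, optionally
# orthogonalized against another series first (so injected variances are
# exact in-sample, not just in expectation).
ar1_standardized <- function(n, phi = 0.9, orth_to = NULL) {
  if (n < 3) return(numeric(n))  # too short to carry a fluctuation
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  for (t in seq_len(n - 1))
    x[t + 1] <- phi * x[t] + sqrt(1 - phi^2) * stats::rnorm(1)
  if (!is.null(orth_to)) {
    z <- orth_to - mean(orth_to)
    x <- x - z * sum(z * x) / sum(z^2)
  }
  x <- x - mean(x)
  x / stats::sd(x)
}

# Spoiled-GRE voxel signal for the phantom at one TE (image units):
# PD * voxel volume * steady state * exp(-TE/T2*), zero outside tissue.
phantom_signal <- function(phantom, te, tr, flip_deg) {
  p <- phantom
  s <- array(0, p$spec$grid_dim)
  inside <- p$labels > 0L
  s[inside] <- p$pd[inside] * prod(p$spec$voxel_dims) *
    steady_state(tr, p$t1[inside], flip_deg) * exp(-te / p$t2star[inside])
  s
}

#' Simulate a multi-echo GRE acquisition
#'
#' Image-domain forward simulation of a 3-D spoiled multi-echo GRE scan of
#' the phantom: voxel signal `PD * steady-state(TR, FA, T1) * exp(-TE/T2*)`
#' at each echo, scaled so the first-echo gray-matter signal is `s0_scale`,
#' plus white Gaussian noise. Defaults follow the 2 mm relaxometry protocol
#' used at 0.5 T: 26 echoes from 5 ms in steps of 3.4 ms, FA 32 deg,
#' TR 97.25 ms.
#'
#' @param phantom A [make_tissue_phantom()] result.
#' @param echo_times Echo times, ms (strictly increasing).
#' @param flip_angle,tr Flip angle (deg) and TR (ms).
#' @param snr First-echo gray-matter SNR (`Inf` for noiseless).
#' @param s0_scale First-echo gray-matter signal level, image units.
#' @param seed Seed for the noise (defaults to the spec seed).
#' @return A [multi_echo_series()].
#' @export
simulate_megre <- function(phantom, echo_times = seq(5, by = 3.4,
                                                     length.out = 26),
                           flip_angle = 32, tr = 97.25, snr = 100,
                           s0_scale = 1000, seed = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo times must be strictly increasing")
  d <- phantom$spec$grid_dim
  if (is.null(seed)) seed <- phantom$spec$seed
  gm <- phantom$masks$GM
  ref <- phantom_signal(phantom, echo_times[1], tr, flip_angle)
  scale <- s0_scale / mean(ref[gm])
  dat <- array(0, c(d, length(echo_times)))
  set.seed(seed)
  sigma <- if (is.finite(snr)) s0_scale / snr else 0
  for (e in seq_along(echo_times)) {
    img <- scale * phantom_signal(phantom, echo_times[e], tr, flip_angle)
    if (sigma > 0) img <- img + stats::rnorm(length(img), sd = sigma)
    dat[, , , e] <- abs(img)
  }
  multi_echo_series(dat, echo_times, phantom$spec$voxel_dims)
}

#' Simulate a multi-coil EPI k-space time series
#'
#' Forward-simulates a repeated single-shot EPI acquisition of the phantom
#' with thermal and physiological noise, returning multi-coil k-space
#' together with the analytic ground truth of the noise decomposition.
#'
#' Per repetition `t`, the image is
#' \deqn{I_t(x) = S(x)\,\bigl(1 + \lambda_c\, g_t +
#'   \lambda_b\, \tfrac{TE}{T_2^*(x)}\, h_t\bigr),}
#' where `S(x)` is the spoiled-GRE signal at the protocol's TE/TR/FA,
#' `g_t` and `h_t` are unit-variance low-frequency (AR(1), coefficient 0.9)
#' processes, `lambda_c` scales the signal-proportional (non-BOLD)
#' physiological term and `lambda_b` the BOLD-like term, whose `TE/T2*`
#' weighting makes the physiological-to-thermal noise ratio grow as
#' `TE exp(-TE/T2*)`, i.e. monotonically as TE approaches T2*. The
#' realizations of `g` and `h` are standardized (and `h` orthogonalized
#' against `g`) so the injected variances hold exactly in-sample. Each
#' image is multiplied by the coil sensitivities, transformed to k-space by
#' the centered unitary FFT, and correlated thermal noise drawn from the
#' coil covariance is added independently per repetition.
#'
#' When the spec carries a `target_ratio`, `lambda_const` is calibrated so
#' the gray-matter mean of the ground-truth sigma_P/sigma_T equals that
#' target at this protocol's TE.
#'
#' @param phantom A [make_tissue_phantom()] result.
#' @param protocol An [epi_protocol()] (its `te`, `tr`, `flip_angle` and
#'   `voxel_dims` drive the signal model; the simulation grid is the
#'   phantom's).
#' @param n_repeats Number of repetitions (default 64).
#' @param coils Optional [synthesize_coils()] result to reuse across
#'   protocols; built from the spec when `NULL`.
#' @param seed Seed (defaults to the spec seed).
#' @return A list of class `epi_simulation`: `kspace` (a 5-D
#'   [kspace_series()]), `coils`, and `truth` — a list with the noiseless
#'   RSS `signal`, `sigma_t` (thermal noise SD of the RSS magnitude image),
#'   `sigma_p` (physiological SD), `ratio` (sigma_P/sigma_T, `NA` outside
#'   tissue), `thermal_sigma` (k-space units), `lambda_const`,
#'   `lambda_bold`.
#' @export
simulate_epi_timeseries <- function(phantom, protocol, n_repeats = 64,
                                    coils = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(protocol, "epi_protocol"))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (is.null(protocol$flip_angle))
    stop("protocol needs a flip angle (e.g. ernst_angle_deg)")
  spec <- phantom$spec
  d <- spec$grid_dim
  if (is.null(coils))
    coils <- synthesize_coils(spec$n_coils, d[1:2], spec$coil_rho)
  if (dim(coils$sens)[2] != d[1] || dim(coils$sens)[3] != d[2])
    stop("coil maps do not match the phantom grid")
  n_coils <- dim(coils$sens)[1]
  if (is.null(seed)) seed <- spec$seed

  S <- phantom_signal(phantom, protocol$te, protocol$tr, protocol$flip_angle)
  rss <- sqrt(apply(Mod(coils$sens)^2, c(2, 3), sum))       # (nx, ny)
  rss3 <- array(rep(rss, d[3]), d)

  # thermal noise level: per-quadrature k-space SD
  sigma <- spec$thermal_sigma
  if (is.null(sigma)) {
    # unit-diagonal psi: RSS-image thermal SD = sigma at every voxel
    sigma <- mean((S * rss3)[phantom$masks$GM]) / spec$target_snr
  }
  psi <- sigma^2 * coils$psi_unit
  # ground-truth thermal SD of the RSS magnitude image (high-SNR projection
  # of the coil noise onto the signal direction)
  st_xy <- matrix(0, d[1], d[2])
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    sv <- coils$sens[, ix, iy]
    st_xy[ix, iy] <- sqrt(Re(Conj(sv) %*% psi %*% sv)) / rss[ix, iy]
  }
  sigma_t <- array(rep(st_xy, d[3]), d)

  # physiological amplitudes
  w_bold <- array(0, d)
  inside <- phantom$labels > 0L
  w_bold[inside] <- protocol$te / phantom$t2star[inside]
  lam_c <- spec$lambda_const; lam_b <- spec$lambda_bold
  if (!is.null(spec$target_ratio)) {
    base <- (S * rss3 / sigma_t)[phantom$masks$GM]
    bold_part <- (lam_b * w_bold)[phantom$masks$GM]
    # solve mean(base * sqrt(lam_c^2 + bold^2)) = target for lam_c
    f <- function(lc) mean(base * sqrt(lc^2 + bold_part^2)) -
      spec$target_ratio
    if (f(0) >= 0) {
      lam_c <- 0
    } else {
      lam_c <- stats::uniroot(f, c(0, 10), tol = 1e-10)$root
    }
  }
  sigma_p <- S * rss3 * sqrt(lam_c^2 + (lam_b * w_bold)^2)
  ratio <- array(NA_real_, d)
  ratio[inside] <- (sigma_p / sigma_t)[inside]

  set.seed(seed)
  g <- ar1_standardized(n_repeats)
  h <- ar1_standardized(n_repeats, orth_to = g)
  L <- psd_factor(psi, strict = FALSE)
  ksp <- array(0i, c(n_coils, d[1], d[2], d[3], n_repeats))
  for (t in seq_len(n_repeats)) {
    img <- S * (1 + lam_c * g[t] + lam_b * w_bold * h[t])
    noise <- draw_coil_noise(L, n_coils, prod(d))
    dim(noise) <- c(n_coils, d)
    for (sl in seq_len(d[3])) {
      for (cl in seq_len(n_coils)) {
        ksp[cl, , , sl, t] <- fft2c(img[, , sl] * coils$sens[cl, , ]) +
          noise[cl, , , sl]
      }
    }
  }
  structure(list(
    kspace = kspace_series(ksp, psi, protocol),
    coils = coils,
    truth = list(signal = S * rss3, sigma_t = sigma_t, sigma_p = sigma_p,
                 ratio = ratio, thermal_sigma = sigma,
                 lambda_const = lam_c, lambda_bold = lam_b)
  ), class = "epi_simulation")
}

#' Reconstruct every repetition of a simulated series
#'
#' Convenience wrapper: root-sum-of-squares reconstruction of each
#' repetition of a 5-D k-space series into a 4-D magnitude time series
#' suitable for [temporal_snr()].
#'
#' @param kspace A 5-D [kspace_series()].
#' @return 4-D array `(x, y, slice, rep)`.
#' @export
recon_timeseries <- function(kspace) {
  stopifnot(inherits(kspace, "kspace_series"))
  d <- dim(kspace$data)
  if (length(d) != 5L) stop("expected a repetition axis")
  out <- array(0, c(d[2], d[3], d[4], d[5]))
  for (t in seq_len(d[5]))
    out[, , , t] <- recon_rss(kspace$data[, , , , t])
  out
}
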