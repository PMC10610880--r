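# Fourier reconstruction helpers. The package uses the unitary centered FFT
# convention: fft2c and ifft2c are exact inverses, both scaled by
# 1/sqrt(Nx*Ny), so Parseval holds with no extra factors and white noise of
# SD sigma in k-space maps to white noise of SD sigma in image space.

fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq_len(ceiling(d[1] / 2)) + floor(d[1] / 2), seq_len(floor(d[1] / 2))),
    c(seq_len(ceiling(d[2] / 2)) + floor(d[2] / 2), seq_len(floor(d[2] / 2))),
    drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq_len(floor(d[1] / 2)) + ceiling(d[1] / 2), seq_len(ceiling(d[1] / 2))),
    c(seq_len(floor(d[2] / 2)) + ceiling(d[2] / 2), seq_len(ceiling(d[2] / 2))),
    drop = FALSE]
}

#' Centered unitary 2-D Fourier transforms
#'
#' `fft2c()` maps an image-space slice to centered k-space (DC at the matrix
#' center); `ifft2c()` is its exact inverse. Both are unitary (scaled by
#' `1/sqrt(Nx*Ny)`), so energy is conserved between domains.
#'
#' @param x 2-D complex or numeric matrix.
#' @return Complex matrix of the same size.
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# Triangular/eigen factor L of a Hermitian positive-definite matrix such
# that L %*% Conj(t(L)) = psi. Complex Cholesky via eigendecomposition
# (base chol() does not accept complex input).
psd_factor <- function(psi, strict = TRUE) {
  psi <- as.matrix(psi)
  if (!isTRUE(all.equal(psi, Conj(t(psi)), tolerance = 1e-10)))
    stop("noise covariance must be Hermitian")
  e <- eigen(psi, symmetric = TRUE)
  top <- max(abs(e$values))
  if (strict && min(e$values) <= 1e-12 * top)
    stop("noise covariance is not positive-definite")
  if (min(e$values) < -1e-10 * max(top, 1))
    stop("noise covariance is indefinite (negative eigenvalues)")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * Conj(t(e$vectors)))
}

#' Multi-coil k-space container
#'
#' Complex Cartesian k-space with coil axis first and an associated coil
#' noise-covariance matrix. The covariance convention is per quadrature:
#' the real and imaginary noise channels each have covariance `noise_cov`
#' across coils, so a diagonal entry `sigma^2` means thermal noise of SD
#' `sigma` in each quadrature, and (after unitary reconstruction) a
#' high-SNR magnitude-image noise SD of `sigma` for a single coil.
#'
#' @param data Complex array `(coil, kx, ky, slice)` or
#'   `(coil, kx, ky, slice, rep)`.
#' @param noise_cov Hermitian positive-definite coil covariance matrix.
#' @param protocol Optional [epi_protocol()] carried as metadata.
#' @return An object of class `kspace_series`.
#' @export
kspace_series <- function(data, noise_cov, protocol = NULL) {
  nd <- length(dim(data))
  if (!(nd %in% c(4L, 5L)))
    stop("data must be (coil, kx, ky, slice[, rep])")
  noise_cov <- as.matrix(noise_cov)
  if (nrow(noise_cov) != dim(data)[1])
    stop("noise_cov dimension (", nrow(noise_cov),
         ") does not match the coil axis (", dim(data)[1], ")")
  psd_factor(noise_cov, strict = FALSE)  # Hermitian PSD (0 = noiseless)
  structure(list(data = data, noise_cov = noise_cov, protocol = protocol),
            class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("k-space series: %d coils, %d x %d matrix, %d slices%s\n",
              d[1], d[2], d[3], d[4],
              if (length(d) == 5L) sprintf(", %d repetitions", d[5]) else ""))
  invisible(x)
}

#' Root-sum-of-squares image reconstruction
#'
#' Reconstructs magnitude images from Cartesian multi-coil k-space by a
#' centered unitary inverse FFT per slice per coil followed by
#' root-sum-of-squares combination over coils.
#'
#' @param kspace A [kspace_series()] or a complex array
#'   `(coil, kx, ky, slice)`.
#' @return 3-D magnitude array `(x, y, slice)`.
#' @export
recon_rss <- function(kspace) {
  k <- if (inherits(kspace, "kspace_series")) kspace$data else kspace
  d <- dim(k)
  if (length(d) != 4L) stop("expected a single acquisition (coil,kx,ky,slice)")
  out <- array(0, d[2:4])
  for (s in seq_len(d[4])) {
    acc <- matrix(0, d[2], d[3])
    for (cl in seq_len(d[1]))
      acc <- acc + Mod(ifft2c(k[cl, , , s]))^2
    out[, , s] <- sqrt(acc)
  }
  out
}

# Draw one correlated complex noise realization for every k-space sample:
# iid CN per coil, colored across coils by the factor of the covariance.
# Each quadrature has covariance `psi` (see kspace_series).
draw_coil_noise <- function(L, n_coils, n_samples) {
  eta <- matrix(stats::rnorm(n_coils * n_samples), n_coils) +
    1i * matrix(stats::rnorm(n_coils * n_samples), n_coils)
  L %*% eta
}
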