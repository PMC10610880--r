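#' Multi-echo gradient-echo image series
#'
#' Container for 4-D multi-echo GRE magnitude data with the echo axis last.
#'
#' @param data 4-D numeric array `(x, y, z, echo)` of magnitudes (>= 0).
#' @param echo_times Strictly increasing echo times, ms; length must equal
#'   the echo axis.
#' @param voxel_dims Voxel dimensions in mm (length 1 or 3).
#' @return An object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(data, echo_times, voxel_dims = c(2, 2, 2)) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4-D array (x, y, z, echo)")
  if (dim(data)[4] != length(echo_times))
    stop("echo axis length (", dim(data)[4], ") != number of echo times (",
         length(echo_times), ")")
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo times must be strictly increasing")
  if (min(data) < 0) stop("magnitude data must be non-negative")
  if (length(voxel_dims) == 1L) voxel_dims <- rep(voxel_dims, 3L)
  structure(list(data = data, echo_times = echo_times,
                 voxel_dims = voxel_dims),
            class = "multi_echo_series")
}

#' @export
print.multi_echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Multi-echo GRE series: %d x %d x %d voxels, %d echoes (%.1f-%.1f ms)\n",
    d[1], d[2], d[3], d[4], min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

#' Fit a mono-exponential decay to one voxel
#'
#' Fits `S(TE) = S0 * exp(-TE / T2*)` to a multi-echo magnitude signal.
#' The default estimator is a weighted log-linear fit (weights proportional
#' to the squared signal, which makes the log-domain least squares
#' equivalent to first-order signal-domain least squares); `method =
#' "nonlin"` refines it with Levenberg-Marquardt nonlinear least squares.
#'
#' Echoes whose magnitude falls below `3 * noise_sd` (the noise floor)
#' or is non-positive are excluded. Fits with fewer than 3 usable echoes,
#' non-decaying signal, `r_squared < 0.8` or T2* outside [1, 2000] ms are
#' flagged invalid rather than raising an error, so that voxel-wise mapping
#' can proceed.
#'
#' @param signal Non-negative magnitudes, one per echo.
#' @param echo_times Echo times, ms.
#' @param method `"loglin"` (default) or `"nonlin"`.
#' @param noise_sd Estimated background noise SD (same units as `signal`);
#'   0 disables the noise floor.
#' @return A list with `s0`, `t2star` (ms), `r_squared` (computed in the
#'   signal domain), and `valid`.
#' @examples
#' te <- seq(5, by = 3.4, length.out = 26)
#' fit_monoexp(1000 * exp(-te / 86.3), te)$t2star
#' @export
fit_monoexp <- function(signal, echo_times, method = c("loglin", "nonlin"),
                        noise_sd = 0) {
  method <- match.arg(method)
  if (length(signal) != length(echo_times))
    stop("signal and echo_times must have equal length")
  if (length(signal) < 3L) stop("need at least 3 echoes")
  if (any(signal < 0)) stop("signal must be non-negative")
  invalid <- list(s0 = NA_real_, t2star = NA_real_, r_squared = NA_real_,
                  valid = FALSE)
  keep <- signal > max(3 * noise_sd, 0) & signal > 0
  if (sum(keep) < 3L) return(invalid)
  s <- signal[keep]; te <- echo_times[keep]
  # weighted log-linear: log S = log S0 - TE/T2*, weights ~ S^2
  fit <- stats::lm.wfit(cbind(1, te), log(s), w = s^2)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0) return(invalid)
  s0 <- unname(exp(fit$coefficients[1])); t2s <- -1 / slope
  if (method == "nonlin") {
    nl <- try(minpack.lm::nlsLM(
      s ~ a * exp(-te / b), start = list(a = s0, b = t2s),
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      cf <- stats::coef(nl)
      if (is.finite(cf[["b"]]) && cf[["b"]] > 0) {
        s0 <- cf[["a"]]; t2s <- cf[["b"]]
      }
    }
  }
  pred <- s0 * exp(-te / t2s)
  ss_tot <- sum((s - mean(s))^2)
  if (ss_tot <= 0) return(invalid)
  r2 <- 1 - sum((s - pred)^2) / ss_tot
  valid <- is.finite(t2s) && t2s >= 1 && t2s <= 2000 && r2 >= 0.8
  list(s0 = unname(s0), t2star = unname(t2s), r_squared = r2, valid = valid)
}

#' Voxel-wise T2* mapping
#'
#' Applies [fit_monoexp()] to every voxel inside a mask.
#'
#' @param series A [multi_echo_series()].
#' @param mask 3-D logical array matching the spatial dimensions, or `NULL`
#'   to fit everywhere.
#' @param method,noise_sd Passed to [fit_monoexp()].
#' @return An object of class `t2star_map`: a list of 3-D arrays `t2star`
#'   (ms), `s0`, `r_squared` and logical `valid` (voxels outside the mask or
#'   failing the fit are `NA` / `FALSE`).
#' @export
map_t2star <- function(series, mask = NULL, method = c("loglin", "nonlin"),
                       noise_sd = 0) {
  stopifnot(inherits(series, "multi_echo_series"))
  method <- match.arg(method)
  sp <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!identical(dim(mask), as.integer(sp)) &&
      !identical(dim(mask), sp))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match spatial dims ", paste(sp, collapse = "x"))
  t2s <- s0 <- r2 <- array(NA_real_, sp)
  valid <- array(FALSE, sp)
  idx <- which(mask)
  if (length(idx)) {
    flat <- matrix(series$data, nrow = prod(sp))
    for (i in idx) {
      f <- fit_monoexp(flat[i, ], series$echo_times, method = method,
                       noise_sd = noise_sd)
      t2s[i] <- f$t2star; s0[i] <- f$s0; r2[i] <- f$r_squared
      valid[i] <- f$valid
    }
  }
  structure(list(t2star = t2s, s0 = s0, r_squared = r2, valid = valid,
                 voxel_dims = series$voxel_dims, method = method),
            class = "t2star_map")
}

#' @export
print.t2star_map <- function(x, ...) {
  cat(sprintf("T2* map (%s fit): %s voxels, %d valid\n",
              x$method, paste(dim(x$t2star), collapse = " x "),
              sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  valid T2*: median %.1f ms, IQR %.1f-%.1f ms\n",
                stats::median(x$t2star[x$valid]),
                stats::quantile(x$t2star[x$valid], 0.25),
                stats::quantile(x$t2star[x$valid], 0.75)))
  invisible(x)
}

#' ROI summary of a T2* map
#'
#' Mean and sample standard deviation of T2* over the valid voxels of a
#' region of interest.
#'
#' @param map A [map_t2star()] result.
#' @param roi_mask 3-D logical ROI mask.
#' @return A data.frame with `mean`, `sd` (ms) and `n_voxels`.
#' @export
roi_stats <- function(map, roi_mask) {
  stopifnot(inherits(map, "t2star_map"))
  if (!all(dim(roi_mask) == dim(map$t2star)))
    stop("ROI mask shape does not match the map")
  sel <- roi_mask & map$valid
  n <- sum(sel)
  if (n == 0L) stop("ROI contains no valid voxels")
  v <- map$t2star[sel]
  data.frame(mean = mean(v), sd = if (n > 1L) stats::sd(v) else 0,
             n_voxels = n)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti for the 4-D series and 3-D maps the package
#' uses. `read_multi_echo()` attaches echo times to a 4-D NIfTI file;
#' `write_map()` stores any 3-D array (`NA` written as 0 with a companion
#' validity volume when `valid` is supplied).
#'
#' @param path NIfTI file path.
#' @param echo_times Echo times, ms, for the 4th axis.
#' @param voxel_dims Voxel size override, mm; taken from the header when
#'   `NULL`.
#' @return `read_multi_echo()` a [multi_echo_series()]; `read_volume()` an
#'   array; `write_map()` the path, invisibly.
#' @export
read_multi_echo <- function(path, echo_times, voxel_dims = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (is.null(voxel_dims))
    voxel_dims <- RNifti::pixdim(img)[1:3]
  multi_echo_series(arr, echo_times, voxel_dims)
}

#' @rdname read_multi_echo
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' @rdname read_multi_echo
#' @param x 3-D array to write.
#' @param voxel_dims Voxel size, mm.
#' @export
write_map <- function(x, path, voxel_dims = c(1, 1, 1)) {
  x[!is.finite(x)] <- 0
  img <- RNifti::asNifti(x, pixdim = voxel_dims)
  RNifti::writeNifti(img, path)
  invisible(path)
}
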