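#' Band-pass filter parameters
#'
#' The transcript channel is filtered with a Gaussian high pass (removes
#' slowly varying background) followed by a Gaussian low pass (smooths
#' spot-scale signal).  `sigma_high` must exceed `sigma_low`: the background
#' varies at cell scale while a diffraction-limited spot has a FWHM of only
#' 2-3 pixels at typical confocal sampling (0.285 um pixels).
#'
#' @param sigma_high High-pass Gaussian width, voxels (default 10).
#' @param sigma_low Low-pass Gaussian width, voxels (default 1).
#' @param truncate Kernel extent in standard deviations (default 4).
#' @param per_axis_sigma Optional length-3 `(z, y, x)` multipliers applied to
#'   both sigmas, for anisotropic filtering; default isotropic.
#' @return A `filter_params` list.
#' @export
filter_params <- function(sigma_high = 10, sigma_low = 1, truncate = 4,
                          per_axis_sigma = c(1, 1, 1)) {
  check_number(sigma_high, "sigma_high", lower = .Machine$double.eps)
  check_number(sigma_low, "sigma_low", lower = .Machine$double.eps)
  check_number(truncate, "truncate", lower = .Machine$double.eps)
  if (sigma_high <= sigma_low) {
    abort("`sigma_high` must be larger than `sigma_low` (background scale > spot scale)")
  }
  stopifnot(length(per_axis_sigma) == 3L, all(per_axis_sigma > 0))
  structure(list(sigma_high = sigma_high, sigma_low = sigma_low,
                 truncate = truncate, per_axis_sigma = as.numeric(per_axis_sigma)),
            class = "filter_params")
}

axis_sigmas <- function(sigma, per_axis) rep_len(sigma, 3L) * per_axis

#' Gaussian high-pass filter
#'
#' Subtracts a wide Gaussian blur and clips negatives to zero:
#' `max(v - G(v; sigma), 0)`.  Constant offsets are removed exactly (away
#' from image borders), so the result is invariant to additive background.
#'
#' @param v A volume.
#' @param sigma Blur width in voxels (scalar, or length 3 for `(z, y, x)`).
#' @param truncate Kernel extent in sigmas.
#' @return Filtered volume, same shape, non-negative.
#' @export
gaussian_high_pass <- function(v, sigma, truncate = 4) {
  if (any(sigma <= 0)) abort("`sigma` must be positive")
  v <- as_volume(v)
  bg <- gaussian_smooth(unclass(v), rep_len(sigma, 3L), truncate)
  volume_like(pmax(unclass(v) - bg, 0), v)
}

#' Gaussian low-pass filter
#'
#' Gaussian blur with width `sigma`; mass-preserving up to boundary effects
#' (the kernel is normalised to unit sum).
#'
#' @inheritParams gaussian_high_pass
#' @return Smoothed volume, same shape.
#' @export
gaussian_low_pass <- function(v, sigma, truncate = 4) {
  if (any(sigma <= 0)) abort("`sigma` must be positive")
  v <- as_volume(v)
  volume_like(gaussian_smooth(unclass(v), rep_len(sigma, 3L), truncate), v)
}

#' Band-pass a transcript channel
#'
#' High pass with `sigma_high` then low pass with `sigma_low` (order fixed).
#' The output is what [detect_spots()] consumes; the operation is a pure
#' function of the volume and parameters.
#'
#' @param v A volume (normalized transcript channel).
#' @param params A [filter_params()] object.
#' @return Filtered volume.
#' @export
bandpass <- function(v, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  hp <- gaussian_high_pass(v, axis_sigmas(params$sigma_high, params$per_axis_sigma),
                           params$truncate)
  gaussian_low_pass(hp, axis_sigmas(params$sigma_low, params$per_axis_sigma),
                    params$truncate)
}
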