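#' Reconstructed volume container
#'
#' A 2D slice (or slice stack) with its pixel size and a tag saying which
#' physical quantity the voxel values carry: `"rho"` (phase-channel
#' reconstruction in fringe units), `"rho_a"`/`"mu"` (absorption channel,
#' 1/length), `"delta"` (refractive index decrement) or `"mask"`.
#'
#' @param values numeric matrix.
#' @param pixel_size voxel edge length.
#' @param quantity one of `"rho"`, `"rho_a"`, `"mu"`, `"delta"`, `"mask"`.
#' @return Object of class `pcct_volume`.
#' @export
pcct_volume <- function(values, pixel_size = 1,
                        quantity = c("rho", "rho_a", "mu", "delta", "mask")) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, pixel_size = pixel_size,
                 quantity = quantity), class = "pcct_volume")
}

#' @export
print.pcct_volume <- function(x, ...) {
  cat("pcct volume [", x$quantity, "]: ",
      paste(dim(x$values), collapse = " x "), " pixels (size ",
      x$pixel_size, "), values in [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.pcct_volume <- function(x, main = NULL, ...) {
  v <- x$values
  image(seq_len(nrow(v)), seq_len(ncol(v)), v, asp = 1,
        col = gray.colors(256), xlab = "x [px]", ylab = "y [px]",
        main = if (is.null(main)) paste("pcct volume:", x$quantity) else main,
        useRaster = TRUE, ...)
  invisible(x)
}

# apply a frequency-domain filter (vector H over padded length) per view
.filter_sinogram <- function(sino, H) {
  n <- ncol(sino); N <- length(H)
  pad <- matrix(0, nrow(sino), N)
  pad[, seq_len(n)] <- sino
  Fs <- mvfft(t(pad))
  q <- Re(mvfft(Fs * H, inverse = TRUE)) / N
  t(q)[, seq_len(n), drop = FALSE]
}

.fbp_backproject <- function(filtered, geometry) {
  back_project(filtered, geometry) *
    (geometry$det_spacing / geometry$pixel_size^2) *
    (pi / geometry$n_angles)
}

.pad_length <- function(n) 2^ceiling(log2(max(2 * n, 16)))

#' Filtered backprojection of the absorption channel
#'
#' Classical parallel-beam FBP: per-view Ram-Lak ramp filtering (optionally
#' windowed) in the frequency domain with zero-padding to the next power of
#' two >= 2*n_det, followed by interpolating backprojection scaled by
#' `pi / n_angles`. Input is the log-transmission sinogram
#' `-log(transmission)`; the output voxel values are the linear attenuation
#' coefficient (1/length).
#'
#' @param log_sinogram `n_angles x n_det` matrix of `-log(T)` values;
#'   non-positive transmissions must already have been masked upstream.
#' @param geometry a [projection_geometry()].
#' @param filter_window `"ramlak"` (pure ramp) or `"hann"`.
#' @return A `pcct_volume` with quantity `"mu"`.
#' @export
fbp_absorption <- function(log_sinogram, geometry,
                           filter_window = c("ramlak", "hann")) {
  filter_window <- match.arg(filter_window)
  log_sinogram <- .check_sino(log_sinogram, geometry)
  N <- .pad_length(geometry$n_det)
  nu <- .fftfreq(N, geometry$det_spacing)
  H <- abs(nu)
  if (filter_window == "hann")
    H <- H * (0.5 + 0.5 * cos(pi * nu / max(abs(nu))))
  img <- .fbp_backproject(.filter_sinogram(log_sinogram, H), geometry)
  pcct_volume(img, geometry$pixel_size, "mu")
}

#' Hilbert-filter filtered backprojection of differential phase data
#'
#' FBP for differential projections: because the measured signal is the
#' detector-axis derivative of the phase line integral, the ramp filter
#' `|nu|` is replaced by the antisymmetric imaginary-odd Hilbert response
#' `-i sign(nu) / (2 pi)` (so that applied to the derivative it equals the
#' ramp applied to the underlying projection), again with power-of-two
#' zero-padding. The DC component is set to zero -- the absolute offset is
#' unobservable in differential data and is restored later by the water
#' offset of [to_delta()]. A calibration scalar absorbs the physics
#' constant between fringe phase and refraction.
#'
#' @param dphase_sinogram `n_angles x n_det` differential-phase sinogram
#'   (radians).
#' @param geometry a [projection_geometry()].
#' @param calibration multiplicative scalar applied to the reconstruction.
#' @return A `pcct_volume` with quantity `"rho"`.
#' @export
fbp_dpc <- function(dphase_sinogram, geometry, calibration = 1) {
  dphase_sinogram <- .check_sino(dphase_sinogram, geometry)
  N <- .pad_length(geometry$n_det)
  nu <- .fftfreq(N, geometry$det_spacing)
  H <- -1i * sign(nu) / (2 * pi)
  img <- .fbp_backproject(.filter_sinogram(dphase_sinogram, H), geometry)
  pcct_volume(calibration * img, geometry$pixel_size, "rho")
}

#' Convert a phase reconstruction to refractive index decrement
#'
#' Affine conversion `delta = c * rho + delta_water`: the calibration
#' scalar `c` maps fringe-scaled reconstruction units to refractive
#' decrement (use `1 / fringe_scale` for simulated data; default 1 keeps
#' simulation units), and adding the decrement of water accounts for the
#' constant offset created by a water bath extending over the field of
#' view, which differential measurements cannot see.
#'
#' @param volume a `pcct_volume` with quantity `"rho"`.
#' @param delta_water refractive index decrement of water (dimensionless).
#' @param calibration scalar `c`.
#' @return A `pcct_volume` with quantity `"delta"`.
#' @export
to_delta <- function(volume, delta_water = 4.567e-7, calibration = 1) {
  stopifnot(inherits(volume, "pcct_volume"))
  if (volume$quantity != "rho")
    stop("to_delta expects a volume with quantity 'rho', got '",
         volume$quantity, "'")
  pcct_volume(calibration * volume$values + delta_water,
              volume$pixel_size, "delta")
}
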