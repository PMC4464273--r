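#' Parallel-beam projection geometry
#'
#' Coordinate conventions used throughout the package: pixel centers sit at
#' `(i + 0.5 - N/2) * pixel_size` (0-based i), rotation is about the image
#' center, and view angles are measured from the detector axis, so at angle
#' zero the detector lies along x and rays run along +y. Detector bin
#' centers sit at `(d + 0.5 - n_det/2) * det_spacing`.
#'
#' @param image_shape integer length-1 or 2, image size in pixels.
#' @param n_angles number of views; angles default to an equispaced grid on
#'   `[0, pi)`.
#' @param angles optional explicit view angles (radians, strictly
#'   increasing, within `[0, pi)`).
#' @param n_det number of detector bins; must cover the image diagonal (no
#'   truncation). Defaults to the diagonal plus a two-bin margin.
#' @param det_spacing detector bin width; defaults to `pixel_size`.
#' @param pixel_size image pixel edge length.
#' @return An object of class `pcct_geometry`.
#' @export
projection_geometry <- function(image_shape, n_angles = 180L, angles = NULL,
                                n_det = NULL, det_spacing = NULL,
                                pixel_size = 1) {
  image_shape <- as.integer(rep(image_shape, length.out = 2))
  if (is.null(det_spacing)) det_spacing <- pixel_size
  if (is.null(angles)) {
    n_angles <- as.integer(n_angles)
    if (n_angles < 1) stop("n_angles must be positive")
    angles <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  }
  angles <- as.numeric(angles)
  if (length(angles) > 1 && any(diff(angles) <= 0))
    stop("angles must be strictly increasing")
  diag_bins <- ceiling(sqrt(sum((image_shape * pixel_size)^2)) / det_spacing)
  if (is.null(n_det)) n_det <- as.integer(diag_bins + 2L)
  if (n_det < diag_bins)
    stop("detector truncates the image: n_det = ", n_det,
         " but the image diagonal spans ", diag_bins, " bins")
  structure(list(n_angles = length(angles), angles = angles,
                 n_det = as.integer(n_det), det_spacing = det_spacing,
                 image_shape = image_shape, pixel_size = pixel_size),
            class = "pcct_geometry")
}

#' @export
print.pcct_geometry <- function(x, ...) {
  cat("pcct parallel-beam geometry:", x$n_angles, "angles over [",
      signif(x$angles[1], 3), ",", signif(x$angles[x$n_angles], 4), "],",
      x$n_det, "detector bins (spacing", x$det_spacing, "),",
      paste(x$image_shape, collapse = "x"), "image (pixel",
      x$pixel_size, ")\n")
  invisible(x)
}

.as_image <- function(image, geometry) {
  if (inherits(image, "pcct_volume")) image <- image$values
  image <- as.matrix(image)
  if (!all(dim(image) == geometry$image_shape))
    stop("image shape ", paste(dim(image), collapse = "x"),
         " does not match geometry ",
         paste(geometry$image_shape, collapse = "x"))
  image
}

.check_sino <- function(sino, geometry) {
  sino <- as.matrix(sino)
  if (nrow(sino) != geometry$n_angles || ncol(sino) != geometry$n_det)
    stop("sinogram shape ", paste(dim(sino), collapse = "x"),
         " does not match geometry ", geometry$n_angles, "x", geometry$n_det)
  sino
}

#' Forward projection (discrete line integrals)
#'
#' Distance-driven (separable-footprint) discretization of the
#' parallel-beam Radon transform: each pixel's shadow on the detector
#' axis, the trapezoid `box(|cos b| px) * box(|sin b| px)`, is integrated
#' exactly over the detector bins, and the pixel deposits
#' `value * pixel_size^2 / det_spacing` times those bin fractions. The
#' fractions sum to one, so projected mass is conserved exactly, and for
#' extended objects the bin values converge to the line integrals scaled
#' by physical length. The operator is linear; [back_project()] is its
#' exact matrix adjoint.
#'
#' @param image numeric matrix (or `pcct_volume`) matching the geometry.
#' @param geometry a [projection_geometry()].
#' @return Sinogram matrix, `n_angles` x `n_det`.
#' @export
forward_project <- function(image, geometry) {
  image <- .as_image(image, geometry)
  cpp_forward_project(image, cos(geometry$angles), sin(geometry$angles),
                      geometry$n_det, geometry$det_spacing,
                      geometry$pixel_size)
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param sinogram numeric matrix, `n_angles` x `n_det`.
#' @param geometry a [projection_geometry()].
#' @return Image matrix.
#' @export
back_project <- function(sinogram, geometry) {
  sinogram <- .check_sino(sinogram, geometry)
  cpp_back_project(sinogram, geometry$image_shape[1], geometry$image_shape[2],
                   cos(geometry$angles), sin(geometry$angles),
                   geometry$det_spacing, geometry$pixel_size)
}

#' Detector-axis derivative of a sinogram and its exact adjoint
#'
#' Central differences along the detector axis scaled by `1/det_spacing`,
#' one-sided at the two boundary bins, so the derivative is a complete
#' linear map on sinograms. `adjoint_diff_detector()` applies the exact
#' transpose stencil (including the boundary rows), as required by the
#' iterative solver.
#'
#' @param sinogram numeric matrix, `n_angles` x `n_det` (`n_det >= 3`).
#' @param geometry a [projection_geometry()].
#' @return Sinogram matrix of the same shape.
#' @export
diff_detector <- function(sinogram, geometry) {
  sinogram <- .check_sino(sinogram, geometry)
  n <- ncol(sinogram)
  if (n < 3) stop("diff_detector needs at least 3 detector bins")
  h <- geometry$det_spacing
  out <- sinogram
  out[, 2:(n - 1)] <- (sinogram[, 3:n] - sinogram[, 1:(n - 2)]) / (2 * h)
  out[, 1] <- (sinogram[, 2] - sinogram[, 1]) / h
  out[, n] <- (sinogram[, n] - sinogram[, n - 1]) / h
  out
}

#' @rdname diff_detector
#' @export
adjoint_diff_detector <- function(sinogram, geometry) {
  y <- .check_sino(sinogram, geometry)
  n <- ncol(y)
  if (n < 3) stop("adjoint_diff_detector needs at least 3 detector bins")
  h <- geometry$det_spacing
  out <- matrix(0, nrow(y), n)
  # interior derivative rows j = 2..n-1: +1/(2h) at j+1, -1/(2h) at j-1
  out[, 3:n] <- out[, 3:n] + y[, 2:(n - 1)] / (2 * h)
  out[, 1:(n - 2)] <- out[, 1:(n - 2)] - y[, 2:(n - 1)] / (2 * h)
  # one-sided boundary rows
  out[, 1] <- out[, 1] - y[, 1] / h
  out[, 2] <- out[, 2] + y[, 1] / h
  out[, n - 1] <- out[, n - 1] - y[, n] / h
  out[, n] <- out[, n] + y[, n] / h
  out
}
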