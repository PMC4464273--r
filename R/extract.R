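# Weighted least-squares stepping-curve retrieval.
#
# The cosine model a0 + a1*cos(2*pi*x/k + phi) is linearized as
# b0 + bc*cos(w x) + bs*sin(w x) with bc = a1*cos(phi), bs = -a1*sin(phi),
# solved by weighted normal equations with w_j = 1/max(I_j, floor)
# (Poisson variance estimated from the observed counts). With these
# weights the inverse normal matrix is the parameter covariance, which is
# pushed through the nonlinear change of variables by the delta method.

.fit_frames <- function(I, positions, period, weight_floor = 1) {
  I <- as.matrix(I)
  ns <- ncol(I)
  if (ns < 3) stop("need at least 3 phase steps")
  if (length(positions) != ns) stop("positions length must match steps")
  if (min(I) < 0) stop("negative intensities")
  w <- 1 / pmax(I, weight_floor)
  ang <- 2 * pi * positions / period
  C <- cos(ang); S <- sin(ang)
  wI <- w * I
  s11 <- rowSums(w)
  s12 <- drop(w %*% C);  s13 <- drop(w %*% S)
  s22 <- drop(w %*% C^2); s23 <- drop(w %*% (C * S)); s33 <- drop(w %*% S^2)
  b1 <- rowSums(wI); b2 <- drop(wI %*% C); b3 <- drop(wI %*% S)
  det <- s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
    s13 * (s12 * s23 - s22 * s13)
  ok <- is.finite(det) & det > 1e-12 * pmax(s11, 1)^3
  det[!ok] <- NA_real_
  i11 <- (s22 * s33 - s23^2) / det
  i12 <- (s13 * s23 - s12 * s33) / det
  i13 <- (s12 * s23 - s13 * s22) / det
  i22 <- (s11 * s33 - s13^2) / det
  i23 <- (s13 * s12 - s11 * s23) / det
  i33 <- (s11 * s22 - s12^2) / det
  b0 <- i11 * b1 + i12 * b2 + i13 * b3
  bc <- i12 * b1 + i22 * b2 + i23 * b3
  bs <- i13 * b1 + i23 * b2 + i33 * b3
  a0 <- b0
  a1 <- sqrt(bc^2 + bs^2)
  phi <- atan2(-bs, bc)
  # delta method through (a0, a1, phi) = g(b0, bc, bs)
  var_a0 <- i11
  var_a1 <- (bc^2 * i22 + 2 * bc * bs * i23 + bs^2 * i33) / a1^2
  var_phi <- (bs^2 * i22 - 2 * bc * bs * i23 + bc^2 * i33) / a1^4
  cov_a0_a1 <- (bc * i12 + bs * i13) / a1
  valid <- ok & is.finite(a0) & a0 > 0 & is.finite(a1) &
    a1 > 1e-8 * pmax(a0, 1)
  fill <- function(v, bad_value = Inf) { v[!valid] <- bad_value; v }
  list(a0 = fill(a0, NA_real_), a1 = fill(a1, NA_real_),
       phi1 = fill(phi, NA_real_),
       var_a0 = fill(var_a0), var_a1 = fill(var_a1),
       var_phi1 = fill(var_phi), cov_a0_a1 = fill(cov_a0_a1, 0),
       valid = valid)
}

#' Fit one phase-stepping curve by weighted least squares
#'
#' Minimizes `sum_j w_j (I_j - a0 - a1 cos(2 pi x_j / k + phi1))^2` with
#' `w_j = 1 / max(I_j, floor)` via the linearized normal equations, and
#' returns the delta-method covariance of `(a0, a1, phi1)`. Degenerate
#' curves (singular normal matrix, non-positive mean, vanishing fringe
#' amplitude) are flagged invalid with infinite variances rather than
#' raising an error, so downstream statistical weighting handles them
#' uniformly as zero-weight pixels.
#'
#' @param intensities counts per step (length >= 3, non-negative).
#' @param positions grating positions `x_g` (same length).
#' @param period grating period `k`.
#' @param weight_floor floor on the per-step variance estimate (counts);
#'   prevents division by zero at starved pixels.
#' @return List with `a0`, `a1`, `phi1`, `cov` (3x3 covariance in
#'   `(a0, a1, phi1)` order) and `valid`.
#' @examples
#' x <- (0:3) / 4
#' I <- 100 + 50 * cos(2 * pi * x + 0.7)
#' fit_stepping_curve(I, x, 1)[c("a0", "a1", "phi1")]
#' @export
fit_stepping_curve <- function(intensities, positions, period,
                               weight_floor = 1) {
  f <- .fit_frames(matrix(intensities, nrow = 1), positions, period,
                   weight_floor)
  cov <- matrix(NA_real_, 3, 3,
                dimnames = list(c("a0", "a1", "phi1"), c("a0", "a1", "phi1")))
  diag(cov) <- c(f$var_a0, f$var_a1, f$var_phi1)
  cov[1, 2] <- cov[2, 1] <- f$cov_a0_a1
  cov[1, 3] <- cov[3, 1] <- 0
  cov[2, 3] <- cov[3, 2] <- 0
  list(a0 = f$a0, a1 = f$a1, phi1 = f$phi1, cov = cov, valid = f$valid)
}

#' Fit every stepping curve of a scan
#'
#' Vectorized [fit_stepping_curve()] over all (view, detector) pixels of a
#' `pcct_scan`.
#'
#' @param scan a `pcct_scan` from [simulate_stepping_scan()] or
#'   [read_scan()].
#' @param weight_floor see [fit_stepping_curve()].
#' @return Object of class `pcct_fit`: list of `n_angles x n_det` matrices
#'   `a0`, `a1`, `phi1`, `var_a0`, `var_a1`, `var_phi1`, `cov_a0_a1`,
#'   `valid`, plus the geometry.
#' @export
fit_scan <- function(scan, weight_floor = 1) {
  stopifnot(inherits(scan, "pcct_scan"))
  d <- dim(scan$intensities)
  na <- d[1]; ns <- d[2]; nd <- d[3]
  I <- aperm(scan$intensities, c(1, 3, 2))
  dim(I) <- c(na * nd, ns)
  f <- .fit_frames(I, scan$step_positions, scan$grating_period, weight_floor)
  out <- lapply(f, function(v) matrix(v, na, nd))
  out$geometry <- scan$geometry
  structure(out, class = "pcct_fit")
}

#' Extract absorption, differential-phase and dark-field sinograms
#'
#' Normalizes per-pixel sample fits by the reference (flat-field) fits:
#' transmission `a0_s / a0_r`, differential phase `wrap(phi_s - phi_r)`,
#' dark field `(a1_s/a0_s) / (a1_r/a0_r)`, each with a delta-method
#' variance propagated from the fit covariances. Pixels invalid in either
#' fit (or with vanishing reference mean) receive infinite variance, i.e.
#' zero statistical weight downstream.
#'
#' @param sample_fits,reference_fits `pcct_fit` objects from [fit_scan()]
#'   (or `pcct_scan` objects, which are fitted on the fly).
#' @return Object of class `pcct_signals`: matrices `transmission`,
#'   `dphase`, `darkfield`, `var_transmission`, `var_dphase`,
#'   `var_darkfield`, `valid`, plus the geometry.
#' @export
extract_signals <- function(sample_fits, reference_fits) {
  if (inherits(sample_fits, "pcct_scan")) sample_fits <- fit_scan(sample_fits)
  if (inherits(reference_fits, "pcct_scan"))
    reference_fits <- fit_scan(reference_fits)
  stopifnot(inherits(sample_fits, "pcct_fit"),
            inherits(reference_fits, "pcct_fit"))
  if (!all(dim(sample_fits$a0) == dim(reference_fits$a0)))
    stop("sample and reference fit shapes differ")
  s <- sample_fits; r <- reference_fits
  valid <- s$valid & r$valid & is.finite(r$a0) & r$a0 > 0
  safe <- function(x, repl = 0) { x[!valid] <- repl; x }
  a0s <- ifelse(valid, s$a0, 1); a0r <- ifelse(valid, r$a0, 1)
  a1s <- ifelse(valid, s$a1, 1); a1r <- ifelse(valid, r$a1, 1)
  trans <- safe(a0s / a0r, 1)
  dph <- safe(wrap_phase(ifelse(valid, s$phi1 - r$phi1, 0)), 0)
  vs <- a1s / a0s; vr <- a1r / a0r
  dark <- safe(vs / vr, 1)
  var_t <- trans^2 * (s$var_a0 / a0s^2 + r$var_a0 / a0r^2)
  var_p <- s$var_phi1 + r$var_phi1
  rel_vs <- s$var_a1 / a1s^2 + s$var_a0 / a0s^2 -
    2 * s$cov_a0_a1 / (a0s * a1s)
  rel_vr <- r$var_a1 / a1r^2 + r$var_a0 / a0r^2 -
    2 * r$cov_a0_a1 / (a0r * a1r)
  var_d <- dark^2 * (rel_vs + rel_vr)
  inf <- function(v) { v[!valid | !is.finite(v)] <- Inf; v }
  structure(list(transmission = trans, dphase = dph, darkfield = dark,
                 var_transmission = inf(var_t), var_dphase = inf(var_p),
                 var_darkfield = inf(var_d), valid = valid,
                 geometry = s$geometry), class = "pcct_signals")
}

#' @export
print.pcct_signals <- function(x, ...) {
  cat("pcct signal triplet:", nrow(x$dphase), "views x", ncol(x$dphase),
      "detector bins;", sum(!x$valid), "invalid pixels\n")
  cat(sprintf("  transmission in [%.3g, %.3g], |dphase| <= %.3g, darkfield in [%.3g, %.3g]\n",
              min(x$transmission), max(x$transmission), max(abs(x$dphase)),
              min(x$darkfield), max(x$darkfield)))
  invisible(x)
}

#' Gaussian PSF deconvolution of detector frames
#'
#' Frequency-domain division by a Gaussian transfer function with a
#' Tikhonov floor: the inverse filter is `G / (G^2 + floor)` where `G =
#' exp(-2 pi^2 sigma^2 nu^2)` (per axis). With `sigma = 0` the input is
#' returned unchanged. Optional preprocessing for detectors with spatial
#' crosstalk; off by default in the pipeline.
#'
#' @param frames numeric matrix (one frame) or 3D array (stack over the
#'   first dimension).
#' @param sigma Gaussian PSF standard deviation in pixels, >= 0.
#' @param floor Tikhonov regularization floor, > 0.
#' @return Deconvolved frames, same shape.
#' @export
deconvolve_psf <- function(frames, sigma, floor = 1e-3) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(frames)
  if (floor <= 0) stop("regularization floor must be positive")
  one <- function(img) {
    n1 <- nrow(img); n2 <- ncol(img)
    g1 <- exp(-2 * pi^2 * sigma^2 * .fftfreq(n1)^2)
    g2 <- exp(-2 * pi^2 * sigma^2 * .fftfreq(n2)^2)
    G <- outer(g1, g2)
    Re(fft(fft(img) * G / (G^2 + floor), inverse = TRUE)) / (n1 * n2)
  }
  if (is.matrix(frames)) return(one(frames))
  if (length(dim(frames)) == 3) {
    out <- frames
    for (k in seq_len(dim(frames)[1])) out[k, , ] <- one(frames[k, , ])
    return(out)
  }
  stop("frames must be a matrix or a 3D array")
}

#' Gaussian blur (the forward counterpart of [deconvolve_psf()])
#'
#' @inheritParams deconvolve_psf
#' @return Blurred frames, same shape.
#' @export
blur_psf <- function(frames, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(frames)
  one <- function(img) {
    n1 <- nrow(img); n2 <- ncol(img)
    g1 <- exp(-2 * pi^2 * sigma^2 * .fftfreq(n1)^2)
    g2 <- exp(-2 * pi^2 * sigma^2 * .fftfreq(n2)^2)
    Re(fft(fft(img) * outer(g1, g2), inverse = TRUE)) / (n1 * n2)
  }
  if (is.matrix(frames)) return(one(frames))
  out <- frames
  for (k in seq_len(dim(frames)[1])) out[k, , ] <- one(frames[k, , ])
  out
}

# unit-spacing DFT sample frequencies (cycles per sample)
.fftfreq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}
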