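#' Acquisition configuration for the phase-stepping simulator
#'
#' Holds the interferometer and sampling parameters. The differential
#' refraction angle produced by a sample maps to a fringe-phase shift
#' through the lumped constant `fringe_scale = 2 * pi * talbot_distance /
#' grating_period`; because the simulator works in detector-pixel length
#' units the constant can also be set directly, keeping the units
#' self-consistent. The defaults emulate a synchrotron scan at a high
#' fractional Talbot order, where bone rims shift the fringe phase well
#' beyond pi.
#'
#' @param n_angles number of projection views.
#' @param n_steps phase steps per view; at least 3 (the stepping-curve fit
#'   has three unknowns). Steps are equispaced over one grating period.
#' @param grating_period period of the analyser grating G2 (m).
#' @param talbot_distance inter-grating distance (m).
#' @param photon_count mean reference counts per pixel per step; > 0.
#' @param visibility reference fringe visibility, in (0, 1].
#' @param detector_pixel detector pixel size (length units).
#' @param seed integer seed; fully determines a noisy scan.
#' @param fringe_scale optional override of the lumped refraction-to-phase
#'   constant (radians per unit transverse gradient of the delta line
#'   integral).
#' @return An object of class `pcct_acquisition`.
#' @export
acquisition_config <- function(n_angles = 200L, n_steps = 4L,
                               grating_period = 2.4e-6,
                               talbot_distance = 0.36,
                               photon_count = 1e4, visibility = 0.3,
                               detector_pixel = 1, seed = 0L,
                               fringe_scale = NULL) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 3) stop("n_steps must be at least 3 (three unknowns in the cosine fit)")
  if (photon_count <= 0) stop("photon_count must be positive")
  if (visibility <= 0 || visibility > 1) stop("visibility must lie in (0, 1]")
  if (is.null(fringe_scale))
    fringe_scale <- 2 * pi * talbot_distance / grating_period
  structure(list(n_angles = as.integer(n_angles), n_steps = n_steps,
                 grating_period = grating_period,
                 talbot_distance = talbot_distance,
                 photon_count = photon_count, visibility = visibility,
                 detector_pixel = detector_pixel, seed = as.integer(seed),
                 fringe_scale = fringe_scale),
            class = "pcct_acquisition")
}

#' @export
print.pcct_acquisition <- function(x, ...) {
  cat("pcct acquisition:", x$n_angles, "views x", x$n_steps, "steps,",
      format(x$photon_count, big.mark = ","), "counts/step, visibility",
      x$visibility, "\n")
  cat(sprintf("  fringe_scale = %.4g rad per unit phase gradient, seed %d\n",
              x$fringe_scale, x$seed))
  invisible(x)
}

#' Wrap phase values into [-pi, pi)
#'
#' Fringe-phase measurements are only defined on the unit circle; any value
#' is congruent (mod 2*pi) to exactly one representative in the half-open
#' interval `[-pi, pi)`. The half-open convention maps `+pi` to `-pi`.
#'
#' @param phi numeric vector/array of phases (radians).
#' @return Wrapped phases, same shape.
#' @examples
#' wrap_phase(c(0, pi, 1.5 * pi, 7.5))
#' @export
wrap_phase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

#' Simulate a grating-interferometer phase-stepping acquisition
#'
#' For each view and detector bin the noiseless stepping curve is
#' `photon_count * T * (1 + visibility * D * cos(2*pi*x_g/k + dphi))` with
#' transmission `T = exp(-A mu)`, visibility reduction `D = exp(-A
#' epsilon)` and fringe shift `dphi = fringe_scale * d/dx (A
#' (delta - delta_water))`, where `A` is the forward projector and `d/dx`
#' the detector-axis derivative. The fringe shift is wrapped into
#' `[-pi, pi)` *before* the Poisson noise is realized, so statistical phase
#' wrapping emerges naturally where strong absorption starves the counts.
#' The reference scan views the empty beam (unit transmission, reference
#' visibility, zero phase).
#'
#' @param phantom a [make_phantom()] object.
#' @param config an [acquisition_config()].
#' @param geometry optional [projection_geometry()]; defaults to one
#'   matching the phantom with `config$n_angles` views.
#' @param noise logical; `FALSE` returns the noiseless mean counts.
#' @param wrap logical; `FALSE` disables phase wrapping (diagnostic mode).
#' @return List with elements `sample` and `reference`, each of class
#'   `pcct_scan` (fields `intensities` as an `n_angles x n_steps x n_det`
#'   array, `step_positions`, `grating_period`, plus photon metadata and
#'   the geometry). The sample scan carries the noiseless ground-truth
#'   sinograms in its `truth` field.
#' @export
simulate_stepping_scan <- function(phantom, config, geometry = NULL,
                                   noise = TRUE, wrap = TRUE) {
  stopifnot(inherits(phantom, "pcct_phantom"),
            inherits(config, "pcct_acquisition"))
  if (config$photon_count <= 0) stop("photon_count must be positive")
  if (config$n_steps < 3) stop("n_steps must be at least 3")
  if (is.null(geometry))
    geometry <- projection_geometry(dim(phantom$delta_map),
                                    n_angles = config$n_angles,
                                    det_spacing = config$detector_pixel,
                                    pixel_size = phantom$pixel_size)
  if (!all(geometry$image_shape == dim(phantom$delta_map)))
    stop("geometry image_shape does not match the phantom")

  trans <- exp(-forward_project(phantom$mu_map, geometry))
  dark <- exp(-forward_project(phantom$epsilon_map, geometry))
  p_delta <- forward_project(phantom$delta_map - phantom$delta_water, geometry)
  dphi_unwrapped <- config$fringe_scale * diff_detector(p_delta, geometry)
  dphi <- if (wrap) wrap_phase(dphi_unwrapped) else dphi_unwrapped

  ns <- config$n_steps
  positions <- (seq_len(ns) - 1) * config$grating_period / ns
  omega <- 2 * pi * positions / config$grating_period
  na <- geometry$n_angles; nd <- geometry$n_det
  mk <- function(tr, dk, ph) {
    arr <- array(0, dim = c(na, ns, nd))
    for (j in seq_len(ns))
      arr[, j, ] <- config$photon_count * tr *
        (1 + config$visibility * dk * cos(omega[j] + ph))
    arr
  }
  mean_s <- mk(trans, dark, dphi)
  mean_r <- mk(1, 1, 0)
  if (noise) {
    set.seed(config$seed)
    mean_s[] <- rpois(length(mean_s), mean_s)
    mean_r[] <- rpois(length(mean_r), mean_r)
  }
  scan <- function(int, truth = NULL) {
    structure(list(intensities = int, step_positions = positions,
                   grating_period = config$grating_period,
                   photon_count = config$photon_count,
                   visibility = config$visibility, geometry = geometry,
                   truth = truth), class = "pcct_scan")
  }
  list(sample = scan(mean_s, truth = list(transmission = trans,
                                          darkfield = dark, dphase = dphi,
                                          dphase_unwrapped = dphi_unwrapped)),
       reference = scan(mean_r))
}

#' @export
print.pcct_scan <- function(x, ...) {
  d <- dim(x$intensities)
  cat("pcct stepping scan:", d[1], "views x", d[2], "steps x", d[3],
      "detector bins\n")
  cat(sprintf("  counts in [%.4g, %.4g], grating period %.3g\n",
              min(x$intensities), max(x$intensities), x$grating_period))
  invisible(x)
}

#' Simulate method for phantoms
#'
#' Convenience wrapper around [simulate_stepping_scan()] following the base
#' `simulate()` generic: returns a list of `nsim` independent scan pairs.
#'
#' @param object a `pcct_phantom`.
#' @param nsim number of scan pairs.
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @param config an [acquisition_config()].
#' @param ... passed to [simulate_stepping_scan()].
#' @return List of length `nsim` of `list(sample, reference)` pairs.
#' @export
simulate.pcct_phantom <- function(object, nsim = 1, seed = 0L,
                                  config = acquisition_config(), ...) {
  lapply(seq_len(nsim), function(r) {
    cfg <- config
    cfg$seed <- as.integer(seed + r - 1)
    simulate_stepping_scan(object, cfg, ...)
  })
}
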