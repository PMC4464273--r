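# Penalized weighted least-squares reconstruction of the phase channel:
#
#   Phi(rho) = sum_rays w (s - D A rho)^2
#            + lambda_q * sum_j sum_{k in N(j)} (rho_j - rho_k)^2
#            + lambda_h * sum_{j in soft} sum_{k in N(j)} psi(rho_j - rho_k, t)
#            + lambda_b * sum_{j in bone} (rho_j - c * rho_a_j)^2
#
# with s the measured differential-phase sinogram, A the forward
# projector, D the detector-axis derivative, w = m / sigma^2 the modified
# statistical weights, psi the Huber potential, and c the bone coupling
# (delta/mu proportionality of the dense material). The quadratic term
# runs over the complete volume; Huber and bone act on the complementary
# soft/bone masks. Minimized by Polak-Ribiere+ nonlinear conjugate
# gradients with Armijo backtracking.

#' Huber potential and its derivative
#'
#' Edge-preserving penalty on a neighbor value difference `d`: quadratic
#' `d^2/2` for `|d| <= t`, linear `t |d| - t^2/2` above, continuously
#' differentiable at the knee. The threshold `t` separates differences
#' treated as noise (smoothed quadratically) from differences treated as
#' genuine edges (penalized only linearly).
#'
#' @param d numeric value difference(s).
#' @param t positive threshold.
#' @return Potential (or derivative) values, same shape as `d`.
#' @examples
#' huber_potential(c(0, 1, 2), 1)   # 0, 0.5, 1.5
#' @export
huber_potential <- function(d, t) {
  if (t <= 0) stop("huber threshold must be positive")
  a <- abs(d)
  ifelse(a <= t, 0.5 * d^2, t * a - 0.5 * t^2)
}

#' @rdname huber_potential
#' @export
huber_derivative <- function(d, t) {
  if (t <= 0) stop("huber threshold must be positive")
  pmin(pmax(d, -t), t)
}

#' Control parameters for the SIR objective and optimizer
#'
#' The regularization strengths are in objective units: the data term sums
#' `w * residual^2` over rays with `w ~ 1/var(dphase)` (typically O(10^2)
#' in the default study), so lambda values of order 1-10 give mild
#' smoothing at the default photon count. The defaults are the documented
#' settings of the default study and are recorded in every result's
#' config snapshot.
#'
#' @param lambda_q weight of the quadratic smoothness term (whole volume).
#' @param lambda_h weight of the Huber term (soft-tissue mask).
#' @param huber_threshold Huber knee `t`, in reconstruction (rho) units;
#'   roughly the soft-tissue contrast scale.
#' @param lambda_b weight of the bone coupling term (bone mask).
#' @param bone_coupling proportionality constant `c` between the phase and
#'   absorption reconstructions in bone (the delta/mu ratio of the dense
#'   material, in rho units per mu unit). Required whenever `lambda_b > 0`
#'   and a prior is supplied.
#' @param max_iters iteration cap, >= 1.
#' @param gradient_tolerance stop when the gradient norm falls below this
#'   fraction of the gradient norm at the zero volume.
#' @param init `"zero"` (default) or `"fbp"` starting point.
#' @param seed integer recorded in the config snapshot.
#' @param armijo_c sufficient-decrease constant of the line search.
#' @param armijo_shrink backtracking shrink factor.
#' @param max_backtracks line-search cap before declaring failure.
#' @return Object of class `sir_control`.
#' @export
sir_control <- function(lambda_q = 30, lambda_h = 1000,
                        huber_threshold = 0.02,
                        lambda_b = 1000, bone_coupling = NULL,
                        max_iters = 200L, gradient_tolerance = 1e-6,
                        init = c("zero", "fbp"), seed = 0L,
                        armijo_c = 1e-4, armijo_shrink = 0.5,
                        max_backtracks = 60L) {
  if (lambda_q < 0 || lambda_h < 0 || lambda_b < 0)
    stop("regularization weights must be non-negative")
  if (huber_threshold <= 0) stop("huber_threshold must be positive")
  max_iters <- as.integer(max_iters)
  if (max_iters < 1) stop("max_iters must be at least 1")
  structure(list(lambda_q = lambda_q, lambda_h = lambda_h,
                 huber_threshold = huber_threshold, lambda_b = lambda_b,
                 bone_coupling = bone_coupling, max_iters = max_iters,
                 gradient_tolerance = gradient_tolerance,
                 init = match.arg(init), seed = as.integer(seed),
                 armijo_c = armijo_c, armijo_shrink = armijo_shrink,
                 max_backtracks = as.integer(max_backtracks)),
            class = "sir_control")
}

#' Default bone coupling constant for simulated data
#'
#' The delta/mu proportionality of the dense material expressed in the
#' reconstruction's units: `fringe_scale * (delta_bone - delta_water) /
#' mu_bone` from the simulator's material table.
#'
#' @param config an [acquisition_config()].
#' @param materials material table, see [pcct_materials()].
#' @return Scalar coupling constant.
#' @export
default_bone_coupling <- function(config, materials = pcct_materials()) {
  bone <- materials[match("bone", materials$material), ]
  water <- materials[match("water", materials$material), ]
  config$fringe_scale * (bone$delta - water$delta) / bone$mu
}

# ---- internal objective machinery ------------------------------------

.rho_values <- function(rho) if (inherits(rho, "pcct_volume")) rho$values else as.matrix(rho)

# sum over ordered neighbor pairs of squared differences (each unordered
# pair counted twice, matching the j-then-neighbors double sum)
.quad_roughness <- function(r) {
  nx <- nrow(r); ny <- ncol(r)
  dx <- r[-1, , drop = FALSE] - r[-nx, , drop = FALSE]
  dy <- r[, -1, drop = FALSE] - r[, -ny, drop = FALSE]
  2 * (sum(dx^2) + sum(dy^2))
}

# gradient of .quad_roughness: 4 * graph-Laplacian action
.quad_grad <- function(r) {
  nx <- nrow(r); ny <- ncol(r)
  s <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  s[-nx, ] <- s[-nx, ] + r[-1, ]; cnt[-nx, ] <- cnt[-nx, ] + 1
  s[-1, ]  <- s[-1, ]  + r[-nx, ]; cnt[-1, ] <- cnt[-1, ] + 1
  s[, -ny] <- s[, -ny] + r[, -1]; cnt[, -ny] <- cnt[, -ny] + 1
  s[, -1]  <- s[, -1]  + r[, -ny]; cnt[, -1] <- cnt[, -1] + 1
  4 * (cnt * r - s)
}

# Huber term over soft-mask voxels and their 4-neighbors (psi is even, so
# the j-in-soft double sum equals sum over unordered pairs weighted by the
# number of soft endpoints)
.huber_value <- function(r, soft, t) {
  nx <- nrow(r); ny <- ncol(r)
  sm <- soft + 0
  dx <- r[-1, , drop = FALSE] - r[-nx, , drop = FALSE]
  wx <- sm[-1, , drop = FALSE] + sm[-nx, , drop = FALSE]
  dy <- r[, -1, drop = FALSE] - r[, -ny, drop = FALSE]
  wy <- sm[, -1, drop = FALSE] + sm[, -ny, drop = FALSE]
  sum(wx * huber_potential(dx, t)) + sum(wy * huber_potential(dy, t))
}

# local curvature of the Huber term along direction d at the point r:
# psi'' is 1 inside the knee and 0 outside
.huber_curv <- function(r, d, soft, t) {
  nx <- nrow(r); ny <- ncol(r)
  sm <- soft + 0
  dxr <- r[-1, , drop = FALSE] - r[-nx, , drop = FALSE]
  dxd <- d[-1, , drop = FALSE] - d[-nx, , drop = FALSE]
  wx <- (sm[-1, , drop = FALSE] + sm[-nx, , drop = FALSE]) * (abs(dxr) <= t)
  dyr <- r[, -1, drop = FALSE] - r[, -ny, drop = FALSE]
  dyd <- d[, -1, drop = FALSE] - d[, -ny, drop = FALSE]
  wy <- (sm[, -1, drop = FALSE] + sm[, -ny, drop = FALSE]) * (abs(dyr) <= t)
  sum(wx * dxd^2) + sum(wy * dyd^2)
}

.huber_grad <- function(r, soft, t) {
  nx <- nrow(r); ny <- ncol(r)
  sm <- soft + 0
  g <- matrix(0, nx, ny)
  dx <- r[-1, , drop = FALSE] - r[-nx, , drop = FALSE]
  wx <- sm[-1, , drop = FALSE] + sm[-nx, , drop = FALSE]
  hx <- wx * huber_derivative(dx, t)
  g[-1, ] <- g[-1, ] + hx; g[-nx, ] <- g[-nx, ] - hx
  dy <- r[, -1, drop = FALSE] - r[, -ny, drop = FALSE]
  wy <- sm[, -1, drop = FALSE] + sm[, -ny, drop = FALSE]
  hy <- wy * huber_derivative(dy, t)
  g[, -1] <- g[, -1] + hy; g[, -ny] <- g[, -ny] - hy
  g
}

.sir_parts <- function(data, weights, geometry, control, prior, rho_a) {
  s <- .check_sino(data, geometry)
  w <- .check_sino(weights, geometry)
  if (any(w < 0)) stop("weights must be non-negative")
  w[!is.finite(w)] <- 0
  soft <- NULL; bone <- NULL; ra <- NULL; coupling <- 0
  if (!is.null(prior)) {
    soft <- prior$soft_mask; bone <- prior$bone_mask
    if (!all(dim(soft) == geometry$image_shape) ||
        !all(dim(bone) == geometry$image_shape))
      stop("prior mask shape does not match geometry")
  } else {
    soft <- matrix(TRUE, geometry$image_shape[1], geometry$image_shape[2])
    bone <- matrix(FALSE, geometry$image_shape[1], geometry$image_shape[2])
  }
  if (control$lambda_b > 0 && any(bone)) {
    if (is.null(rho_a)) stop("bone term requires the absorption volume rho_a")
    if (is.null(control$bone_coupling))
      stop("bone term requires control$bone_coupling (the delta/mu constant)")
    ra <- .rho_values(rho_a)
    if (!all(dim(ra) == geometry$image_shape))
      stop("rho_a shape does not match geometry")
    coupling <- control$bone_coupling
  } else {
    ra <- matrix(0, geometry$image_shape[1], geometry$image_shape[2])
  }
  list(s = s, w = w, soft = soft, bone = bone, ra = ra, coupling = coupling)
}

#' Evaluate the SIR objective function
#'
#' See the package vignette for the full model. Exposed mainly for testing
#' and diagnostics; [reconstruct_sir()] evaluates it internally.
#'
#' @param rho image matrix or `pcct_volume` (quantity `"rho"`).
#' @param data measured differential-phase sinogram `s`.
#' @param weights data-fidelity weight sinogram `w >= 0` (typically
#'   [apply_weight_modification()] output).
#' @param geometry a [projection_geometry()].
#' @param control a [sir_control()].
#' @param prior optional [bone_prior()] (masks for the Huber/bone terms).
#' @param rho_a absorption reconstruction coupled to in bone (required when
#'   `lambda_b > 0` and the prior marks bone voxels).
#' @return Scalar objective value.
#' @export
sir_objective <- function(rho, data, weights, geometry,
                          control = sir_control(), prior = NULL,
                          rho_a = NULL) {
  p <- .sir_parts(data, weights, geometry, control, prior, rho_a)
  r <- .as_image(.rho_values(rho), geometry)
  resid <- p$s - diff_detector(forward_project(r, geometry), geometry)
  val <- sum(p$w * resid^2)
  if (control$lambda_q > 0) val <- val + control$lambda_q * .quad_roughness(r)
  if (control$lambda_h > 0)
    val <- val + control$lambda_h *
      .huber_value(r, p$soft, control$huber_threshold)
  if (control$lambda_b > 0 && any(p$bone))
    val <- val + control$lambda_b *
      sum((r[p$bone] - p$coupling * p$ra[p$bone])^2)
  val
}

#' Analytic gradient of the SIR objective
#'
#' `-2 A^T D^T (w (s - D A rho))` plus the regularizer gradients
#' (quadratic: graph-Laplacian action; Huber: clipped differences over
#' soft-mask neighbor pairs; bone: `2 lambda_b (rho - c rho_a)` on bone
#' voxels).
#'
#' @inheritParams sir_objective
#' @return Gradient image matrix.
#' @export
sir_gradient <- function(rho, data, weights, geometry,
                         control = sir_control(), prior = NULL,
                         rho_a = NULL) {
  p <- .sir_parts(data, weights, geometry, control, prior, rho_a)
  r <- .as_image(.rho_values(rho), geometry)
  resid <- p$s - diff_detector(forward_project(r, geometry), geometry)
  g <- -2 * back_project(adjoint_diff_detector(p$w * resid, geometry),
                         geometry)
  if (control$lambda_q > 0) g <- g + control$lambda_q * .quad_grad(r)
  if (control$lambda_h > 0)
    g <- g + control$lambda_h * .huber_grad(r, p$soft, control$huber_threshold)
  if (control$lambda_b > 0 && any(p$bone))
    g[p$bone] <- g[p$bone] +
      2 * control$lambda_b * (r[p$bone] - p$coupling * p$ra[p$bone])
  g
}

#' Statistical iterative reconstruction of the phase channel
#'
#' Minimizes the penalized weighted least-squares objective by
#' Polak-Ribiere+ nonlinear conjugate gradients: directions restart on
#' non-descent, step lengths come from a backtracking Armijo line search
#' initialized at the exact minimizer of the local quadratic model, and
#' the objective trace is non-increasing by construction. Stops at
#' `max_iters`, when the gradient norm falls below `gradient_tolerance`
#' relative to its value at the zero volume, or when the line search can
#' no longer make progress (returning the best iterate).
#'
#' @param data differential-phase sinogram matrix, or a `pcct_signals`
#'   object (its `dphase` is used, and missing `weights` default to
#'   inverse variances, modified by the prior's m when a prior is given).
#' @param weights weight sinogram; see [apply_weight_modification()].
#' @param geometry a [projection_geometry()]; taken from `data` when it is
#'   a `pcct_signals`.
#' @param control a [sir_control()].
#' @param prior optional [bone_prior()].
#' @param rho_a absorption reconstruction (`pcct_volume`, quantity
#'   `"mu"`), required for the bone term.
#' @param init optional starting image (matrix or `pcct_volume`);
#'   otherwise `control$init` selects the zero volume or an FBP start.
#' @return Object of class `pcct_sir`: `rho` (a `pcct_volume`),
#'   `objective_trace`, `grad_norm_trace`, `iterations`, `converged`,
#'   `line_search_failed`, `config_snapshot`, and the inputs needed by the
#'   `predict`/`residuals` methods.
#' @examples
#' ph <- default_phantom(32)
#' cfg <- acquisition_config(n_angles = 48, seed = 1)
#' scans <- simulate_stepping_scan(ph, cfg)
#' sig <- extract_signals(scans$sample, scans$reference)
#' fit <- reconstruct_sir(sig, control = sir_control(lambda_b = 0,
#'                        lambda_h = 0, max_iters = 10))
#' fit
#' @export
reconstruct_sir <- function(data, weights = NULL, geometry = NULL,
                            control = sir_control(), prior = NULL,
                            rho_a = NULL, init = NULL) {
  if (inherits(data, "pcct_signals")) {
    if (is.null(geometry)) geometry <- data$geometry
    if (is.null(weights)) {
      m <- if (is.null(prior)) matrix(1, nrow(data$dphase), ncol(data$dphase))
           else prior$weight_modification
      weights <- apply_weight_modification(data$var_dphase, m)
    }
    data <- data$dphase
  }
  if (is.null(geometry)) stop("geometry is required")
  if (is.null(weights)) weights <- matrix(1, nrow(data), ncol(data))
  p <- .sir_parts(data, weights, geometry, control, prior, rho_a)
  nx <- geometry$image_shape[1]; ny <- geometry$image_shape[2]
  lam_q <- control$lambda_q; lam_h <- control$lambda_h
  lam_b <- if (any(p$bone)) control$lambda_b else 0
  t_h <- control$huber_threshold
  target <- if (lam_b > 0) p$coupling * p$ra else matrix(0, nx, ny)
  bone_n <- p$bone + 0

  mfwd <- function(x) diff_detector(forward_project(x, geometry), geometry)
  mback <- function(y) back_project(adjoint_diff_detector(y, geometry),
                                    geometry)
  objective_of <- function(r, Mr) {
    val <- sum(p$w * (p$s - Mr)^2)
    if (lam_q > 0) val <- val + lam_q * .quad_roughness(r)
    if (lam_h > 0) val <- val + lam_h * .huber_value(r, p$soft, t_h)
    if (lam_b > 0) val <- val + lam_b * sum(bone_n * (r - target)^2)
    val
  }
  gradient_of <- function(r, Mr) {
    g <- -2 * mback(p$w * (p$s - Mr))
    if (lam_q > 0) g <- g + lam_q * .quad_grad(r)
    if (lam_h > 0) g <- g + lam_h * .huber_grad(r, p$soft, t_h)
    if (lam_b > 0) g <- g + 2 * lam_b * bone_n * (r - target)
    g
  }

  rho <- if (!is.null(init)) .as_image(.rho_values(init), geometry)
         else if (control$init == "fbp") fbp_dpc(p$s, geometry)$values
         else matrix(0, nx, ny)
  g_ref <- sqrt(sum(gradient_of(matrix(0, nx, ny),
                                matrix(0, geometry$n_angles,
                                       geometry$n_det))^2))
  if (g_ref == 0) g_ref <- .Machine$double.eps

  Mr <- mfwd(rho)
  obj <- objective_of(rho, Mr)
  g <- gradient_of(rho, Mr)
  gnorm <- sqrt(sum(g^2))
  obj_trace <- obj
  grad_trace <- gnorm
  d <- -g
  converged <- gnorm <= control$gradient_tolerance * g_ref
  ls_failed <- FALSE
  iter <- 0L
  while (!converged && !ls_failed && iter < control$max_iters) {
    iter <- iter + 1L
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- -sum(g * g) }
    Md <- mfwd(d)
    curv <- 2 * sum(p$w * Md^2)
    if (lam_q > 0) curv <- curv + 2 * lam_q * .quad_roughness(d)
    if (lam_b > 0) curv <- curv + 2 * lam_b * sum(bone_n * d^2)
    if (lam_h > 0) curv <- curv + lam_h * .huber_curv(rho, d, p$soft, t_h)
    if (!is.finite(curv)) break
    alpha <- if (curv > 0) -gd / curv else 1
    # cheap exact line objective in alpha for the quadratic pieces
    wrM <- sum(p$w * (p$s - Mr) * Md)
    wMM <- sum(p$w * Md^2)
    quad_cross <- if (lam_q > 0)
      (.quad_roughness(rho + d) - .quad_roughness(rho) -
         .quad_roughness(d)) / 2 else 0
    quad_d <- if (lam_q > 0) .quad_roughness(d) else 0
    bone_cross <- if (lam_b > 0) sum(bone_n * (rho - target) * d) else 0
    bone_d <- if (lam_b > 0) sum(bone_n * d^2) else 0
    base_nh <- sum(p$w * (p$s - Mr)^2) +
      (if (lam_q > 0) lam_q * .quad_roughness(rho) else 0) +
      (if (lam_b > 0) lam_b * sum(bone_n * (rho - target)^2) else 0)
    phi_alpha <- function(a) {
      v <- base_nh - 2 * a * wrM + a^2 * wMM +
        (if (lam_q > 0) lam_q * (2 * a * quad_cross + a^2 * quad_d) else 0) +
        (if (lam_b > 0) lam_b * (2 * a * bone_cross + a^2 * bone_d) else 0)
      if (lam_h > 0) v <- v + lam_h * .huber_value(rho + a * d, p$soft, t_h)
      v
    }
    accepted <- FALSE
    for (bt in seq_len(control$max_backtracks)) {
      cand <- phi_alpha(alpha)
      if (is.finite(cand) && cand <= obj + control$armijo_c * alpha * gd) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * control$armijo_shrink
    }
    if (!accepted || alpha * sqrt(sum(d^2)) <
        .Machine$double.eps * (1 + sqrt(sum(rho^2)))) {
      ls_failed <- TRUE
      break
    }
    rho <- rho + alpha * d
    Mr <- Mr + alpha * Md
    obj_new <- objective_of(rho, Mr)
    if (obj_new > obj) { ls_failed <- TRUE; rho <- rho - alpha * d; break }
    obj <- obj_new
    g_new <- gradient_of(rho, Mr)
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    d <- -g_new + beta * d
    g <- g_new
    gnorm <- sqrt(sum(g^2))
    obj_trace <- c(obj_trace, obj)
    grad_trace <- c(grad_trace, gnorm)
    converged <- gnorm <= control$gradient_tolerance * g_ref
  }
  structure(list(
    rho = pcct_volume(rho, geometry$pixel_size, "rho"),
    objective_trace = obj_trace, grad_norm_trace = grad_trace,
    iterations = iter, converged = converged,
    line_search_failed = ls_failed,
    config_snapshot = list(control = control, geometry = geometry),
    data = p$s, weights = p$w, prior = prior, rho_a = rho_a,
    call = match.call()
  ), class = "pcct_sir")
}

#' Standard iterative reconstruction (comparison arm)
#'
#' Defined as [reconstruct_sir()] with uniform weights (no statistical
#' weighting, `m == 1`) and quadratic-only regularization (`lambda_h =
#' lambda_b = 0`) -- the conventional penalized least-squares baseline the
#' statistical method is compared against.
#'
#' @param data differential-phase sinogram matrix (or `pcct_signals`).
#' @param geometry a [projection_geometry()].
#' @param control a [sir_control()]; its Huber/bone weights are forced to
#'   zero.
#' @param init optional starting image.
#' @return A `pcct_sir` object.
#' @export
reconstruct_ir <- function(data, geometry = NULL, control = sir_control(),
                           init = NULL) {
  if (inherits(data, "pcct_signals")) {
    if (is.null(geometry)) geometry <- data$geometry
    data <- data$dphase
  }
  control$lambda_h <- 0
  control$lambda_b <- 0
  weights <- matrix(1, nrow(data), ncol(data))
  reconstruct_sir(data, weights, geometry, control)
}
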