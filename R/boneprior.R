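# Absorption-derived bone prior: dense-material segmentation, boundary
# gradients, and the projection-space weight modification m in [0, 1] that
# down-weights rays through bone/soft-tissue boundaries, where fringe
# shifts are large and phase wrapping is likely.

#' Segment dense material (bone) by thresholding an absorption volume
#'
#' A voxel belongs to the dense mask iff `mu >= threshold`. No
#' morphological cleanup is applied, preserving the full internal detail
#' of the bone. `threshold = "auto"` takes the midpoint between the two
#' highest modes of the intensity histogram (soft tissue/water vs bone).
#'
#' @param absorption a `pcct_volume` with quantity `"mu"` (or `"rho_a"`).
#' @param threshold attenuation threshold, or `"auto"`.
#' @return Logical matrix (dense mask) with attribute `threshold`.
#' @export
segment_dense <- function(absorption, threshold = "auto") {
  stopifnot(inherits(absorption, "pcct_volume"))
  if (!absorption$quantity %in% c("mu", "rho_a"))
    stop("segment_dense expects an absorption volume (quantity 'mu' or 'rho_a')")
  v <- absorption$values
  if (identical(threshold, "auto")) threshold <- auto_threshold(v)
  mask <- v >= threshold
  if (all(mask))
    warning("threshold below background level: entire volume segmented as dense")
  attr(mask, "threshold") <- threshold
  mask
}

#' Automatic bimodal threshold (Otsu's method)
#'
#' Maximizes the between-class variance of the intensity histogram --
#' the standard automatic choice for separating a small dense class
#' (bone) from a dominant soft-tissue/water background, where
#' histogram-mode heuristics are unreliable because the dense class holds
#' only a few percent of the voxels.
#'
#' @param values numeric vector or matrix.
#' @param nbins number of histogram bins.
#' @return Scalar threshold.
#' @export
auto_threshold <- function(values, nbins = 256) {
  v <- as.numeric(values)
  h <- graphics::hist(v, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[length(m0)]
  between <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  mean(mids[c(k, min(k + 1, length(mids)))])
}

#' Gradient magnitude of a (binary) volume
#'
#' Euclidean norm of per-axis central differences (one-sided at the array
#' boundaries), in units of value change per voxel. On a segmentation mask
#' this is nonzero only in the two-voxel band around mask boundaries,
#' locating the tissue-bone interfaces where the phase gradient is
#' largest.
#'
#' @param mask logical or numeric matrix.
#' @return Numeric matrix of gradient magnitudes.
#' @export
gradient_magnitude <- function(mask) {
  v <- mask
  if (is.logical(v)) v <- v + 0
  v <- as.matrix(v)
  n1 <- nrow(v); n2 <- ncol(v)
  gx <- v; gy <- v
  gx[2:(n1 - 1), ] <- (v[3:n1, ] - v[1:(n1 - 2), ]) / 2
  gx[1, ] <- v[2, ] - v[1, ]
  gx[n1, ] <- v[n1, ] - v[n1 - 1, ]
  gy[, 2:(n2 - 1)] <- (v[, 3:n2] - v[, 1:(n2 - 2)]) / 2
  gy[, 1] <- v[, 2] - v[, 1]
  gy[, n2] <- v[, n2] - v[, n2 - 1]
  sqrt(gx^2 + gy^2)
}

#' Projection-space weight modification from a boundary-gradient volume
#'
#' Forward-projects the gradient volume, normalizes the projections to
#' `[0, 1]` and inverts: `m = 1 - g / max(g)` (all ones when the gradient
#' volume is empty). Rays crossing many tissue-bone boundary voxels --
#' exactly the rays likely to contain wrapped phase -- receive small m.
#' Optionally the normalizer is an upper quantile instead of the global
#' maximum (with clipping), so that a single hot ray does not dilute the
#' modification; by default no clipping is applied.
#'
#' @param gradient_volume numeric matrix from [gradient_magnitude()] (or a
#'   `pcct_volume`).
#' @param geometry a [projection_geometry()].
#' @param clip optional quantile in (0, 1] used as the normalizer.
#' @return Sinogram-shaped matrix m with entries in `[0, 1]`.
#' @export
make_weight_modification <- function(gradient_volume, geometry, clip = NULL) {
  g <- forward_project(gradient_volume, geometry)
  top <- if (is.null(clip)) max(g) else quantile(g, clip, names = FALSE)
  if (!is.finite(top) || top <= 0) return(matrix(1, nrow(g), ncol(g)))
  pmin(pmax(1 - g / top, 0), 1)
}

#' Combine the weight modification with statistical weights
#'
#' The data-fidelity weight of each projection pixel is `w = m / sigma^2`:
#' inverse-variance statistical weighting multiplied by the bone-prior
#' modification. Pixels with infinite variance (degenerate fits) get
#' weight zero.
#'
#' @param variances sinogram of per-pixel variances (> 0, or `Inf` for
#'   invalid pixels).
#' @param m weight modification in `[0, 1]`, same shape.
#' @return Weight sinogram `w >= 0`.
#' @export
apply_weight_modification <- function(variances, m) {
  if (!all(dim(variances) == dim(m))) stop("shape mismatch")
  if (any(variances < 0, na.rm = TRUE)) stop("negative variance")
  w <- m / variances
  w[!is.finite(variances)] <- 0
  w
}

#' Build the full bone prior from an absorption reconstruction
#'
#' Runs the mask pipeline: threshold segmentation of dense material,
#' complement soft mask, boundary gradient magnitude, forward projection,
#' normalization and inversion into the weight modification m.
#'
#' @param absorption a `pcct_volume` with quantity `"mu"`.
#' @param geometry a [projection_geometry()].
#' @param threshold see [segment_dense()].
#' @param clip see [make_weight_modification()].
#' @return Object of class `pcct_prior` with `bone_mask`, `soft_mask`
#'   (exact complement), `weight_modification`, `threshold_used`.
#' @export
bone_prior <- function(absorption, geometry, threshold = "auto",
                       clip = 0.99) {
  bone <- segment_dense(absorption, threshold)
  grad <- gradient_magnitude(bone)
  m <- make_weight_modification(grad, geometry, clip)
  structure(list(bone_mask = unname(bone) & TRUE,
                 soft_mask = !(unname(bone) & TRUE),
                 weight_modification = m,
                 threshold_used = attr(bone, "threshold"),
                 gradient = grad),
            class = "pcct_prior")
}

#' @export
print.pcct_prior <- function(x, ...) {
  cat("pcct bone prior:", sum(x$bone_mask), "dense voxels of",
      length(x$bone_mask),
      sprintf("(threshold %.4g);", x$threshold_used),
      sprintf("m in [%.3g, %.3g], %.1f%% of rays with m < 0.5\n",
              min(x$weight_modification), max(x$weight_modification),
              100 * mean(x$weight_modification < 0.5)))
  invisible(x)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; used to score threshold choices against a
#' ground-truth label map.
#'
#' @param a,b logical matrices of equal shape.
#' @return Scalar in `[0, 1]` (1 if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
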