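# Shared fixtures and independent oracles, all built in code.

# dense matrix of a linear operator, built column-by-column from impulses
dense_operator <- function(op, in_dim, out_len) {
  A <- matrix(0, out_len, prod(in_dim))
  for (k in seq_len(prod(in_dim))) {
    e <- array(0, dim = in_dim)
    e[k] <- 1
    A[, k] <- as.vector(op(e))
  }
  A
}

# independent Radon oracle: numerical line integration of the bilinearly
# interpolated image, sampled finely along each ray
fine_radon <- function(image, geometry, step = 0.02) {
  nx <- nrow(image); ny <- ncol(image)
  px <- geometry$pixel_size
  half <- sqrt((nx * px)^2 + (ny * px)^2) / 2 + 2 * px
  svals <- seq(-half, half, by = step * px)
  interp <- function(x, y) {
    fx <- x / px + nx / 2 + 0.5
    fy <- y / px + ny / 2 + 0.5
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    val <- numeric(length(x))
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
      wgt <- (if (di == 0) 1 - wx else wx) * (if (dj == 0) 1 - wy else wy)
      idx <- (jj[ok] - 1) * nx + ii[ok]
      val[ok] <- val[ok] + wgt[ok] * image[idx]
    }
    val
  }
  sino <- matrix(0, geometry$n_angles, geometry$n_det)
  tvals <- (seq_len(geometry$n_det) - 0.5 - geometry$n_det / 2) *
    geometry$det_spacing
  for (a in seq_len(geometry$n_angles)) {
    cb <- cos(geometry$angles[a]); sb <- sin(geometry$angles[a])
    for (d in seq_len(geometry$n_det)) {
      x <- tvals[d] * cb - svals * sb
      y <- tvals[d] * sb + svals * cb
      sino[a, d] <- sum(interp(x, y)) * step * px
    }
  }
  sino
}

# centered Gaussian blob image (effectively band-limited test object)
gaussian_blob <- function(n, sigma = n / 8, amplitude = 1) {
  xc <- seq_len(n) - 0.5 - n / 2
  amplitude * exp(-outer(xc^2, xc^2, "+") / (2 * sigma^2))
}

# small noiseless stepping-curve generator
stepping_curve <- function(a0, a1, phi, n_steps = 4, period = 1) {
  x <- (seq_len(n_steps) - 1) * period / n_steps
  list(I = a0 + a1 * cos(2 * pi * x / period + phi), x = x, period = period)
}

# direct scalar-loop objective oracle (independent of the vectorized code)
objective_loop_oracle <- function(rho, s, w, geometry, control, bone, ra) {
  M <- diff_detector(forward_project(rho, geometry), geometry)
  val <- sum(w * (s - M)^2)
  hub <- function(d, t) if (abs(d) <= t) d^2 / 2 else t * abs(d) - t^2 / 2
  nx <- nrow(rho); ny <- ncol(rho)
  qsum <- 0; hsum <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny))
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      i2 <- i + dd[1]; j2 <- j + dd[2]
      if (i2 >= 1 && i2 <= nx && j2 >= 1 && j2 <= ny) {
        qsum <- qsum + (rho[i, j] - rho[i2, j2])^2
        if (!bone[i, j])
          hsum <- hsum + hub(rho[i, j] - rho[i2, j2],
                             control$huber_threshold)
      }
    }
  bsum <- sum((rho[bone] - control$bone_coupling * ra[bone])^2)
  val + control$lambda_q * qsum + control$lambda_h * hsum +
    control$lambda_b * bsum
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) /
              max(abs(expected), .Machine$double.eps), tol)
}

# shared small SIR problem with all regularizers active
sir_fixture <- function(n = 6, na = 8, seed = 7) {
  set.seed(seed)
  g <- projection_geometry(n, n_angles = na)
  rho <- matrix(rnorm(n * n), n, n)
  s <- matrix(rnorm(na * g$n_det), na, g$n_det)
  w <- matrix(runif(na * g$n_det), na, g$n_det)
  bone <- matrix(FALSE, n, n); bone[2:3, 4:5] <- TRUE
  prior <- structure(list(bone_mask = bone, soft_mask = !bone,
                          weight_modification = w * 0 + 1),
                     class = "pcct_prior")
  ra <- pcct_volume(matrix(runif(n * n), n, n), quantity = "rho")
  ctl <- sir_control(lambda_q = 0.7, lambda_h = 1.3, huber_threshold = 0.5,
                     lambda_b = 2.1, bone_coupling = 1.7)
  list(g = g, rho = rho, s = s, w = w, bone = bone, prior = prior,
       ra = ra, ctl = ctl)
}
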