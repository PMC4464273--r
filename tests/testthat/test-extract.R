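test_that("noiseless cosine curves are recovered exactly", {
  sc <- stepping_curve(100, 50, 0.7)
  f <- fit_stepping_curve(sc$I, sc$x, sc$period)
  expect_true(f$valid)
  expect_lt(abs(f$a0 - 100), 1e-9)
  expect_lt(abs(f$a1 - 50), 1e-9)
  expect_lt(abs(f$phi1 - 0.7), 1e-9)
  # other step counts and phases
  for (phi in c(-2.9, -0.4, 1.1, 3.0)) {
    sc <- stepping_curve(2000, 240, phi, n_steps = 7, period = 2.4)
    f <- fit_stepping_curve(sc$I, sc$x, sc$period)
    expect_lt(abs(wrap_phase(f$phi1 - phi)), 1e-9)
  }
  expect_error(fit_stepping_curve(c(1, 2), c(0, 0.5), 1), "3 phase steps")
})

test_that("degenerate curves are flagged invalid with infinite variance", {
  f <- fit_stepping_curve(rep(80, 4), (0:3) / 4, 1)
  expect_false(f$valid)
  expect_identical(f$cov[3, 3], Inf)
  expect_true(is.na(f$phi1))
})

test_that("weighted fit agrees with a brute-force grid-search oracle", {
  sc <- stepping_curve(120, 30, -1.1, n_steps = 5)
  f <- fit_stepping_curve(sc$I, sc$x, sc$period)
  # oracle: profile the weighted RSS over phi (linear solve for a0, a1 at
  # each phi), coarse-to-fine down to 1e-5 resolution
  w <- 1 / pmax(sc$I, 1)
  rss_at <- function(phi) {
    X <- cbind(1, cos(2 * pi * sc$x / sc$period + phi))
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * sc$I))
    sum(w * (sc$I - X %*% beta)^2)
  }
  # the 2-parameter solve admits a negative amplitude at phi +/- pi;
  # canonicalize the oracle's solution to a1 >= 0 before comparing
  canonical <- function(phi) {
    X <- cbind(1, cos(2 * pi * sc$x / sc$period + phi))
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * sc$I))
    if (beta[2] < 0) wrap_phase(phi + pi) else wrap_phase(phi)
  }
  grid <- seq(-pi, pi, by = 1e-3)
  best <- grid[which.min(vapply(grid, rss_at, 0))]
  fine <- seq(best - 2e-3, best + 2e-3, by = 1e-5)
  best <- canonical(fine[which.min(vapply(fine, rss_at, 0))])
  expect_lt(abs(wrap_phase(f$phi1 - best)), 2e-5)
})

test_that("delta-method phase variance matches Monte-Carlo and scales as 1/(a0 V^2)", {
  set.seed(42)
  nrep <- 2000; a0 <- 1e4; V <- 0.3
  x <- (0:3) / 4
  mu <- a0 * (1 + V * cos(2 * pi * x + 0.4))
  I <- matrix(rpois(nrep * 4, rep(mu, each = nrep)), nrep, 4)
  f <- pcct:::.fit_frames(I, x, 1)
  expect_lt(abs(var(f$phi1) / mean(f$var_phi1) - 1), 0.1)
  # doubling the counts halves the phase variance (Monte-Carlo)
  I2 <- matrix(rpois(nrep * 4, rep(2 * mu, each = nrep)), nrep, 4)
  f2 <- pcct:::.fit_frames(I2, x, 1)
  expect_lt(abs(var(f$phi1) / var(f2$phi1) - 2), 0.2 * 2)
  # monotonicity of the predicted variance on a noiseless curve family
  preds <- sapply(c(4000, 2000, 1000, 500), function(cnt) {
    sc <- stepping_curve(cnt, 0.3 * cnt, 0.9)
    fit_stepping_curve(sc$I, sc$x, sc$period)$cov[3, 3]
  })
  expect_true(all(diff(preds) > 0))
})

test_that("signal extraction reproduces identity and ratio cases", {
  sc <- stepping_curve(400, 120, 0.3)
  mk_scan <- function(scale_a0 = 1, scale_a1 = 1, dphi = 0) {
    arr <- array(0, dim = c(2, 4, 3))
    for (j in 1:4)
      arr[, j, ] <- scale_a0 * 400 + scale_a1 * 120 *
        cos(2 * pi * sc$x[j] + 0.3 + dphi)
    structure(list(intensities = arr, step_positions = sc$x,
                   grating_period = 1, geometry = NULL),
              class = "pcct_scan")
  }
  ref <- fit_scan(mk_scan())
  same <- extract_signals(fit_scan(mk_scan()), ref)
  expect_lt(max(abs(same$transmission - 1)), 1e-10)
  expect_lt(max(abs(same$dphase)), 1e-10)
  expect_lt(max(abs(same$darkfield - 1)), 1e-10)
  half <- extract_signals(fit_scan(mk_scan(0.5, 0.5)), ref)
  expect_lt(max(abs(half$transmission - 0.5)), 1e-10)
  expect_lt(max(abs(half$darkfield - 1)), 1e-10)
  shifted <- extract_signals(fit_scan(mk_scan(dphi = 0.25)), ref)
  expect_lt(max(abs(shifted$dphase - 0.25)), 1e-9)
})

test_that("invalid reference pixels yield zero-weight (infinite-variance) signals", {
  arr <- array(50, dim = c(1, 4, 2))     # constant: no fringe
  flat <- structure(list(intensities = arr, step_positions = (0:3) / 4,
                         grating_period = 1, geometry = NULL),
                    class = "pcct_scan")
  sc <- stepping_curve(50, 20, 0)
  arr2 <- array(0, dim = c(1, 4, 2))
  for (j in 1:4) arr2[, j, ] <- sc$I[j]
  good <- structure(list(intensities = arr2, step_positions = sc$x,
                         grating_period = 1, geometry = NULL),
                    class = "pcct_scan")
  sig <- extract_signals(fit_scan(good), fit_scan(flat))
  expect_true(all(!sig$valid))
  expect_true(all(is.infinite(sig$var_dphase)))
})

test_that("PSF deconvolution inverts a matched Gaussian blur", {
  expect_identical(deconvolve_psf(diag(8), 0), diag(8))
  expect_error(deconvolve_psf(diag(8), 1, floor = 0), "positive")
  img <- matrix(0, 32, 32); img[16, 16] <- 1
  blurred <- blur_psf(img, 1.5)
  sharp <- deconvolve_psf(blurred, 1.5, floor = 1e-6)
  expect_gt(max(sharp), max(blurred))
  set.seed(8)
  rnd <- matrix(runif(32 * 32), 32, 32)
  rb <- blur_psf(rnd, 1)
  rd <- deconvolve_psf(rb, 1, floor = 1e-3)
  err_blur <- sqrt(mean((rb - rnd)^2))
  err_deconv <- sqrt(mean((rd - rnd)^2))
  expect_lt(err_deconv, err_blur)
})
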