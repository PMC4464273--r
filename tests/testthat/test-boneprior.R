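test_that("threshold segmentation separates two-level phantoms exactly", {
  ph <- default_phantom(48)
  vol <- pcct_volume(ph$mu_map, quantity = "mu")
  mask <- segment_dense(vol, threshold = 0.15)
  attr(mask, "threshold") <- NULL
  expect_identical(mask, ph$label_map == 3)
  low <- pcct_volume(matrix(0.01, 8, 8), quantity = "mu")
  expect_identical(sum(segment_dense(low, threshold = 0.5)), 0L)
  expect_warning(segment_dense(low, threshold = 0), "background")
  expect_error(segment_dense(pcct_volume(matrix(0, 8, 8),
                                         quantity = "rho")), "absorption")
})

test_that("automatic threshold maximizes Dice against ground-truth labels", {
  ph <- default_phantom(64)
  cfg <- acquisition_config(n_angles = 96, seed = 4)
  sc <- simulate_stepping_scan(ph, cfg)
  sig <- extract_signals(sc$sample, sc$reference)
  mu <- fbp_absorption(-log(pmax(sig$transmission, 1e-6)), sig$geometry)
  truth <- ph$label_map == 3
  sweep <- sapply(c(0.03, 0.09, 0.15, 0.21, 0.27), function(t)
    dice_coefficient(segment_dense(mu, t), truth))
  # the best threshold is interior, not at either end of the sweep
  expect_gt(max(sweep), sweep[1])
  expect_gt(max(sweep), sweep[5])
  auto <- segment_dense(mu, "auto")
  expect_gt(dice_coefficient(auto, truth), 0.8)
})

test_that("gradient magnitude matches the stencil and a per-voxel oracle", {
  expect_true(all(gradient_magnitude(matrix(1, 6, 6)) == 0))
  step <- matrix(0, 8, 8); step[5:8, ] <- 1
  gm <- gradient_magnitude(step)
  expect_true(all(gm[c(4, 5), ] == 0.5))
  expect_true(all(gm[c(1, 2, 3, 6, 7, 8), ] == 0))
  set.seed(10)
  m <- matrix(runif(80) > 0.6, 8, 10)
  gm <- gradient_magnitude(m)
  v <- m + 0
  oracle <- matrix(0, 8, 10)
  for (i in 1:8) for (j in 1:10) {
    gx <- if (i == 1) v[2, j] - v[1, j]
          else if (i == 8) v[8, j] - v[7, j]
          else (v[i + 1, j] - v[i - 1, j]) / 2
    gy <- if (j == 1) v[i, 2] - v[i, 1]
          else if (j == 10) v[i, 10] - v[i, 9]
          else (v[i, j + 1] - v[i, j - 1]) / 2
    oracle[i, j] <- sqrt(gx^2 + gy^2)
  }
  expect_lt(max(abs(gm - oracle)), 1e-12)
})

test_that("weight modification is normalized, inverted and scale-invariant", {
  g <- projection_geometry(16, n_angles = 10)
  m0 <- make_weight_modification(matrix(0, 16, 16), g)
  expect_true(all(m0 == 1))
  hot <- matrix(0, 16, 16); hot[6, 11] <- 3
  m1 <- make_weight_modification(hot, g)
  expect_true(all(m1 >= 0 & m1 <= 1))
  expect_identical(min(m1), 0)
  expect_equal(m1, make_weight_modification(100 * hot, g),
               tolerance = 1e-12)
})

test_that("rays grazing a bone rim receive smaller m than rays missing it", {
  n <- 48
  ph <- make_phantom(n, list(ellipse_spec(c(6, -4), 8, "bone")))
  g <- projection_geometry(n, n_angles = 24)
  grad <- gradient_magnitude(ph$label_map == 3)
  m <- make_weight_modification(grad, g)
  tt <- (seq_len(g$n_det) - 0.5 - g$n_det / 2) * g$det_spacing
  tangent <- miss <- matrix(FALSE, g$n_angles, g$n_det)
  for (a in seq_len(g$n_angles)) {
    tc <- 6 * cos(g$angles[a]) - 4 * sin(g$angles[a])
    dist <- abs(tt - tc)
    tangent[a, ] <- dist >= 7 & dist <= 8.5
    miss[a, ] <- dist > 11
  }
  expect_lt(max(m[tangent]), min(m[miss]))
})

test_that("weights are the modification over the variance, exactly", {
  set.seed(12)
  sig2 <- matrix(runif(60, 0.2, 5), 6, 10)
  m <- matrix(runif(60), 6, 10)
  w <- apply_weight_modification(sig2, m)
  expect_lt(max(abs(w * sig2 - m)), 1e-15)
  sig2[2, 3] <- Inf
  w <- apply_weight_modification(sig2, m)
  expect_identical(w[2, 3], 0)
  m[4, 4] <- 0
  expect_identical(apply_weight_modification(sig2, m)[4, 4], 0)
  expect_true(all(apply_weight_modification(sig2, m) >= 0))
  expect_error(apply_weight_modification(-sig2, m), "negative")
  expect_error(apply_weight_modification(sig2[, 1:3], m), "mismatch")
})

test_that("bone and soft masks partition the volume and m stays usable", {
  ph <- default_phantom(64)
  cfg <- acquisition_config(n_angles = 96, seed = 4)
  sc <- simulate_stepping_scan(ph, cfg)
  sig <- extract_signals(sc$sample, sc$reference)
  mu <- fbp_absorption(-log(pmax(sig$transmission, 1e-6)), sig$geometry)
  pr <- bone_prior(mu, sig$geometry)
  expect_true(all(xor(pr$bone_mask, pr$soft_mask)))
  expect_true(all(pr$weight_modification >= 0 &
                    pr$weight_modification <= 1))
  # the prior must not blank the data
  expect_lt(mean(pr$weight_modification < 0.5), 0.2)
})
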