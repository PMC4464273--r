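test_that("an empty phantom produces sample identical to reference", {
  ph <- make_phantom(16, list())
  cfg <- acquisition_config(n_angles = 8, seed = 1)
  sc <- simulate_stepping_scan(ph, cfg, noise = FALSE)
  expect_equal(sc$sample$intensities, sc$reference$intensities,
               tolerance = 1e-12)
})

test_that("pure-absorption transmission equals the independent Radon oracle", {
  ph <- make_phantom(24, list(ellipse_spec(c(0, 0), 7, "water")))
  ph$delta_map[] <- 0; ph$epsilon_map[] <- 0
  cfg <- acquisition_config(n_angles = 6, seed = 1)
  sc <- simulate_stepping_scan(ph, cfg, noise = FALSE)
  g <- sc$sample$geometry
  ratio <- sc$sample$intensities[, 1, ] / sc$reference$intensities[, 1, ]
  oracle <- exp(-fine_radon(ph$mu_map, g, step = 0.02))
  expect_lt(max(abs(ratio - oracle)), 0.02 * max(1 - min(oracle), 0.01))
})

test_that("noiseless extraction recovers the simulated signals to 1e-10", {
  ph <- default_phantom(32)
  cfg <- acquisition_config(n_angles = 16, seed = 2)
  sc <- simulate_stepping_scan(ph, cfg, noise = FALSE)
  sig <- extract_signals(sc$sample, sc$reference)
  tr <- sc$sample$truth
  expect_lt(max(abs(sig$transmission - tr$transmission)), 1e-10)
  expect_lt(max(abs(sig$darkfield - tr$darkfield)), 1e-10)
  expect_lt(max(abs(wrap_phase(sig$dphase - tr$dphase))), 1e-10)
})

test_that("fringe shifts beyond pi alias by exactly 2 pi", {
  ph <- default_phantom(48)
  cfg0 <- acquisition_config(n_angles = 12, seed = 3)
  free <- simulate_stepping_scan(ph, cfg0, noise = FALSE, wrap = FALSE)
  peak <- max(abs(free$sample$truth$dphase))
  expect_gt(peak, pi)   # the default study is in the wrapping regime
  # rescale the fringe constant so the peak shift is exactly 1.5 pi
  cfg <- acquisition_config(n_angles = 12, seed = 3,
                            fringe_scale = cfg0$fringe_scale * 1.5 * pi / peak)
  wrapped <- simulate_stepping_scan(ph, cfg, noise = FALSE, wrap = TRUE)
  unwrapped <- simulate_stepping_scan(ph, cfg, noise = FALSE,
                                      wrap = FALSE)$sample$truth$dphase
  k <- which.max(abs(unwrapped))
  expect_equal(abs(unwrapped[k]), 1.5 * pi, tolerance = 1e-6)
  # the simulated (and hence extracted) shift at that ray is the 2 pi alias
  expect_equal(wrapped$sample$truth$dphase[k],
               sign(unwrapped[k]) * (1.5 * pi - 2 * pi), tolerance = 1e-6)
  sig_w <- extract_signals(wrapped$sample, wrapped$reference)
  expect_equal(sig_w$dphase[k],
               sign(unwrapped[k]) * (1.5 * pi - 2 * pi), tolerance = 1e-6)
  # every |shift| > pi ray aliases by exactly a nonzero multiple of 2 pi
  over <- abs(unwrapped) > pi + 1e-6
  shift <- (unwrapped - wrapped$sample$truth$dphase)[over] / (2 * pi)
  expect_lt(max(abs(shift - round(shift))), 1e-9)
  expect_true(all(round(shift) != 0))
})

test_that("the seed fully determines a noisy scan", {
  ph <- default_phantom(16)
  cfg <- acquisition_config(n_angles = 5, seed = 7)
  s1 <- simulate_stepping_scan(ph, cfg)
  s2 <- simulate_stepping_scan(ph, cfg)
  expect_identical(s1$sample$intensities, s2$sample$intensities)
  cfg2 <- acquisition_config(n_angles = 5, seed = 8)
  s3 <- simulate_stepping_scan(ph, cfg2)
  expect_false(identical(s1$sample$intensities, s3$sample$intensities))
  reps <- simulate(ph, nsim = 2, seed = 7, config = cfg)
  expect_identical(reps[[1]]$sample$intensities, s1$sample$intensities)
})

test_that("halving the photon count doubles the extracted phase variance", {
  ph <- make_phantom(8, list())
  extract_phis <- function(count, nrep) {
    phis <- numeric(nrep)
    for (r in seq_len(nrep)) {
      cfg <- acquisition_config(n_angles = 1, photon_count = count,
                                seed = 1000 + r)
      sc <- simulate_stepping_scan(ph, cfg)
      sig <- suppressWarnings(extract_signals(sc$sample, sc$reference))
      phis[r] <- sig$dphase[1, 5]
    }
    phis
  }
  v_full <- var(extract_phis(4000, 500))
  v_half <- var(extract_phis(2000, 500))
  expect_lt(abs(v_half / v_full - 2), 0.6)
})

test_that("invalid acquisition parameters are rejected", {
  expect_error(acquisition_config(n_steps = 2), "at least 3")
  expect_error(acquisition_config(photon_count = 0), "positive")
  expect_error(acquisition_config(visibility = 0), "\\(0, 1\\]")
  expect_error(acquisition_config(visibility = 1.2), "\\(0, 1\\]")
})
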