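test_that("Huber potential is piecewise correct, continuous, with matching derivative", {
  expect_identical(huber_potential(0, 1), 0)
  expect_identical(huber_potential(1, 1), 0.5)
  expect_identical(huber_potential(2, 1), 1.5)
  expect_error(huber_potential(1, 0), "positive")
  set.seed(13)
  for (k in 1:100) {
    d <- runif(1, -4, 4); t <- runif(1, 0.1, 2)
    h <- 1e-6
    fd <- (huber_potential(d + h, t) - huber_potential(d - h, t)) / (2 * h)
    expect_lt(abs(fd - huber_derivative(d, t)), 1e-6)
  }
  # continuity across the knee
  eps <- 1e-12
  expect_lt(abs(huber_potential(1 + eps, 1) - huber_potential(1 - eps, 1)),
            1e-10)
})

test_that("objective equals an explicit scalar-loop oracle", {
  f <- sir_fixture()
  obj <- sir_objective(f$rho, f$s, f$w, f$g, f$ctl, f$prior, f$ra)
  oracle <- objective_loop_oracle(f$rho, f$s, f$w, f$g, f$ctl, f$bone,
                                  f$ra$values)
  expect_lt(abs(obj - oracle) / abs(oracle), 1e-10)
})

test_that("objective vanishes in its structural zero cases", {
  n <- 8
  g <- projection_geometry(n, n_angles = 6)
  truth <- gaussian_blob(n, 2)
  s <- diff_detector(forward_project(truth, g), g)
  w <- matrix(1, g$n_angles, g$n_det)
  ctl0 <- sir_control(lambda_q = 0, lambda_h = 0, lambda_b = 0)
  expect_lt(sir_objective(truth, s, w, g, ctl0), 1e-18)
  # rho = coupling * rho_a inside bone nulls the bone term
  f <- sir_fixture()
  rho2 <- f$rho
  rho2[f$bone] <- f$ctl$bone_coupling * f$ra$values[f$bone]
  ctl_b <- f$ctl; ctl_b$lambda_q <- 0; ctl_b$lambda_h <- 0
  ctl_d <- ctl_b; ctl_d$lambda_b <- 0
  expect_equal(sir_objective(rho2, f$s, f$w, f$g, ctl_b, f$prior, f$ra),
               sir_objective(rho2, f$s, f$w, f$g, ctl_d, f$prior, f$ra),
               tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  f <- sir_fixture()
  gr <- sir_gradient(f$rho, f$s, f$w, f$g, f$ctl, f$prior, f$ra)
  set.seed(14)
  for (k in 1:20) {
    i <- sample(6, 1); j <- sample(6, 1); h <- 1e-6
    rp <- f$rho; rp[i, j] <- rp[i, j] + h
    rm <- f$rho; rm[i, j] <- rm[i, j] - h
    fd <- (sir_objective(rp, f$s, f$w, f$g, f$ctl, f$prior, f$ra) -
             sir_objective(rm, f$s, f$w, f$g, f$ctl, f$prior, f$ra)) /
      (2 * h)
    expect_lt(abs(fd - gr[i, j]) / max(abs(fd), 1), 1e-5)
  }
})

test_that("gradient reduces to the dense operator form without regularization", {
  n <- 6
  g <- projection_geometry(n, n_angles = 8)
  M <- dense_operator(function(e) diff_detector(forward_project(e, g), g),
                      c(n, n), g$n_angles * g$n_det)
  set.seed(15)
  rho <- matrix(rnorm(n * n), n, n)
  w <- matrix(1, g$n_angles, g$n_det)
  s <- matrix(0, g$n_angles, g$n_det)
  ctl0 <- sir_control(lambda_q = 0, lambda_h = 0, lambda_b = 0)
  gr <- sir_gradient(rho, s, w, g, ctl0)
  dense <- 2 * t(M) %*% (M %*% as.vector(rho))
  expect_lt(max(abs(as.vector(gr) - dense)), 1e-10)
})

test_that("gradient vanishes at the weighted least-squares solution", {
  n <- 6
  g <- projection_geometry(n, n_angles = 10)
  M <- dense_operator(function(e) diff_detector(forward_project(e, g), g),
                      c(n, n), g$n_angles * g$n_det)
  set.seed(16)
  w <- runif(g$n_angles * g$n_det, 0.5, 2)
  s <- rnorm(g$n_angles * g$n_det)
  L <- dense_operator(pcct:::.quad_grad, c(n, n), n * n)
  lam <- 0.3
  xstar <- solve(2 * t(M) %*% (w * M) + lam * L, 2 * t(M) %*% (w * s))
  ctl <- sir_control(lambda_q = lam, lambda_h = 0, lambda_b = 0)
  gr <- sir_gradient(matrix(xstar, n, n),
                     matrix(s, g$n_angles, g$n_det),
                     matrix(w, g$n_angles, g$n_det), g, ctl)
  expect_lt(sqrt(sum(gr^2)), 1e-8 * max(1, sqrt(sum(xstar^2))))
})

test_that("NCG reaches the direct normal-equations solution of quadratic problems", {
  n <- 8
  g <- projection_geometry(n, n_angles = 10)
  M <- dense_operator(function(e) diff_detector(forward_project(e, g), g),
                      c(n, n), g$n_angles * g$n_det)
  set.seed(17)
  w <- runif(g$n_angles * g$n_det, 0.5, 2)
  s <- rnorm(g$n_angles * g$n_det)
  lam <- 0.5
  L <- dense_operator(pcct:::.quad_grad, c(n, n), n * n)
  xstar <- solve(2 * t(M) %*% (w * M) + lam * L, 2 * t(M) %*% (w * s))
  ctl <- sir_control(lambda_q = lam, lambda_h = 0, lambda_b = 0,
                     max_iters = 500, gradient_tolerance = 1e-13)
  fit <- reconstruct_sir(matrix(s, g$n_angles, g$n_det),
                         matrix(w, g$n_angles, g$n_det), g, ctl)
  rel <- sqrt(sum((as.vector(coef(fit)) - xstar)^2)) / sqrt(sum(xstar^2))
  expect_lt(rel, 1e-6)
  expect_true(all(diff(fit$objective_trace) <=
                    1e-10 * pmax(abs(fit$objective_trace[-1]), 1)))
  # stationary start terminates immediately
  fit2 <- reconstruct_sir(matrix(s, g$n_angles, g$n_det),
                          matrix(w, g$n_angles, g$n_det), g, ctl,
                          init = matrix(xstar, n, n))
  expect_lte(fit2$iterations, 2L)
  expect_true(fit2$converged)
})

test_that("descent holds with all regularizers active", {
  f <- sir_fixture(n = 10, na = 12, seed = 18)
  ctl <- f$ctl; ctl$max_iters <- 40L
  fit <- reconstruct_sir(f$s, f$w, f$g, ctl, f$prior, f$ra)
  expect_true(all(diff(fit$objective_trace) <= 0))
  expect_true(all(is.finite(fit$objective_trace)))
  s2 <- summary(fit)
  expect_identical(s2$iterations, fit$iterations)
  # methods are consistent with the optimizer state
  expect_equal(fit$objective_trace[length(fit$objective_trace)],
               sir_objective(coef(fit), f$s, f$w, f$g, ctl, f$prior, f$ra),
               tolerance = 1e-10)
  expect_equal(residuals(fit), f$s - fitted(fit), tolerance = 1e-12)
})

test_that("SIR recovers a noiseless unwrapped phantom to below 1% RMSE", {
  n <- 48
  ph <- default_phantom(n)
  cfg <- acquisition_config(n_angles = 72, seed = 5,
                            fringe_scale = 2e5)  # mild shifts: no wrapping
  sc <- simulate_stepping_scan(ph, cfg, noise = FALSE)
  expect_lt(max(abs(sc$sample$truth$dphase_unwrapped)), pi)
  sig <- extract_signals(sc$sample, sc$reference)
  truth <- phantom_rho(ph, cfg)$values
  ctl <- sir_control(lambda_q = 1e-6, lambda_h = 0, lambda_b = 0,
                     max_iters = 400, gradient_tolerance = 1e-10)
  fit <- reconstruct_sir(sig$dphase, matrix(1, cfg$n_angles, sig$geometry$n_det),
                         sig$geometry, ctl)
  rmse <- sqrt(mean((coef(fit) - truth)^2))
  expect_lt(rmse / max(abs(truth)), 0.01)
})

test_that("IR is SIR with uniform weights and quadratic-only regularization", {
  f <- sir_fixture(n = 8, na = 10, seed = 19)
  ctl <- sir_control(lambda_q = 0.4, lambda_h = 5, lambda_b = 5,
                     bone_coupling = 1, max_iters = 30)
  ir <- reconstruct_ir(f$s, f$g, ctl)
  ctl2 <- ctl; ctl2$lambda_h <- 0; ctl2$lambda_b <- 0
  manual <- reconstruct_sir(f$s, matrix(1, f$g$n_angles, f$g$n_det), f$g,
                            ctl2)
  expect_identical(coef(ir), coef(manual))
  expect_identical(ir$objective_trace, manual$objective_trace)
  expect_true(all(diff(ir$objective_trace) <= 0))
})

test_that("IR round-trip error is comparable to the analytic baseline", {
  n <- 48
  ph <- default_phantom(n)
  cfg <- acquisition_config(n_angles = 72, seed = 5, fringe_scale = 2e5)
  sc <- simulate_stepping_scan(ph, cfg, noise = FALSE)
  sig <- extract_signals(sc$sample, sc$reference)
  truth <- phantom_rho(ph, cfg)$values
  fbp <- fbp_dpc(sig$dphase, sig$geometry)$values
  ctl <- sir_control(lambda_q = 1e-6, max_iters = 300,
                     gradient_tolerance = 1e-9)
  ir <- reconstruct_ir(sig$dphase, sig$geometry, ctl)
  rmse_ir <- sqrt(mean((coef(ir) - truth)^2))
  rmse_fbp <- sqrt(mean((fbp - truth)^2))
  expect_lt(rmse_ir, 2 * rmse_fbp)
})

test_that("stronger quadratic regularization strictly reduces roughness", {
  f <- sir_fixture(n = 10, na = 12, seed = 20)
  rough <- sapply(c(0.1, 1, 10), function(lam) {
    ctl <- sir_control(lambda_q = lam, lambda_h = 0, lambda_b = 0,
                       max_iters = 200, gradient_tolerance = 1e-10)
    pcct:::.quad_roughness(coef(reconstruct_sir(f$s, f$w, f$g, ctl)))
  })
  expect_true(all(diff(rough) < 0))
})

test_that("control and input validation catch inconsistent problems", {
  expect_error(sir_control(lambda_q = -1), "non-negative")
  expect_error(sir_control(huber_threshold = 0), "positive")
  expect_error(sir_control(max_iters = 0), "at least 1")
  f <- sir_fixture()
  ctl <- f$ctl; ctl$bone_coupling <- NULL
  expect_error(reconstruct_sir(f$s, f$w, f$g, ctl, f$prior, f$ra),
               "bone_coupling")
  expect_error(reconstruct_sir(f$s, f$w, f$g, f$ctl, f$prior, NULL),
               "rho_a")
  expect_error(reconstruct_sir(f$s, -f$w, f$g, f$ctl, f$prior, f$ra),
               "non-negative")
})
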