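# Standard modelling-object methods for pcct_sir fits.

#' @export
print.pcct_sir <- function(x, ...) {
  ctl <- x$config_snapshot$control
  cat("Statistical iterative phase-contrast CT reconstruction\n")
  cat("  image:", paste(dim(x$rho$values), collapse = " x "),
      "pixels;", x$config_snapshot$geometry$n_angles, "views\n")
  cat(sprintf("  lambda_q = %g, lambda_h = %g (t = %g), lambda_b = %g\n",
              ctl$lambda_q, ctl$lambda_h, ctl$huber_threshold, ctl$lambda_b))
  cat(sprintf("  %d iterations, objective %.6g -> %.6g%s%s\n",
              x$iterations, x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)],
              if (x$converged) ", converged" else "",
              if (x$line_search_failed) ", line search stalled" else ""))
  invisible(x)
}

#' @export
summary.pcct_sir <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    iterations = object$iterations,
    converged = object$converged,
    line_search_failed = object$line_search_failed,
    objective_initial = object$objective_trace[1],
    objective_final = object$objective_trace[length(object$objective_trace)],
    grad_norm_final = object$grad_norm_trace[length(object$grad_norm_trace)],
    rho_range = range(object$rho$values),
    weighted_rss = sum(object$weights * res^2),
    n_zero_weight = sum(object$weights == 0),
    control = object$config_snapshot$control
  )
  class(out) <- "summary.pcct_sir"
  out
}

#' @export
print.summary.pcct_sir <- function(x, ...) {
  cat("SIR reconstruction summary\n")
  cat(sprintf("  iterations: %d (converged: %s)\n", x$iterations,
              x$converged))
  cat(sprintf("  objective: %.6g -> %.6g, final |grad| = %.3g\n",
              x$objective_initial, x$objective_final, x$grad_norm_final))
  cat(sprintf("  weighted RSS: %.6g, zero-weight rays: %d\n",
              x$weighted_rss, x$n_zero_weight))
  cat(sprintf("  rho in [%.4g, %.4g]\n", x$rho_range[1], x$rho_range[2]))
  invisible(x)
}

#' Extract the reconstructed image from a SIR fit
#'
#' @param object a `pcct_sir` fit.
#' @param ... unused.
#' @return The reconstructed image matrix (rho units).
#' @export
coef.pcct_sir <- function(object, ...) object$rho$values

#' Model predictions of a SIR fit
#'
#' @param object a `pcct_sir` fit.
#' @param type `"sinogram"` for the forward-modelled differential-phase
#'   sinogram `D A rho`, or `"delta"` for the reconstruction converted to
#'   refractive index decrement.
#' @param delta_water,calibration passed to [to_delta()] for
#'   `type = "delta"`.
#' @param ... unused.
#' @return Sinogram matrix or `pcct_volume`.
#' @export
predict.pcct_sir <- function(object, type = c("sinogram", "delta"),
                             delta_water = 4.567e-7, calibration = 1, ...) {
  type <- match.arg(type)
  geom <- object$config_snapshot$geometry
  if (type == "sinogram")
    diff_detector(forward_project(object$rho$values, geom), geom)
  else
    to_delta(object$rho, delta_water = delta_water,
             calibration = calibration)
}

#' @export
fitted.pcct_sir <- function(object, ...) predict(object, "sinogram")

#' Data residuals of a SIR fit
#'
#' @param object a `pcct_sir` fit.
#' @param weighted multiply residuals by `sqrt(w)` (whitened residuals).
#' @param ... unused.
#' @return Residual sinogram `s - D A rho`.
#' @export
residuals.pcct_sir <- function(object, weighted = FALSE, ...) {
  r <- object$data - fitted(object)
  if (weighted) r <- sqrt(object$weights) * r
  r
}

#' Plot a SIR fit
#'
#' Shows the reconstructed slice next to the objective convergence trace.
#'
#' @param x a `pcct_sir` fit.
#' @param ... passed to [plot.pcct_volume()].
#' @export
plot.pcct_sir <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(par(op))
  plot(x$rho, main = "SIR reconstruction", ...)
  plot(seq_along(x$objective_trace) - 1, x$objective_trace, type = "b",
       log = "y", xlab = "iteration", ylab = "objective",
       main = "convergence", pch = 20)
  invisible(x)
}
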