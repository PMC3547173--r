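# S3 methods for fitted cmc_dcm objects.

#' @export
print.cmc_dcm <- function(x, ...) {
  cat(sprintf("Canonical-microcircuit %s DCM\n", x$model$variant))
  cat(sprintf("  %d frequency bins (%g-%g Hz), %d free log-scalings\n",
              length(x$model$freqs), min(x$model$freqs),
              max(x$model$freqs), length(x$mu)))
  cat(sprintf("  free energy F = %.3f (%d iterations, %s)\n", x$F,
              x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.cmc_dcm <- function(object, type = c("log_scaling", "parameter"), ...) {
  type <- match.arg(type)
  if (type == "log_scaling") return(object$mu)
  pack_parameters(object$model, object$mu)$theta
}

#' @export
summary.cmc_dcm <- function(object, ...) {
  sd <- sqrt(diag(object$C))
  tab <- data.frame(log_scaling = as.numeric(object$mu),
                    sd = sd,
                    ci_lo = object$mu - 1.645 * sd,
                    ci_hi = object$mu + 1.645 * sd,
                    value = pack_parameters(object$model,
                                            object$mu)$theta[names(object$mu)],
                    row.names = names(object$mu))
  out <- list(table = tab, F = object$F, lambda = object$lambda,
              variant = object$model$variant, converged = object$converged,
              iterations = object$iterations)
  class(out) <- "summary.cmc_dcm"
  out
}

#' @export
print.summary.cmc_dcm <- function(x, digits = 3, ...) {
  cat(sprintf("Canonical-microcircuit %s DCM: F = %.3f, lambda = %.3f (%s, %d it.)\n",
              x$variant, x$F, x$lambda,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  cat("Posterior log-scalings (90% credible intervals):\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
fitted.cmc_dcm <- function(object, ...) {
  sp <- pack_parameters(object$model, object$mu)
  predict_spectrum(object$model$freqs, sp$params, sp$field, sp$obs,
                   object$model$linearization)$power
}

#' Predicted spectrum of a fitted DCM
#'
#' @param object A `cmc_dcm` object.
#' @param freqs Frequencies at which to predict (Hz); default the fitted
#'   grid.
#' @param ... Unused.
#' @return A [spectral_data()] object.
#' @export
predict.cmc_dcm <- function(object, freqs = object$model$freqs, ...) {
  sp <- pack_parameters(object$model, object$mu)
  out <- predict_spectrum(freqs, sp$params, sp$field, sp$obs,
                          object$model$linearization)
  out$label <- sprintf("fitted (%s)", object$model$variant)
  out
}

#' @export
residuals.cmc_dcm <- function(object, ...) {
  y <- object$data$power
  f <- fitted(object)
  if (object$model$fit_log_power) log(y) - log(f) else y - f
}

#' @export
logLik.cmc_dcm <- function(object, ...) {
  # the free energy: a lower bound on the log evidence
  structure(object$F, df = length(object$mu) + 1, class = "logLik")
}

#' @export
plot.cmc_dcm <- function(x, ...) {
  f <- x$model$freqs
  graphics::plot(f, x$data$power, type = "p", pch = 1,
                 xlab = "frequency (Hz)", ylab = "power",
                 main = sprintf("%s model fit", x$model$variant), ...)
  graphics::lines(f, fitted(x), lwd = 2)
  graphics::legend("topleft", bty = "n", pch = c(1, NA), lwd = c(NA, 2),
                   legend = c("data", "fitted"))
  invisible(x)
}

#' Simulate spectra from a fitted DCM
#'
#' Draws observation noise around the fitted prediction with the
#' fitted residual standard deviation `exp(-lambda/2)`.
#'
#' @param object A `cmc_dcm` object.
#' @param nsim Number of spectra.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return List of [spectral_data()] objects.
#' @export
simulate.cmc_dcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sd <- exp(-object$lambda / 2)
  lapply(seq_len(nsim), function(i) {
    spectral_data(object$model$freqs,
                  pmax(0, mu + stats::rnorm(length(mu), 0, sd)),
                  label = sprintf("simulated %d", i))
  })
}
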