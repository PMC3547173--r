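# Variational-Laplace inversion of spectra under the field / mass model.

#' Default free parameters of the inversion
#'
#' Synaptic (`kappa_1`, `m_e`, all intrinsic amplitudes), spatial
#' (`upsilon`, the two kernel-decay groups `c_diag` and `c_off`) and
#' sigmoid (`r`, `eta`) parameters; the mass variant pins `upsilon`.
#'
#' @param variant `"field"` or `"mass"`.
#' @return Character vector of free parameter names.
#' @export
cmc_free_default <- function(variant = c("field", "mass")) {
  variant <- match.arg(variant)
  free <- c("kappa_1", "m_e", .pair_names, "upsilon",
            "c_diag", "c_off", "r", "eta")
  if (variant == "mass") free <- setdiff(free, "upsilon")
  free
}

#' Default prior variances of the free log-scalings
#'
#' Weakly-informative shrinkage: 1/8 for synaptic and amplitude
#' parameters, 1/16 for the spatial decays and conduction speed, and
#' 1/16 for the sigmoid parameters.
#'
#' @param free Character vector of free parameter names.
#' @return Named numeric vector of prior variances.
#' @export
cmc_prior_variances <- function(free = cmc_free_default()) {
  v <- ifelse(free %in% c("upsilon", "c_diag", "c_off", "r", "eta"),
              1 / 16, 1 / 8)
  stats::setNames(v, free)
}

#' Model specification for spectral inversion
#'
#' Bundles the prior-mean parameters, the variant (field or mass), the
#' frequency grid, the free parameters with their prior log-scaling
#' variances, the noise hyperprior and numerical options.  The mass
#' variant is the field model with conduction delays shrunk to zero:
#' `upsilon` is pinned at 0 (removed from the free set) and the
#' spatial-frequency grid is reduced to `{0}`.
#'
#' @param variant `"field"` or `"mass"`.
#' @param params,field,obs Prior-mean parameter objects.
#' @param freqs Frequency grid of the fit (Hz); default 30-80 Hz at
#'   1 Hz.
#' @param free Free parameter names (log-scalings); default
#'   [cmc_free_default()].
#' @param prior_var Named prior variances of the free log-scalings;
#'   default [cmc_prior_variances()].
#' @param hyper_mean,hyper_var Gaussian prior on the log noise
#'   precision `lambda` (residual covariance `exp(-lambda) I`).
#'   `hyper_mean = NA` (default) centres the prior at the precision of
#'   a 5% relative-error guess derived from the data at fit time.
#' @param linearization Sigmoid linearisation point (see
#'   [sensor_spectrum()]).
#' @param fit_log_power Fit log power instead of raw power.
#' @return An object of class `cmc_model`.
#' @export
cmc_model <- function(variant = c("field", "mass"),
                      params = cmc_params(), field = field_params(),
                      obs = obs_model(), freqs = 30:80,
                      free = NULL, prior_var = NULL,
                      hyper_mean = NA, hyper_var = 4,
                      linearization = c("origin", "fixed_point"),
                      fit_log_power = FALSE) {
  variant <- match.arg(variant)
  linearization <- match.arg(linearization)
  if (variant == "mass") {
    field$upsilon <- 0
    obs$n_k <- 0L
  }
  if (is.null(free)) free <- cmc_free_default(variant)
  if (variant == "mass" && "upsilon" %in% free)
    stop("the mass variant pins upsilon; remove it from 'free'")
  if (is.null(prior_var)) prior_var <- cmc_prior_variances(free)
  theta_bar <- flatten_theta(params, field, obs)
  bad <- setdiff(free, names(theta_bar))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  stopifnot(all(prior_var > 0), setequal(names(prior_var), free),
            hyper_var > 0)
  structure(list(variant = variant, params = params, field = field,
                 obs = obs, freqs = as.numeric(freqs),
                 free = free, prior_var = prior_var[free],
                 hyper_mean = hyper_mean, hyper_var = hyper_var,
                 linearization = linearization,
                 fit_log_power = fit_log_power,
                 theta_bar = theta_bar),
            class = "cmc_model")
}

#' @export
print.cmc_model <- function(x, ...) {
  cat(sprintf("Canonical-microcircuit %s model\n", x$variant))
  cat(sprintf("  %d free log-scaling parameters; %d frequency bins (%g-%g Hz)\n",
              length(x$free), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Apply log-scalings to the prior-mean parameters
#'
#' Multiplicative reparameterisation: each free parameter equals its
#' prior mean times `exp(vartheta)`.  Free parameters whose prior mean
#' is exactly 0 (e.g. `eta`) are offset additively instead, since a
#' multiplicative scaling could never move them.
#'
#' @param model A [cmc_model()] object.
#' @param vartheta Named numeric vector of log-scalings over (a subset
#'   of) `model$free`; unnamed vectors are taken in `model$free` order.
#' @return List with elements `params`, `field`, `obs`, `theta` (the
#'   full flat parameter vector).
#' @export
pack_parameters <- function(model, vartheta) {
  if (is.null(names(vartheta)) && length(vartheta) == length(model$free))
    names(vartheta) <- model$free
  bad <- setdiff(names(vartheta), names(model$theta_bar))
  if (length(bad)) stop("unknown parameter name(s): ",
                        paste(bad, collapse = ", "))
  th <- model$theta_bar
  for (nm in names(vartheta)) {
    th[nm] <- if (th[nm] == 0) vartheta[[nm]] else
      th[nm] * exp(vartheta[[nm]])
  }
  out <- split_theta(th, model$params, model$field, model$obs)
  out$theta <- th
  out
}

# prediction of the observed spectrum at log-scalings vt (vector over
# model$free); returns numeric power vector or NULL if unstable
model_prediction <- function(model, vt) {
  sp <- pack_parameters(model, vt)
  out <- tryCatch(
    predict_spectrum(model$freqs, sp$params, sp$field, sp$obs,
                     model$linearization)$power,
    error = function(e) NULL)
  if (!is.null(out) && model$fit_log_power) {
    if (any(out <= 0)) return(NULL)
    out <- log(out)
  }
  out
}

# KL divergence of N(mu, C) from N(0, diag(v0))
kl_gauss <- function(mu, C, v0) {
  p <- length(mu)
  ld0 <- sum(log(v0))
  ldC <- determinant(C, logarithm = TRUE)$modulus[1]
  0.5 * (sum(diag(C) / v0) + sum(mu^2 / v0) - p + ld0 - ldC)
}

#' Variational free energy of a spectral fit
#'
#' `F = accuracy - complexity` under the Laplace assumption:
#' the accuracy is the Gaussian log-likelihood of the spectral
#' residuals with diagonal covariance `exp(-lambda) I`; the complexity
#' is the KL divergence of `N(mu, C)` from the prior on the
#' log-scalings plus the KL divergence of the hyperparameter posterior
#' from its prior.
#'
#' @param data A [spectral_data()] object on the model's grid.
#' @param model A [cmc_model()] object.
#' @param mu Posterior mean log-scalings (named over `model$free`).
#' @param C Posterior covariance of the log-scalings.
#' @param lambda Posterior mean log noise precision.
#' @param lambda_var Posterior variance of `lambda` (default 0, i.e.
#'   point hyperparameter).
#' @param hyper_mean Prior mean of `lambda`; default from the model
#'   (resolved against the data if `NA`).
#' @return Numeric `F` in nats, with attribute `parts` giving the
#'   accuracy and the two complexity terms.
#' @export
free_energy <- function(data, model, mu, C, lambda, lambda_var = 0,
                        hyper_mean = NULL) {
  stopifnot(inherits(data, "spectral_data"))
  if (!isTRUE(all.equal(data$freqs, model$freqs)))
    stop("data frequency grid does not match the model grid")
  y <- if (model$fit_log_power) log(data$power) else data$power
  pred <- model_prediction(model, mu)
  if (is.null(pred) || any(!is.finite(pred))) {
    cond <- structure(
      class = c("cmcfield_instability", "error", "condition"),
      list(message = "non-finite prediction at the supplied log-scalings",
           call = sys.call(-1), mu = mu))
    stop(cond)
  }
  e <- y - pred
  n <- length(y)
  if (is.null(hyper_mean)) hyper_mean <- resolve_hyper_mean(model, y)
  accuracy <- -0.5 * n * log(2 * pi) + 0.5 * n * lambda -
    0.5 * exp(lambda) * sum(e^2)
  kl_theta <- kl_gauss(mu, C, model$prior_var)
  kl_lambda <- if (lambda_var > 0) {
    0.5 * (lambda_var / model$hyper_var +
             (lambda - hyper_mean)^2 / model$hyper_var - 1 +
             log(model$hyper_var / lambda_var))
  } else {
    0.5 * (lambda - hyper_mean)^2 / model$hyper_var
  }
  F <- accuracy - kl_theta - kl_lambda
  attr(F, "parts") <- c(accuracy = accuracy, kl_theta = kl_theta,
                        kl_lambda = kl_lambda)
  F
}

resolve_hyper_mean <- function(model, y) {
  if (!is.na(model$hyper_mean)) return(model$hyper_mean)
  # centre the log-precision prior at a 5% relative-error guess
  s <- 0.05 * mean(abs(y))
  if (s <= 0) s <- 1
  -2 * log(s)
}

#' Fitting control parameters
#'
#' @param max_iter Maximum Gauss-Newton iterations (default 128).
#' @param tol_F Convergence tolerance: the fit has converged after
#'   `tol_count` consecutive accepted steps with `dF < tol_F`.
#' @param tol_count See `tol_F`.
#' @param jacobian_step Central-difference step in log-scaling space.
#' @param lm_init,lm_up,lm_down Levenberg-Marquardt damping: initial
#'   value and the factors applied on rejection/acceptance.
#' @param max_reject Step rejections allowed per iteration before
#'   giving up.
#' @return List of control settings.
#' @export
cmc_control <- function(max_iter = 128L, tol_F = 1e-2, tol_count = 4L,
                        jacobian_step = 1e-3, lm_init = 1e-4,
                        lm_up = 8, lm_down = 0.5, max_reject = 8L) {
  list(max_iter = max_iter, tol_F = tol_F, tol_count = tol_count,
       jacobian_step = jacobian_step, lm_init = lm_init, lm_up = lm_up,
       lm_down = lm_down, max_reject = max_reject)
}

# central-difference Jacobian of the prediction wrt log-scalings
prediction_jacobian <- function(model, vt, step) {
  p <- length(vt)
  J <- NULL
  for (i in seq_len(p)) {
    d <- rep(0, p); d[i] <- step
    up <- model_prediction(model, vt + d)
    dn <- model_prediction(model, vt - d)
    if (is.null(up) || is.null(dn)) return(NULL)
    col <- (up - dn) / (2 * step)
    if (is.null(J)) J <- matrix(0, length(col), p)
    J[, i] <- col
  }
  J
}

# Newton updates of the log noise precision lambda given residuals and
# the current parameter covariance (expected sum of squares)
update_lambda <- function(lambda, ess, n, hyper_mean, hyper_var) {
  for (i in 1:16) {
    g <- n / 2 - 0.5 * exp(lambda) * ess - (lambda - hyper_mean) / hyper_var
    h <- -0.5 * exp(lambda) * ess - 1 / hyper_var
    d <- g / h
    lambda <- lambda - max(-4, min(4, d))
    if (abs(d) < 1e-8) break
  }
  vl <- -1 / h
  list(lambda = lambda, var = vl)
}

#' Fit a canonical-microcircuit model to a power spectrum
#'
#' Variational-Laplace inversion: Gauss-Newton / Levenberg-Marquardt
#' ascent on the free energy with numerical Jacobians of the predicted
#' spectrum with respect to the free log-scalings, and an inner Newton
#' update of the log noise precision.  Deterministic given the data and
#' settings.
#'
#' @param data A [spectral_data()] object (or a file readable by
#'   [read_spectrum()]).
#' @param variant `"field"` or `"mass"` (ignored when `model` is
#'   given).
#' @param model A [cmc_model()] specification; default
#'   `cmc_model(variant)` on the data's frequency grid.
#' @param control A [cmc_control()] list.
#' @return An object of class `cmc_dcm` with components `mu` (posterior
#'   mean log-scalings), `C` (posterior covariance), `lambda` and
#'   `lambda_var` (noise hyperparameter posterior), `F` (free energy),
#'   `trajectory` (accepted `F` per iteration), `converged`, plus the
#'   model, data and diagnostics.
#' @seealso [compare_models()], [posterior_correlations()],
#'   [free_energy()]
#' @examples
#' \donttest{
#' truth <- ground_truth(noise_sd = 0)
#' y <- simulate_spectrum(truth, freqs = seq(30, 80, 5))
#' fit <- cmc_dcm(y, model = cmc_model(freqs = seq(30, 80, 5)),
#'                control = cmc_control(max_iter = 8))
#' fit
#' }
#' @export
cmc_dcm <- function(data, variant = c("field", "mass"), model = NULL,
                    control = cmc_control()) {
  if (is.character(data)) data <- read_spectrum(data)
  stopifnot(inherits(data, "spectral_data"))
  variant <- match.arg(variant)
  if (is.null(model)) model <- cmc_model(variant, freqs = data$freqs)
  if (!isTRUE(all.equal(data$freqs, model$freqs)))
    stop("data frequency grid does not match the model grid")
  y <- if (model$fit_log_power) log(data$power) else data$power
  n <- length(y)
  p <- length(model$free)
  hyper_mean <- resolve_hyper_mean(model, y)
  prior_prec <- 1 / model$prior_var

  vt <- stats::setNames(rep(0, p), model$free)
  lambda <- hyper_mean
  lambda_var <- model$hyper_var
  pred <- model_prediction(model, vt)
  if (is.null(pred)) stop("model is unstable at the prior means")
  e <- y - pred
  Fcur <- -Inf
  C <- diag(model$prior_var, p)
  tau <- control$lm_init
  traj <- numeric(0)
  n_small <- 0L
  converged <- FALSE

  eval_F <- function(vt, C, lambda, lambda_var, e) {
    acc <- -0.5 * n * log(2 * pi) + 0.5 * n * lambda -
      0.5 * exp(lambda) * sum(e^2)
    acc - kl_gauss(vt, C, model$prior_var) -
      0.5 * (lambda_var / model$hyper_var +
               (lambda - hyper_mean)^2 / model$hyper_var - 1 +
               log(model$hyper_var / lambda_var))
  }

  for (iter in seq_len(control$max_iter)) {
    J <- prediction_jacobian(model, vt, control$jacobian_step)
    if (is.null(J)) break
    JJ <- crossprod(J)
    accepted <- FALSE
    for (trial in seq_len(control$max_reject)) {
      H <- exp(lambda) * JJ + diag(prior_prec, p) + diag(tau * diag(JJ) * exp(lambda) + tau, p)
      g <- exp(lambda) * crossprod(J, e) - prior_prec * vt
      dv <- tryCatch(solve(H, g), error = function(err) NULL)
      if (is.null(dv)) { tau <- tau * control$lm_up; next }
      vt2 <- vt + as.numeric(dv)
      names(vt2) <- model$free
      pred2 <- model_prediction(model, vt2)
      if (is.null(pred2)) { tau <- tau * control$lm_up; next }
      e2 <- y - pred2
      # curvature (without LM damping) for the posterior covariance
      H2 <- exp(lambda) * JJ + diag(prior_prec, p)
      C2 <- tryCatch(solve(H2), error = function(err) NULL)
      if (is.null(C2)) { tau <- tau * control$lm_up; next }
      C2 <- (C2 + t(C2)) / 2
      ess <- sum(e2^2) + sum(diag(JJ %*% C2))
      lu <- update_lambda(lambda, ess, n, hyper_mean, model$hyper_var)
      F2 <- eval_F(vt2, C2, lu$lambda, lu$var, e2)
      if (is.finite(F2) && F2 > Fcur) {
        dF <- F2 - Fcur
        vt <- vt2; e <- e2; C <- C2
        lambda <- lu$lambda; lambda_var <- lu$var
        Fcur <- F2
        tau <- max(tau * control$lm_down, 1e-8)
        accepted <- TRUE
        break
      }
      tau <- tau * control$lm_up
    }
    if (!accepted) {
      # ascent exhausted: no damped step improves F, so we are at a
      # local maximum within numerical resolution
      converged <- length(traj) > 0
      break
    }
    traj <- c(traj, Fcur)
    if (length(traj) >= 2 && (dF < control$tol_F)) {
      n_small <- n_small + 1L
      if (n_small >= control$tol_count) { converged <- TRUE; break }
    } else n_small <- 0L
  }

  structure(list(mu = vt, C = C, lambda = lambda, lambda_var = lambda_var,
                 F = as.numeric(Fcur), trajectory = traj,
                 converged = converged, model = model, data = data,
                 hyper_mean = hyper_mean, iterations = length(traj)),
            class = "cmc_dcm")
}

#' Posterior correlation matrix of a fit
#'
#' Normalises the posterior covariance to unit diagonal.
#'
#' @param fit A `cmc_dcm` object (or any list with elements `C` and,
#'   optionally, `mu` for labels).
#' @return Labelled symmetric correlation matrix with unit diagonal.
#' @export
posterior_correlations <- function(fit) {
  C <- fit$C
  d <- diag(C)
  if (any(d <= 0)) stop("zero or negative posterior variance on the diagonal")
  R <- stats::cov2cor(C)
  nm <- names(fit$mu)
  if (!is.null(nm)) dimnames(R) <- list(nm, nm)
  R
}

#' Compare field and mass fits by free energy
#'
#' Per-dataset relative log evidence `dF = F_field - F_mass`, the group
#' mean, and a strong-evidence flag at `|dF| >= 3` (inclusive).
#'
#' @param field_fits A `cmc_dcm` object or list of them (field
#'   variant).
#' @param mass_fits Matching `cmc_dcm` object(s) fitted to the same
#'   data.
#' @return An object of class `cmc_bmc`: a data.frame with columns
#'   `dataset`, `F_field`, `F_mass`, `dF`, `strong`, plus attribute
#'   `mean_dF`.
#' @export
compare_models <- function(field_fits, mass_fits) {
  if (inherits(field_fits, "cmc_dcm")) field_fits <- list(field_fits)
  if (inherits(mass_fits, "cmc_dcm")) mass_fits <- list(mass_fits)
  stopifnot(length(field_fits) == length(mass_fits))
  rows <- lapply(seq_along(field_fits), function(i) {
    ff <- field_fits[[i]]; mf <- mass_fits[[i]]
    if (!isTRUE(all.equal(ff$data$freqs, mf$data$freqs)) ||
        !isTRUE(all.equal(ff$data$power, mf$data$power)))
      stop("fit pair ", i, " was not computed on identical data")
    dF <- ff$F - mf$F
    data.frame(dataset = if (nzchar(ff$data$label)) ff$data$label else
                 as.character(i),
               F_field = ff$F, F_mass = mf$F, dF = dF,
               strong = abs(dF) >= 3)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_dF") <- mean(out$dF)
  class(out) <- c("cmc_bmc", "data.frame")
  out
}

#' @export
print.cmc_bmc <- function(x, ...) {
  cat("Field vs mass model comparison (dF = F_field - F_mass)\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("group mean dF = %.3f (|dF| >= 3 is strong evidence)\n",
              attr(x, "mean_dF")))
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' Writes the posterior (mu, C, lambda), the free energy, convergence
#' diagnostics, the model settings and a content hash of the settings.
#'
#' @param fit A `cmc_dcm` object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cmc_dcm"))
  settings <- list(variant = fit$model$variant, free = fit$model$free,
                   prior_var = as.list(fit$model$prior_var),
                   freqs = fit$model$freqs,
                   linearization = fit$model$linearization,
                   fit_log_power = fit$model$fit_log_power,
                   theta_bar = as.list(fit$model$theta_bar))
  tf <- tempfile()
  writeLines(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  obj <- list(mu = as.list(fit$mu), C = unclass(fit$C),
              lambda = fit$lambda, lambda_var = fit$lambda_var,
              F = fit$F, trajectory = fit$trajectory,
              converged = fit$converged, iterations = fit$iterations,
              settings = settings, settings_hash = hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
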