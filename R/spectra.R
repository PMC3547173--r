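# Field transfer function on the (k, omega) grid, lead field and the
# predicted single-channel spectrum.
#
# Two independent routes to the transfer function are kept side by side:
# the matrix route (direct inversion of the linearised system) and the
# closed-form route assembled from the scalar expressions R, S_a, Q_a,
# V_ab.  The closed form is fully vectorised over omega and is what the
# spectrum (and hence the fitter) uses; the matrix route is retained as
# an independent cross-check.

#' Field transfer function (matrix route)
#'
#' Direct evaluation of
#' `T(k, omega) = (-omega^2 I - 2 i omega B + B^2 - J(k, omega))^-1 G`
#' with `J = A B D(k, omega) Gamma` assembled from the signed kernel
#' transforms and the sigmoid gain.
#'
#' @param k Spatial angular frequency (rad/mm); scalar.
#' @param omega Temporal angular frequency (rad/ms); scalar.
#' @param params A [cmc_params()] object.
#' @param field A [field_params()] object.
#' @param gain Optional 4-vector of per-population gains (default:
#'   sigmoid gain at `v = 0`).
#' @return Complex 4-vector of transfer values, one per population.
#'   Signals `cmcfield_instability` if the system matrix is singular.
#' @export
transfer_matrix <- function(k, omega, params = cmc_params(),
                            field = field_params(),
                            gain = gain_vector(params)) {
  D <- kernel_transform_matrix(k, omega, params, field)
  B <- diag(params$kappa)
  A <- diag(pop_m(params))
  J <- A %*% B %*% D %*% diag(gain)
  M <- -omega^2 * diag(4) - 2i * omega * B + B %*% B - J
  G <- c(params$kappa[1] * params$m_e, 0, 0, 0)
  out <- tryCatch(solve(M, G), error = function(e) e)
  if (inherits(out, "error")) {
    cond <- structure(
      class = c("cmcfield_instability", "error", "condition"),
      list(message = sprintf("singular system at (k, omega) = (%g, %g)",
                             k, omega),
           call = sys.call(-1), k = k, omega = omega))
    stop(cond)
  }
  out
}

# closed-form route, vectorised over omega at fixed k.
# Returns a list of 4 complex vectors (T_a per omega).
closed_form_core <- function(k, omega, params, field, gain) {
  kap <- params$kappa
  m <- pop_m(params)
  u <- field$upsilon
  a <- params$a
  sgn <- params$sign
  cd <- field$c_diag; co <- field$c_off

  Di <- function(nm, to, from) {
    cab <- if (to == from) cd else co
    sgn[to, from] * intrinsic_ft(k, omega, a[[nm]], cab, u)
  }
  # diagonal transforms (intrinsic + extrinsic)
  Daa <- lapply(1:4, function(i) {
    Di(sprintf("a_%d%d", i, i), i, i) +
      extrinsic_ft(k, omega, cd, field$h[i], u)
  })
  D12 <- Di("a_12", 1, 2); D21 <- Di("a_21", 2, 1)
  D14 <- Di("a_14", 1, 4); D41 <- Di("a_41", 4, 1)
  D23 <- Di("a_23", 2, 3); D32 <- Di("a_32", 3, 2)

  Q <- lapply(1:4, function(i) {
    -kap[i]^2 + gain[i] * Daa[[i]] * kap[i] * m[i] +
      2i * kap[i] * omega + omega^2
  })
  V12 <- D12 * D21 * gain[1] * gain[2] * kap[1] * kap[2] * m[1] * m[2]
  V14 <- D14 * D41 * gain[1] * gain[4] * kap[1] * kap[4] * m[1] * m[4]
  V23 <- D23 * D32 * gain[2] * gain[3] * kap[2] * kap[3] * m[2] * m[3]

  W23 <- Q[[2]] * Q[[3]] - V23
  R <- -V14 * W23 + Q[[4]] * (-V23 * Q[[1]] + Q[[3]] * (Q[[1]] * Q[[2]] - V12))
  S1 <- -Q[[4]] * W23
  S2 <- D21 * gain[1] * kap[2] * m[2] * Q[[3]] * Q[[4]]
  S3 <- -D21 * D32 * gain[1] * gain[2] * kap[2] * kap[3] * m[2] * m[3] * Q[[4]]
  S4 <- D41 * gain[1] * kap[4] * m[4] * W23
  list(S = list(S1, S2, S3, S4), R = R)
}

#' Field transfer function (closed-form route)
#'
#' The same 4-vector as [transfer_matrix()], assembled from the scalar
#' expressions: per-population numerators `S_a(k, omega)` and the common
#' denominator `R(k, omega)` built from `Q_a` and `V_ab`, scaled by
#' `kappa_1 m_e`.  Vectorised over `omega`.
#'
#' @inheritParams transfer_matrix
#' @param omega Temporal angular frequencies (rad/ms); vectorised.
#' @return Complex matrix with `length(omega)` rows and 4 columns.
#'   Signals `cmcfield_instability` at a pole (`R` nearly zero).
#' @export
closed_form_sr <- function(k, omega, params = cmc_params(),
                           field = field_params(),
                           gain = gain_vector(params)) {
  cf <- closed_form_core(k, omega, params, field, gain)
  if (any(!is.finite(Mod(cf$R))) || any(Mod(cf$R) == 0)) {
    cond <- structure(
      class = c("cmcfield_instability", "error", "condition"),
      list(message = sprintf("pole of the transfer function at k = %g", k),
           call = sys.call(-1), k = k, omega = omega[which(Mod(cf$R) == 0)[1]]))
    stop(cond)
  }
  scale <- params$kappa[1] * params$m_e
  out <- vapply(cf$S, function(s) scale * s / cf$R,
                complex(length(omega)))
  matrix(out, nrow = length(omega), ncol = 4)
}

#' Gaussian lead-field coefficients
#'
#' Spatial Fourier coefficients of the Gaussian gain function over the
#' patch: `L(k, phi) = exp(-2 pi^2 phi_mm^2 k^2)` with `k` in cycles/mm
#' and `phi_mm = phi * L_patch` the dispersion in mm.
#'
#' @param phi Dispersion as a fraction of the patch length; positive.
#' @param k_cycles Spatial frequencies (cycles/mm); vectorised.
#' @param L_patch Patch length (mm).
#' @return Real weights, maximal (1) at `k = 0`, even in `k`.
#' @export
lead_field_coefficients <- function(phi, k_cycles, L_patch = 25) {
  stopifnot(phi > 0)
  phi_mm <- phi * L_patch
  exp(-2 * pi^2 * phi_mm^2 * k_cycles^2)
}

#' Discrete spatial-frequency grid of the patch
#'
#' Symmetric Fourier grid `k_n = n / L_patch` cycles/mm,
#' `n = -N .. N`.  When `obs$n_k` is `NULL`, `N` is the smallest order
#' at which the lead-field weight falls below 1e-6 (capped at 64).
#'
#' @param obs An [obs_model()] object.
#' @param field A [field_params()] object (for the patch length).
#' @return Numeric vector of spatial frequencies (cycles/mm) including 0.
#' @export
lead_k_grid <- function(obs = obs_model(), field = field_params()) {
  L <- field$L_patch
  N <- obs$n_k
  if (is.null(N)) {
    phi_mm <- obs$phi * L
    k_min <- sqrt(log(1e6) / (2 * pi^2 * phi_mm^2))
    N <- min(64L, as.integer(ceiling(k_min * L)))
  }
  seq(-N, N) / L
}

#' Input and channel-noise spectral curves
#'
#' White-plus-coloured curves `g_u` (input) and `g_n` (channel noise).
#' Under the default `"one_over_f"` colour law the curve is
#' `alpha + beta / f` with `f` in Hz; the `"linear"` option is the
#' literal linear-in-omega law `alpha + beta * omega` with `omega` in
#' rad/ms.
#'
#' @param freqs Temporal frequencies (Hz).
#' @param obs An [obs_model()] object carrying the coefficients and the
#'   colour law.
#' @return List with numeric vectors `g_u` and `g_n`.  Errors if either
#'   curve is negative anywhere on the grid.
#' @export
input_noise_spectra <- function(freqs, obs = obs_model()) {
  shape <- switch(obs$colour,
                  one_over_f = 1 / freqs,
                  linear = 2 * pi * freqs / 1000)
  g_u <- obs$alpha_u + obs$beta_u * shape
  g_n <- obs$alpha_n + obs$beta_n * shape
  if (any(g_u < 0) || any(g_n < 0))
    stop("input/noise spectral coefficients give a negative curve on the grid")
  list(g_u = g_u, g_n = g_n)
}

#' Predicted neural spectrum at the sensor
#'
#' The neural (source) component of the single-channel power spectrum:
#' `g(omega) = sum_k |L(k, phi)|^2 |q . T(k, omega)|^2 g_u(omega)`,
#' summed over the symmetric spatial-frequency grid of the patch.
#'
#' @param freqs Temporal frequencies (Hz).
#' @param params A [cmc_params()] object.
#' @param field A [field_params()] object.
#' @param obs An [obs_model()] object.
#' @param linearization Where the sigmoid is linearised: `"origin"`
#'   (`v = 0`, the default) or `"fixed_point"` (the homogeneous steady
#'   state).
#' @param k_grid Optional explicit spatial-frequency grid (cycles/mm);
#'   default from [lead_k_grid()].
#' @return A [spectral_data()] object (real, non-negative power).
#'   Signals `cmcfield_instability` (with location) if the transfer
#'   function has a pole on the grid.
#' @export
sensor_spectrum <- function(freqs, params = cmc_params(),
                            field = field_params(), obs = obs_model(),
                            linearization = c("origin", "fixed_point"),
                            k_grid = NULL) {
  linearization <- match.arg(linearization)
  gain <- gain_vector(params, total_connectivity(params, field),
                      linearization)
  if (is.null(k_grid)) k_grid <- lead_k_grid(obs, field)
  omega <- 2 * pi * freqs / 1000
  L2 <- lead_field_coefficients(obs$phi, k_grid, field$L_patch)^2
  g <- numeric(length(omega))
  for (i in seq_along(k_grid)) {
    Tk <- closed_form_sr(2 * pi * k_grid[i], omega, params, field, gain)
    g <- g + L2[i] * Mod(Tk %*% obs$q)^2
  }
  g <- as.numeric(g) * input_noise_spectra(freqs, obs)$g_u
  if (any(!is.finite(g))) {
    bad <- freqs[which(!is.finite(g))[1]]
    cond <- structure(
      class = c("cmcfield_instability", "error", "condition"),
      list(message = sprintf("non-finite spectrum at %g Hz", bad),
           call = sys.call(-1), freq = bad))
    stop(cond)
  }
  spectral_data(freqs, g, label = "predicted (neural)")
}

#' Predicted observed spectrum (neural plus channel noise)
#'
#' The noiseless expectation of the data: [sensor_spectrum()] plus the
#' channel-noise curve `g_n`.
#'
#' @inheritParams sensor_spectrum
#' @return A [spectral_data()] object.
#' @export
predict_spectrum <- function(freqs, params = cmc_params(),
                             field = field_params(), obs = obs_model(),
                             linearization = c("origin", "fixed_point"),
                             k_grid = NULL) {
  linearization <- match.arg(linearization)
  neural <- sensor_spectrum(freqs, params, field, obs, linearization, k_grid)
  g_n <- input_noise_spectra(freqs, obs)$g_n
  spectral_data(freqs, neural$power + g_n, label = "predicted")
}

#' Contribution analysis: spectra across a log-scaling sweep
#'
#' Recomputes the predicted spectrum with one named parameter scaled by
#' `exp(s)` for each `s` in `log_scalings` (parameters with baseline 0,
#' such as `eta`, are offset additively instead).
#'
#' @param parameter Name of a flat parameter key (see
#'   [flatten_theta()]), e.g. `"a_23"` or `"c_diag"`.
#' @param log_scalings Numeric vector of log-scalings; 0 reproduces the
#'   base prediction.
#' @inheritParams sensor_spectrum
#' @return Named list (one [spectral_data()] per scaling, names the
#'   scaling values), with the scalings as attribute `log_scalings`.
#' @export
contribution_sweep <- function(parameter, log_scalings,
                               params = cmc_params(),
                               field = field_params(), obs = obs_model(),
                               freqs = 30:80,
                               linearization = c("origin", "fixed_point")) {
  linearization <- match.arg(linearization)
  theta0 <- flatten_theta(params, field, obs)
  if (!parameter %in% names(theta0))
    stop("unknown parameter name: ", parameter)
  out <- lapply(log_scalings, function(s) {
    th <- theta0
    th[parameter] <- if (theta0[parameter] == 0) s else
      theta0[parameter] * exp(s)
    sp <- split_theta(th, params, field, obs)
    spec <- predict_spectrum(freqs, sp$params, sp$field, sp$obs,
                             linearization)
    spec$label <- sprintf("%s x exp(%g)", parameter, s)
    spec
  })
  names(out) <- as.character(log_scalings)
  attr(out, "log_scalings") <- log_scalings
  attr(out, "parameter") <- parameter
  out
}
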