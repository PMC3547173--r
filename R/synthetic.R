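# Synthetic-data generation: forward-model spectra with observation
# noise, linearised time-series simulation (the oracle for the analytic
# spectrum), gamma-peak extraction and correlated group datasets.

#' Ground truth for synthetic spectra
#'
#' Bundles a full parameter set, an observation model, the per-bin
#' observation-error scale and an RNG seed, so that every synthetic
#' dataset is reproducible from its generator settings.
#'
#' `noise_sd = NA` (the default) resolves, at simulation time, to 3% of
#' the mean in-band noiseless power — the relative error expected of a
#' spectral estimate averaged over roughly a thousand degrees of freedom
#' (e.g. 180 trials x 7 tapers), which we treat as moderate noise.
#'
#' @param params,field,obs Parameter objects (see [cmc_params()],
#'   [field_params()], [obs_model()]).
#' @param noise_sd Observation-error standard deviation per frequency
#'   bin (power units), or `NA` for the 3% default.
#' @param seed RNG seed (integer).
#' @param linearization Sigmoid linearisation point.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(params = cmc_params(), field = field_params(),
                         obs = obs_model(), noise_sd = NA,
                         seed = 1L,
                         linearization = c("origin", "fixed_point")) {
  linearization <- match.arg(linearization)
  stopifnot(is.na(noise_sd) || noise_sd >= 0)
  structure(list(params = params, field = field, obs = obs,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 linearization = linearization),
            class = "ground_truth")
}

resolve_noise_sd <- function(truth, clean) {
  if (!is.na(truth$noise_sd)) return(truth$noise_sd)
  0.03 * mean(clean)
}

#' Simulate an observed power spectrum
#'
#' The noiseless expectation ([predict_spectrum()]) plus seeded Gaussian
#' observation error per bin, floored at zero.  Identical seeds give
#' identical datasets.
#'
#' @param truth A [ground_truth()] object.
#' @param freqs Frequency grid (Hz); default 30-80 Hz at 1 Hz.
#' @param label Label for the returned spectrum.
#' @return A [spectral_data()] object.
#' @export
simulate_spectrum <- function(truth, freqs = 30:80, label = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  clean <- predict_spectrum(freqs, truth$params, truth$field, truth$obs,
                            truth$linearization)$power
  sd <- resolve_noise_sd(truth, clean)
  if (sd > 0) {
    rs <- local({ set.seed(truth$seed); stats::rnorm(length(clean), 0, sd) })
    clean <- pmax(0, clean + rs)
  }
  spectral_data(freqs, clean, label = label)
}

#' Simulate a linearised sensor time series
#'
#' Frequency-domain synthesis: seeded complex Gaussian weights are
#' shaped by the square root of the (k-summed, lead-field-weighted)
#' neural sensor spectrum, treated as a one-sided power spectral
#' density, and inverted to a real series.  The Welch spectrum of the
#' result converges to [sensor_spectrum()] with duration.
#'
#' @param truth A [ground_truth()] object.
#' @param duration Length of the series (s).
#' @param dt Sampling step (s); must resolve the band of interest
#'   (default 2.5 ms, Nyquist 200 Hz).
#' @param f_min Frequencies below this (Hz) carry no power (the model
#'   spectrum is evaluated from `f_min` up to Nyquist).
#' @return Numeric time series with attributes `dt` (s) and `fs` (Hz).
#' @export
simulate_timeseries <- function(truth, duration = 60, dt = 0.0025,
                                f_min = 1) {
  stopifnot(inherits(truth, "ground_truth"), duration > 0, dt > 0)
  n <- as.integer(round(duration / dt))
  if (n %% 2L == 1L) n <- n + 1L
  fs <- 1 / dt
  df <- fs / n
  j <- seq_len(n / 2 - 1)          # positive frequencies below Nyquist
  fj <- j * df
  psd <- numeric(length(fj))
  keep <- fj >= f_min & fj <= fs / 2
  if (any(keep)) {
    psd[keep] <- sensor_spectrum(fj[keep], truth$params, truth$field,
                                 truth$obs, truth$linearization)$power
  }
  if (all(psd == 0)) return(structure(numeric(n), dt = dt, fs = fs))
  set.seed(truth$seed)
  z <- complex(real = stats::rnorm(length(fj), 0, sqrt(0.5)),
               imaginary = stats::rnorm(length(fj), 0, sqrt(0.5)))
  # one-sided PSD (power per Hz) -> FFT coefficient variance
  X <- sqrt(psd * n * fs / 2) * z
  spec <- complex(length.out = n)
  spec[1 + j] <- X
  spec[1 + n - j] <- Conj(X)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  structure(x, dt = dt, fs = fs)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann taper (one-sided density,
#' power per Hz).  Defaults: 2 s segments, 50% overlap.
#'
#' @param x Real time series.
#' @param fs Sampling frequency (Hz).
#' @param seg_sec Segment length (s).
#' @param overlap Fractional overlap between segments.
#' @return List with `freqs` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_sec = 2, overlap = 0.5) {
  nseg <- as.integer(round(seg_sec * fs))
  stopifnot(nseg >= 8, length(x) >= nseg)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  norm <- sum(w^2) * fs
  nf <- nseg %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[2:(nf + 1)]
    acc <- acc + (Mod(X)^2) / norm
  }
  psd <- 2 * acc / length(starts)   # one-sided
  list(freqs = seq_len(nf) * fs / nseg, psd = psd)
}

#' Extract the gamma peak from a spectrum
#'
#' Least-squares Gaussian fit (`amplitude * exp(-(f - peak)^2 / 2 sd^2)
#' + offset`) to the percentage power change when a baseline spectrum
#' is given, or to raw power otherwise.
#'
#' @param spectrum A [spectral_data()] object covering the band of
#'   interest.
#' @param baseline Optional baseline [spectral_data()] on the same
#'   grid; when given the fit is to `100 * (spectrum - baseline) /
#'   baseline`.
#' @return List with `peak_hz`, `amplitude`, `bandwidth` (Gaussian SD,
#'   Hz).  Signals an error of class `cmcfield_no_peak` when the fit
#'   does not converge, the fitted peak sits at the grid boundary, or
#'   the fitted bump has no prominence.
#' @export
extract_gamma_peak <- function(spectrum, baseline = NULL) {
  stopifnot(inherits(spectrum, "spectral_data"))
  f <- spectrum$freqs
  y <- spectrum$power
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "spectral_data"))
    if (!isTRUE(all.equal(baseline$freqs, f)))
      stop("baseline must share the spectrum's frequency grid")
    y <- 100 * (y - baseline$power) / baseline$power
  }
  no_peak <- function(msg) {
    cond <- structure(class = c("cmcfield_no_peak", "error", "condition"),
                      list(message = msg, call = sys.call(-2)))
    stop(cond)
  }
  i0 <- which.max(y)
  start <- list(a = max(y) - min(y), mu = f[i0],
                s = diff(range(f)) / 6, b = min(y))
  if (start$a <= 0) no_peak("spectrum has no prominence above its minimum")
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(f - mu)^2 / (2 * s^2)) + b,
                      start = start,
                      lower = c(a = 0, mu = min(f), s = 1e-3, b = -Inf),
                      upper = c(a = Inf, mu = max(f), s = Inf, b = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) no_peak("Gaussian peak fit did not converge")
  cf <- stats::coef(fit)
  edge <- min(diff(f))
  if (cf[["mu"]] <= min(f) + edge / 2 || cf[["mu"]] >= max(f) - edge / 2)
    no_peak("fitted peak lies at the grid boundary")
  if (cf[["a"]] <= 2 * stats::sd(stats::resid(fit)))
    no_peak("fitted bump has no prominence above the residual noise")
  list(peak_hz = unname(cf[["mu"]]), amplitude = unname(cf[["a"]]),
       bandwidth = unname(cf[["s"]]))
}

#' Simulate a group dataset with a prescribed correlation structure
#'
#' Draws `n` multivariate-Gaussian subject rows (unit variances) with
#' the target correlation matrix, via its Cholesky factor; seeded and
#' bit-reproducible.
#'
#' @param target A [correlation_matrix()] object or plain symmetric
#'   positive-definite matrix with unit diagonal.
#' @param n Number of subjects (>= 4).
#' @param seed RNG seed.
#' @return Data frame with columns `subject` and one column per
#'   variable (default labels `v1_size`, `width`, `a23`, `f`).
#' @export
simulate_group_dataset <- function(target, n, seed = 1L) {
  if (inherits(target, "correlation_matrix")) {
    labels <- target$labels
    R <- target$values
  } else {
    R <- as.matrix(target)
    labels <- colnames(R)
    if (is.null(labels)) labels <- c("v1_size", "width", "a23", "f")[seq_len(ncol(R))]
  }
  stopifnot(n >= 4, nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8))
    stop("target must be symmetric with unit diagonal")
  ch <- tryCatch(chol(R), error = function(e)
    stop("target correlation matrix is not positive definite"))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * ncol(R)), n, ncol(R))
  X <- Z %*% ch
  colnames(X) <- labels
  cbind(data.frame(subject = seq_len(n)), as.data.frame(X))
}

#' Write / read a group dataset as CSV
#'
#' @param x Data frame from [simulate_group_dataset()].
#' @param path CSV path.
#' @return `path` invisibly / the data frame.
#' @export
write_group_dataset <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_group_dataset
#' @export
read_group_dataset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
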