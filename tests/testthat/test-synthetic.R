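test_that("simulated spectra are seeded, floored and unbiased", {
  truth0 <- ground_truth(noise_sd = 0)
  clean <- predict_spectrum(30:80)$power
  expect_equal(simulate_spectrum(truth0)$power, clean)
  t1 <- ground_truth(seed = 11)
  expect_identical(simulate_spectrum(t1)$power, simulate_spectrum(t1)$power)
  expect_false(identical(simulate_spectrum(t1)$power,
                         simulate_spectrum(ground_truth(seed = 12))$power))
  # law of large numbers: the mean of many replicates approaches the
  # noiseless curve within 3 standard errors per bin
  n_rep <- 1000
  sd_bin <- 0.03 * mean(clean)
  acc <- matrix(0, n_rep, length(clean))
  for (s in seq_len(n_rep)) {
    set.seed(s)
    acc[s, ] <- pmax(0, clean + rnorm(length(clean), 0, sd_bin))
  }
  se <- sd_bin / sqrt(n_rep)
  expect_true(all(abs(colMeans(acc) - clean) < 3 * se))
})

test_that("time-domain synthesis reproduces the analytic sensor spectrum", {
  # zero layer weights give the zero series
  t0 <- ground_truth(obs = obs_model(q = rep(0, 4)), noise_sd = 0)
  expect_equal(as.numeric(simulate_timeseries(t0, duration = 2)),
               rep(0, 800))
  truth <- ground_truth(noise_sd = 0, seed = 21)
  x <- simulate_timeseries(truth, duration = 120, dt = 0.0025)
  w <- welch_psd(as.numeric(x), fs = attr(x, "fs"))
  band <- w$freqs >= 30 & w$freqs <= 80
  ref <- sensor_spectrum(w$freqs[band])$power
  rel <- (w$psd[band] - ref) / ref
  expect_lt(sqrt(mean(rel^2)), 0.15)
  # Parseval: series variance equals the spectral integral
  full <- sensor_spectrum(seq(1, 199.9, 0.5))$power
  expect_equal(var(as.numeric(x)), sum(full) * 0.5, tolerance = 0.05)
})

test_that("gamma-peak extraction recovers a known bump and refuses flat spectra", {
  f <- 30:80
  bump <- 5 * exp(-(f - 55)^2 / (2 * 4^2)) + 1
  pk <- extract_gamma_peak(spectral_data(f, bump))
  expect_equal(pk$peak_hz, 55, tolerance = 1e-6)
  expect_equal(pk$bandwidth, 4, tolerance = 1e-6)
  expect_error(extract_gamma_peak(spectral_data(f, rep(2, length(f)))),
               class = "cmcfield_no_peak")
  # percentage-change route against a baseline
  base <- spectral_data(f, rep(10, length(f)))
  stim <- spectral_data(f, 10 * (1 + 0.4 * exp(-(f - 62)^2 / (2 * 9))))
  pk2 <- extract_gamma_peak(stim, base)
  expect_equal(pk2$peak_hz, 62, tolerance = 1e-6)
  expect_equal(pk2$amplitude, 40, tolerance = 1e-4)
})

test_that("peak recovery survives noise at SNR 5", {
  f <- 30:80
  clean <- 5 * exp(-(f - 55)^2 / (2 * 4^2))
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    y <- pmax(0, clean + rnorm(length(f), 0, 1))
    pk <- tryCatch(extract_gamma_peak(spectral_data(f, y)),
                   error = function(e) NULL)
    if (!is.null(pk) && abs(pk$peak_hz - 55) < 1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("group simulator hits its target correlation structure", {
  id <- correlation_matrix(diag(4), c("v1_size", "width", "a23", "f"), 32)
  big <- simulate_group_dataset(id, n = 10000, seed = 1)
  R <- cor(big[, -1])
  expect_true(all(abs(R[upper.tri(R)]) < 0.05))
  expect_identical(simulate_group_dataset(id, 50, seed = 7),
                   simulate_group_dataset(id, 50, seed = 7))
  t2 <- group_correlations()
  big2 <- simulate_group_dataset(t2, n = 10000, seed = 2)
  R2 <- cor(big2[, -1])
  expect_lt(max(abs(R2 - t2$values[colnames(R2), colnames(R2)])), 0.03)
  # non-PD targets are rejected
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  colnames(bad) <- rownames(bad) <- c("x", "y", "z")
  expect_error(simulate_group_dataset(bad, 10), "positive definite")
})

test_that("group datasets round-trip through CSV", {
  d <- simulate_group_dataset(group_correlations(), 12, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_group_dataset(d, f)
  d2 <- read_group_dataset(f)
  expect_equal(names(d2), c("subject", "width", "v1_size", "a23", "f"))
  expect_equal(d2$a23, d$a23, tolerance = 1e-12)
  unlink(f)
})

test_that("the simulate -> fit loop recovers generating scalings at high SNR", {
  # end-to-end: data generated just off the priors along the dominant
  # identifiable direction are recovered in sign and within 2 SD
  model <- cmc_model("field")
  vt <- setNames(rep(0, length(model$free)), model$free)
  vt["c_diag"] <- 0.3
  sp <- pack_parameters(model, vt)
  clean <- predict_spectrum(30:80, sp$params, sp$field, sp$obs)$power
  truth <- ground_truth(sp$params, sp$field, sp$obs,
                        noise_sd = 0.002 * mean(clean), seed = 31)
  fit <- cmc_dcm(simulate_spectrum(truth))
  expect_gt(fit$mu[["c_diag"]], 0)
  sd_cd <- sqrt(diag(fit$C))[which(model$free == "c_diag")]
  expect_lt(abs(fit$mu[["c_diag"]] - 0.3), 2 * sd_cd)
})
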