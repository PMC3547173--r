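test_that("matrix and closed-form transfer routes agree at random draws", {
  for (seed in 1:30) {
    jp <- jittered_parameters(seed)
    set.seed(1000 + seed)
    k <- runif(1, -3, 3); w <- runif(1, 0.05, 0.6)
    t_mat <- transfer_matrix(k, w, jp$params, jp$field)
    t_cf <- closed_form_sr(k, w, jp$params, jp$field)[1, ]
    expect_lt(max(Mod(t_mat - t_cf)) / max(Mod(t_mat)), 1e-8)
  }
})

test_that("transfer function is conjugate-symmetric and decoupled without coupling", {
  p <- cmc_params(); fp <- field_params()
  for (k in c(-1, 0.5)) for (w in c(0.1, 0.4)) {
    expect_equal(transfer_matrix(-k, -w, p, fp),
                 Conj(transfer_matrix(k, w, p, fp)), tolerance = 1e-10)
  }
  # no connectivity, no gain: only the input population responds
  p0 <- p; p0$a[] <- 0
  T0 <- transfer_matrix(0, 0, p0, fp, gain = rep(0, 4))
  expect_equal(Re(T0[1]), p$m_e / p$kappa[1], tolerance = 1e-12)
  expect_equal(T0[2:4], rep(0 + 0i, 3))
})

test_that("populations downstream of the stellate input lose their drive when its efferents vanish", {
  # S_2, S_3 carry D_21 and S_4 carries D_41: cutting a_21 and a_41
  # silences every population but the input one
  p <- cmc_params()
  p$a["a_21"] <- 0
  p$a["a_41"] <- 0
  fp <- field_params()
  Tv <- closed_form_sr(0.5, 0.3, p, fp)[1, ]
  expect_equal(Tv[2:4], rep(0 + 0i, 3))
  expect_gt(Mod(Tv[1]), 0)
})

test_that("lead field is a unit-peak even Gaussian and sizes its own grid", {
  expect_equal(lead_field_coefficients(0.1, 0), 1)
  ks <- seq(0.05, 0.4, 0.05)
  expect_equal(lead_field_coefficients(0.1, ks),
               lead_field_coefficients(0.1, -ks))
  kg <- lead_k_grid(obs_model(), field_params())
  expect_true(0 %in% kg)
  expect_equal(kg, -rev(kg))
  expect_lt(lead_field_coefficients(0.1, max(kg)), 1e-6)
})

test_that("input and noise curves follow the selected colour law", {
  f <- 30:80
  flat <- input_noise_spectra(f, obs_model(alpha_u = 2, beta_u = 0))
  expect_equal(flat$g_u, rep(2, length(f)))
  one_f <- input_noise_spectra(f, obs_model(alpha_u = 0, beta_u = 1))
  expect_equal(one_f$g_u[f == 60], one_f$g_u[f == 30] / 2)
  pos <- input_noise_spectra(f, obs_model(alpha_u = 1, beta_u = 2,
                                          alpha_n = 0.5, beta_n = 1))
  expect_true(all(pos$g_u > 0) && all(pos$g_n > 0))
  lin <- input_noise_spectra(f, obs_model(alpha_u = 1, beta_u = 3,
                                          colour = "linear"))
  expect_equal(lin$g_u, 1 + 3 * 2 * pi * f / 1000)
  expect_error(input_noise_spectra(f, obs_model(alpha_u = 0, beta_u = -1)),
               "negative")
})

test_that("sensor spectrum is a quadratic form in the layer weights", {
  f <- seq(30, 80, 5)
  zero <- sensor_spectrum(f, obs = obs_model(q = rep(0, 4)))
  expect_equal(zero$power, rep(0, length(f)))
  s1 <- sensor_spectrum(f, obs = obs_model(q = c(10, 0, 10, 80)))
  s2 <- sensor_spectrum(f, obs = obs_model(q = 2 * c(10, 0, 10, 80)))
  expect_equal(s2$power, 4 * s1$power, tolerance = 1e-12)
  expect_true(all(is.finite(s1$power)) && all(s1$power >= 0))
})

test_that("doubling the spatial-frequency grid leaves the spectrum unchanged", {
  f <- seq(30, 80, 5)
  base <- sensor_spectrum(f)
  N <- (length(lead_k_grid(obs_model(), field_params())) - 1) / 2
  fine <- sensor_spectrum(f, obs = obs_model(n_k = 2 * N))
  expect_lt(max(abs(fine$power - base$power) / base$power), 1e-3)
})

test_that("field prediction reduces to the mass spectrum in the delay-free limit", {
  f <- 30:80
  p <- cmc_params()
  fp0 <- field_params(upsilon = 0)
  s_field <- sensor_spectrum(f, p, fp0, obs_model(n_k = 0))
  K <- total_connectivity(p, fp0)
  q <- obs_model()$q
  s_mass <- vapply(f, function(fr)
    Mod(sum(q * mass_transfer(p, 2 * pi * fr / 1000, K)))^2, numeric(1))
  expect_lt(max(abs(s_field$power - s_mass) / s_mass), 1e-8)
})

test_that("observed prediction is channel noise plus a non-negative neural part", {
  f <- seq(30, 80, 2)
  obs_n <- obs_model(q = rep(0, 4), alpha_n = 0.3, beta_n = 1)
  g_n <- input_noise_spectra(f, obs_n)$g_n
  expect_equal(predict_spectrum(f, obs = obs_n)$power, g_n)
  obs_full <- obs_model(alpha_n = 0.3, beta_n = 1)
  expect_true(all(predict_spectrum(f, obs = obs_full)$power >=
                    input_noise_spectra(f, obs_full)$g_n))
})

test_that("contribution sweep reproduces the base spectrum and stays smooth", {
  base <- predict_spectrum(30:80)
  sw0 <- contribution_sweep("a_23", 0)
  expect_equal(sw0[["0"]]$power, base$power)
  sw <- contribution_sweep("a_23", seq(-1, 1, 0.25))
  expect_true(all(vapply(sw, function(s) all(is.finite(s$power)), logical(1))))
  expect_error(contribution_sweep("a_99", 0), "unknown parameter")
})

test_that("sweep centroid trajectory matches the frozen regression fixture", {
  # power-weighted in-band centroid per a_23 log-scaling; values frozen
  # from the first validated run, monotone over the sub-range [-1, 0.25]
  sw <- contribution_sweep("a_23", seq(-1, 1, 0.25))
  cen <- vapply(sw, function(s) sum(s$freqs * s$power) / sum(s$power),
                numeric(1))
  frozen <- c(55.2218, 55.2237, 55.2252, 55.2262, 55.2267, 55.2268,
              55.2266, 55.2262, 55.2256)
  expect_equal(unname(cen), frozen, tolerance = 1e-5)
  expect_true(all(diff(cen[1:6]) > 0))
})

test_that("narrowing the columns moves the spectrum the way the sweep records", {
  # direction of the c_diag effect from the sweep ...
  sw <- contribution_sweep("c_diag", c(0, 0.4), freqs = seq(30, 80, 2))
  sweep_dir <- sign(mean(sw[["0.4"]]$power - sw[["0"]]$power))
  # ... matches an independent forward evaluation
  fp2 <- field_params(c_diag = 2 * exp(0.4))
  d <- predict_spectrum(seq(30, 80, 2), field = fp2)$power -
    predict_spectrum(seq(30, 80, 2))$power
  expect_equal(sign(mean(d)), sweep_dir)
})
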