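test_that("log-scalings pack multiplicatively with an additive zero-mean rule", {
  model <- cmc_model("field")
  th0 <- pack_parameters(model, setNames(rep(0, 17), model$free))$theta
  expect_equal(th0, model$theta_bar)
  th <- pack_parameters(model, c(m_e = log(2)))$theta
  expect_equal(th["m_e"], c(m_e = 16))
  expect_equal(th[setdiff(names(th), "m_e")],
               model$theta_bar[setdiff(names(th), "m_e")])
  # round trip by elementwise log-ratio
  set.seed(1)
  vt <- setNames(rnorm(17, 0, 0.2), model$free)
  thv <- pack_parameters(model, vt)$theta
  mult <- setdiff(model$free, "eta")
  expect_equal(log(thv[mult] / model$theta_bar[mult]),
               setNames(vt[mult], mult), tolerance = 1e-12)
  # eta has prior mean zero: additive offset
  expect_equal(unname(thv["eta"]), unname(vt["eta"]))
  expect_error(pack_parameters(model, c(nonsense = 1)), "unknown")
})

test_that("free energy reduces to pure accuracy at a perfect prior fit", {
  f <- seq(30, 80, 5)
  model <- cmc_model("field", freqs = f, hyper_mean = 0)
  mu <- setNames(rep(0, length(model$free)), model$free)
  data <- spectral_data(f, cmcfield:::model_prediction(model, mu))
  C <- diag(model$prior_var)
  Fv <- free_energy(data, model, mu, C, lambda = 0)
  n <- length(f)
  expect_equal(as.numeric(Fv), -n / 2 * log(2 * pi))
  parts <- attr(Fv, "parts")
  expect_equal(unname(parts["kl_theta"]), 0, tolerance = 1e-12)
  expect_equal(unname(parts["kl_lambda"]), 0, tolerance = 1e-12)
  # at a general lambda the identity F = -(n/2) ln 2pi + (n/2) lambda
  # holds up to the hyperparameter KL
  F2 <- free_energy(data, model, mu, C, lambda = 2)
  expect_equal(attr(F2, "parts")[["accuracy"]],
               -n / 2 * log(2 * pi) + n / 2 * 2)
})

test_that("shrinking the posterior covariance raises the complexity", {
  f <- seq(30, 80, 5)
  model <- cmc_model("field", freqs = f, hyper_mean = 0)
  mu <- setNames(rep(0, length(model$free)), model$free)
  data <- spectral_data(f, cmcfield:::model_prediction(model, mu))
  kl_of <- function(scale) {
    attr(free_energy(data, model, mu, diag(model$prior_var) * scale, 0),
         "parts")[["kl_theta"]]
  }
  expect_true(kl_of(1e-2) > kl_of(1e-1))
  expect_true(kl_of(1e-1) > kl_of(1))
})

test_that("free energy prefers the generating parameters, more so at high SNR", {
  f <- 30:80
  model <- cmc_model("field", freqs = f)
  vt_true <- setNames(rep(0, length(model$free)), model$free)
  vt_true["c_diag"] <- 0.4
  clean <- cmcfield:::model_prediction(model, vt_true)
  C <- diag(model$prior_var)
  margin <- vapply(c(0.03, 0.005), function(rel) {
    set.seed(42)
    y <- spectral_data(f, pmax(0, clean + rnorm(length(f), 0,
                                                rel * mean(clean))))
    lam <- -2 * log(rel * mean(clean))
    F_true <- free_energy(y, model, vt_true, C, lam)
    F_prior <- free_energy(y, model, vt_true * 0, C, lam)
    as.numeric(F_true - F_prior)
  }, numeric(1))
  expect_true(all(margin > 0))
  expect_gt(margin[2], margin[1])
})

test_that("fitting self-generated data keeps the posterior near the prior truth", {
  truth <- ground_truth(noise_sd = 1e-6)
  y <- simulate_spectrum(truth)
  fit <- cmc_dcm(y)
  sd <- sqrt(diag(fit$C))
  expect_true(all(abs(fit$mu) <= 2 * sd))
  expect_true(all(diff(fit$trajectory) >= 0))
  # posterior covariance stays symmetric PSD
  expect_equal(fit$C, t(fit$C))
  expect_true(all(eigen(fit$C, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("the mass variant equals the field model with delays and k-grid collapsed", {
  truth <- ground_truth(seed = 3)
  y <- simulate_spectrum(truth)
  fit_mass <- cmc_dcm(y, model = cmc_model("mass", freqs = y$freqs))
  equiv <- cmc_model("field", field = field_params(upsilon = 0),
                     obs = obs_model(n_k = 0), freqs = y$freqs,
                     free = cmc_free_default("mass"))
  fit_equiv <- cmc_dcm(y, model = equiv)
  expect_lt(abs(fit_mass$F - fit_equiv$F), 1e-6)
})

test_that("posterior correlations are a unit-diagonal normalisation of C", {
  fake <- list(C = diag(c(1, 4, 9)), mu = setNames(1:3, c("a", "b", "c")))
  expect_equal(posterior_correlations(fake), diag(3),
               ignore_attr = "dimnames")
  set.seed(2)
  A <- matrix(rnorm(16), 4)
  C <- crossprod(A) + diag(4)
  R <- posterior_correlations(list(C = C, mu = setNames(rep(0, 4),
                                                        letters[1:4])))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_true(all(abs(R) <= 1 + 1e-12))
  expect_equal(unname(R), C / sqrt(outer(diag(C), diag(C))),
               tolerance = 1e-12)
  expect_error(posterior_correlations(list(C = diag(c(1, 0)))), "variance")
})

test_that("model comparison flags strong evidence at |dF| >= 3 inclusively", {
  truth <- ground_truth(seed = 5)
  y <- simulate_spectrum(truth)
  fit <- cmc_dcm(y, model = cmc_model("field"),
                 control = cmc_control(max_iter = 4))
  self <- compare_models(fit, fit)
  expect_equal(self$dF, 0)
  expect_false(self$strong)
  # boundary: exactly 3 counts as strong
  fit3 <- fit; fit3$F <- fit$F - 3
  cmp <- compare_models(fit, fit3)
  expect_equal(cmp$dF, 3)
  expect_true(cmp$strong)
  # mismatched data refuse to compare
  y2 <- simulate_spectrum(ground_truth(seed = 6))
  fit2 <- fit; fit2$data <- y2
  expect_error(compare_models(fit, fit2), "identical data")
})

test_that("field data give the field model more evidence than the mass model", {
  # high-SNR (0.5%) spectra simulated from the field variant at its
  # prior conduction delay
  dF <- vapply(1:10, function(s) {
    clean <- predict_spectrum(30:80)$power
    truth <- ground_truth(noise_sd = 0.005 * mean(clean), seed = s)
    y <- simulate_spectrum(truth)
    ff <- cmc_dcm(y, model = cmc_model("field"))
    mf <- cmc_dcm(y, model = cmc_model("mass"))
    ff$F - mf$F
  }, numeric(1))
  expect_gt(mean(dF), 0)
})

test_that("an irrelevant extra free parameter never gains free energy on average", {
  diffs <- vapply(1:3, function(s) {
    y <- simulate_spectrum(ground_truth(seed = s))
    f_base <- cmc_dcm(y, model = cmc_model("field"))
    f_extra <- cmc_dcm(y, model = cmc_model("field",
                                            free = c(cmc_free_default("field"),
                                                     "m_i")))
    f_extra$F - f_base$F
  }, numeric(1))
  expect_lte(mean(diffs), 0.1)
})

test_that("fit serialisation writes a parseable record with a settings hash", {
  y <- simulate_spectrum(ground_truth(seed = 9), freqs = seq(30, 80, 10))
  fit <- cmc_dcm(y, model = cmc_model("field", freqs = y$freqs),
                 control = cmc_control(max_iter = 2))
  f <- tempfile(fileext = ".json")
  write_fit(fit, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$F, fit$F)
  expect_equal(unlist(obj$mu), fit$mu)
  expect_match(obj$settings_hash, "^[0-9a-f]{32}$")
  unlink(f)
})
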