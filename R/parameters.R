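# Parameter containers for the canonical-microcircuit field model.
#
# Population indexing is fixed throughout the package:
#   1 spiny stellate (input), 2 inhibitory interneuron,
#   3 deep pyramidal (output), 4 superficial pyramidal.

.pair_names <- c("a_11", "a_12", "a_14", "a_21", "a_22",
                 "a_23", "a_32", "a_33", "a_41", "a_44")

#' Population labels of the canonical microcircuit
#'
#' @return Character vector of length 4 naming the populations in their
#'   fixed order: spiny stellate, inhibitory interneuron, deep pyramidal,
#'   superficial pyramidal.
#' @export
population_labels <- function() {
  c("spiny stellate", "inhibitory interneuron",
    "deep pyramidal", "superficial pyramidal")
}

#' Ordered (target, source) pairs of the intrinsic connectivity pattern
#'
#' The microcircuit admits ten intrinsic connections; all other entries of
#' the 4 x 4 connectivity matrix are structurally zero.
#'
#' @return Integer matrix with columns `to` and `from`, one row per
#'   connection, in the order of the `a_<to><from>` amplitude names.
#' @export
connection_pairs <- function() {
  m <- cbind(to   = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L),
             from = c(1L, 2L, 4L, 1L, 2L, 3L, 2L, 3L, 1L, 4L))
  rownames(m) <- .pair_names
  m
}

#' Fixed sign map of the intrinsic connections
#'
#' Presynaptic input enters each population with a fixed sign: negative
#' for the connections 1<-4, 1<-2 and 3<-2, positive for all others
#' (including every self-connection).
#'
#' @return 4 x 4 matrix of +1/-1 on the connectivity pattern (and +1
#'   elsewhere, where amplitudes are structurally zero).
#' @export
sign_matrix <- function() {
  s <- matrix(1, 4, 4)
  s[1, 2] <- -1
  s[1, 4] <- -1
  s[3, 2] <- -1
  s
}

#' Synaptic and sigmoid parameters of the canonical microcircuit
#'
#' Defaults are the prior expectations used throughout the package:
#' maximum postsynaptic depolarisations `m_e = 8`, `m_i = 32` mV,
#' postsynaptic rate constants `kappa = (1/2, 1/2, 1/16, 1/28)` per ms,
#' sigmoid gain `r = 0.54` per mV and inflection `eta = 0` mV, and
#' intrinsic amplitudes `a_22 = a_33 = a_41 = 3200`, `a_12 = a_44 = 800`,
#' `a_23 = a_32 = 1600`, `a_11 = 9600`, `a_14 = 4000`, `a_21 = 4800`.
#'
#' @param m_e,m_i Maximum excitatory/inhibitory postsynaptic
#'   depolarisation (mV); both positive.
#' @param kappa Numeric vector of 4 postsynaptic rate constants (1/ms).
#' @param r Sigmoid gain (1/mV), positive.
#' @param eta Sigmoid inflection potential (mV).
#' @param a Named numeric vector of intrinsic amplitudes on the sparsity
#'   pattern (`a_11`, `a_12`, `a_14`, `a_21`, `a_22`, `a_23`, `a_32`,
#'   `a_33`, `a_41`, `a_44`); all non-negative.
#' @param sign 4 x 4 sign matrix; the default is the fixed convention of
#'   [sign_matrix()].  Exposed so a variant with conventional inhibitory
#'   self-connections can be selected; the default is never altered by
#'   the fitting machinery.
#' @return An object of class `cmc_params`.
#' @seealso [field_params()], [obs_model()], [cmc_model()]
#' @export
cmc_params <- function(m_e = 8, m_i = 32,
                       kappa = c(1/2, 1/2, 1/16, 1/28),
                       r = 0.54, eta = 0,
                       a = c(a_11 = 9600, a_12 = 800, a_14 = 4000,
                             a_21 = 4800, a_22 = 3200, a_23 = 1600,
                             a_32 = 1600, a_33 = 3200, a_41 = 3200,
                             a_44 = 800),
                       sign = sign_matrix()) {
  stopifnot(m_e > 0, m_i > 0, length(kappa) == 4, all(kappa > 0), r > 0,
            is.finite(eta))
  if (is.null(names(a)) || !setequal(names(a), .pair_names))
    stop("'a' must be named with exactly: ", paste(.pair_names, collapse = ", "))
  a <- a[.pair_names]
  if (any(a < 0)) stop("intrinsic amplitudes must be >= 0")
  stopifnot(is.matrix(sign), dim(sign) == c(4, 4), all(sign %in% c(-1, 1)))
  structure(list(m_e = m_e, m_i = m_i, kappa = as.numeric(kappa),
                 r = r, eta = eta, a = a, sign = sign),
            class = "cmc_params")
}

#' @export
print.cmc_params <- function(x, ...) {
  cat("Canonical microcircuit parameters\n")
  cat(sprintf("  m_e = %g mV, m_i = %g mV\n", x$m_e, x$m_i))
  cat(sprintf("  kappa = %s (1/ms)\n", paste(signif(x$kappa, 4), collapse = ", ")))
  cat(sprintf("  sigmoid: r = %g /mV, eta = %g mV\n", x$r, x$eta))
  cat("  amplitudes:\n")
  print(x$a)
  invisible(x)
}

# per-population maximum depolarisation: m_e for excitatory, m_i for the
# inhibitory interneurons (population 2)
pop_m <- function(params) c(params$m_e, params$m_i, params$m_e, params$m_e)

#' Signed intrinsic amplitude matrix
#'
#' @param params A [cmc_params()] object.
#' @return 4 x 4 matrix `sign_ab * a_ab` on the connectivity pattern,
#'   zero elsewhere.
#' @export
amplitude_matrix <- function(params) {
  m <- matrix(0, 4, 4)
  p <- connection_pairs()
  m[p] <- params$a
  m * params$sign
}

#' Spatial (field) parameters
#'
#' Spatial decay rates of the connectivity kernels, the separation of
#' columns reached by patchy horizontal connections, the inverse
#' conduction speed, and the size of the modelled cortical patch.
#'
#' Defaults are the prior expectations: decay 2/mm within a layer
#' (diagonal), 0.6/mm between layers, column separation 4.5 mm, inverse
#' conduction speed 0.6 ms/mm (speed ~1.5 m/s), patch length 25 mm.
#'
#' @param c_diag Spatial decay of the within-layer (diagonal) kernels
#'   (1/mm); `1/c_diag` is read as the macrocolumn width.
#' @param c_off Spatial decay of the interlaminar (off-diagonal) kernels
#'   (1/mm).
#' @param h Separation between columns (mm), non-negative; one value
#'   shared by all layers or a vector of 4.
#' @param upsilon Inverse conduction speed (ms/mm); 0 gives
#'   instantaneous propagation (the neural-mass limit).
#' @param L_patch Cortical patch length (mm), positive.
#' @return An object of class `field_params`.
#' @export
field_params <- function(c_diag = 2, c_off = 0.6, h = 4.5,
                         upsilon = 0.6, L_patch = 25) {
  stopifnot(c_diag > 0, c_off > 0, all(h >= 0), upsilon >= 0, L_patch > 0)
  h <- rep_len(as.numeric(h), 4)
  structure(list(c_diag = c_diag, c_off = c_off, h = h,
                 upsilon = upsilon, L_patch = L_patch),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat("Field parameters\n")
  cat(sprintf("  c_diag = %g /mm (width 1/c = %g mm), c_off = %g /mm\n",
              x$c_diag, 1 / x$c_diag, x$c_off))
  cat(sprintf("  h = %s mm, upsilon = %g ms/mm, patch = %g mm\n",
              paste(unique(signif(x$h, 4)), collapse = "/"), x$upsilon,
              x$L_patch))
  invisible(x)
}

# spatial decay for an ordered pair (to, from)
pair_decay <- function(field, to, from) {
  ifelse(to == from, field$c_diag, field$c_off)
}

#' Observation model for the single-channel spectrum
#'
#' A Gaussian lead field over the patch, four layer-contribution weights,
#' and the input and channel-noise spectral laws.
#'
#' @param phi Lead-field dispersion as a fraction of the patch length
#'   (default 2/20 = 0.1, i.e. 2.5 mm on a 25 mm patch); positive.
#' @param q Numeric vector of 4 layer-contribution weights.
#' @param alpha_u,beta_u White and coloured coefficients of the input
#'   spectrum; `alpha_u >= 0`.
#' @param alpha_n,beta_n Same for the channel-noise spectrum;
#'   `alpha_n >= 0`.
#' @param colour Colour law for the beta terms: `"one_over_f"` (default,
#'   `alpha + beta/f` with `f` in Hz) or `"linear"` (the literal
#'   linear-in-omega law `alpha + beta*omega`, omega in rad/ms).
#' @param n_k Truncation order of the spatial-frequency grid (grid is
#'   `k_n = n/L_patch` cycles/mm, `n = -n_k..n_k`).  `NULL` (default)
#'   sizes the grid so the lead-field weight at the boundary is below
#'   1e-6.
#' @return An object of class `obs_model`.
#' @export
obs_model <- function(phi = 2/20, q = c(10, 0, 10, 80),
                      alpha_u = 1, beta_u = 0,
                      alpha_n = 0, beta_n = 0,
                      colour = c("one_over_f", "linear"),
                      n_k = NULL) {
  colour <- match.arg(colour)
  stopifnot(phi > 0, length(q) == 4, alpha_u >= 0, alpha_n >= 0)
  if (!is.null(n_k)) stopifnot(n_k >= 0, n_k == round(n_k))
  structure(list(phi = phi, q = as.numeric(q),
                 alpha_u = alpha_u, beta_u = beta_u,
                 alpha_n = alpha_n, beta_n = beta_n,
                 colour = colour, n_k = n_k),
            class = "obs_model")
}

#' @export
print.obs_model <- function(x, ...) {
  cat("Observation model\n")
  cat(sprintf("  lead-field dispersion phi = %g (fraction of patch)\n", x$phi))
  cat(sprintf("  layer weights q = (%s)\n", paste(x$q, collapse = ", ")))
  cat(sprintf("  input: alpha_u = %g, beta_u = %g (%s colour)\n",
              x$alpha_u, x$beta_u, x$colour))
  cat(sprintf("  channel noise: alpha_n = %g, beta_n = %g\n",
              x$alpha_n, x$beta_n))
  invisible(x)
}

# ---- flat serialisation -----------------------------------------------

#' Flatten a parameter set to a named key-value vector
#'
#' Keys follow the field's symbols: `m_e`, `m_i`, `kappa_1..kappa_4`,
#' `r`, `eta`, `a_11..a_44`, `c_diag`, `c_off`, `h`, `upsilon`,
#' `L_patch`, `phi`, `q_1..q_4`, `alpha_u`, `beta_u`, `alpha_n`,
#' `beta_n`.
#'
#' @param params,field,obs Parameter objects (see [cmc_params()],
#'   [field_params()], [obs_model()]).
#' @return Named numeric vector.
#' @export
flatten_theta <- function(params = cmc_params(), field = field_params(),
                          obs = obs_model()) {
  c(m_e = params$m_e, m_i = params$m_i,
    stats::setNames(params$kappa, paste0("kappa_", 1:4)),
    r = params$r, eta = params$eta,
    params$a,
    c_diag = field$c_diag, c_off = field$c_off, h = field$h[1],
    upsilon = field$upsilon, L_patch = field$L_patch,
    phi = obs$phi, stats::setNames(obs$q, paste0("q_", 1:4)),
    alpha_u = obs$alpha_u, beta_u = obs$beta_u,
    alpha_n = obs$alpha_n, beta_n = obs$beta_n)
}

#' Rebuild parameter objects from a flat key-value vector
#'
#' Inverse of [flatten_theta()].  Options that are not numeric (the sign
#' map, colour law, grid order) are taken from the supplied templates.
#'
#' @param theta Named numeric vector as produced by [flatten_theta()].
#' @param params,field,obs Template objects providing non-numeric
#'   settings.
#' @return List with elements `params`, `field`, `obs`.
#' @export
split_theta <- function(theta, params = cmc_params(),
                        field = field_params(), obs = obs_model()) {
  g <- function(nm) unname(theta[nm])
  list(
    params = cmc_params(m_e = g("m_e"), m_i = g("m_i"),
                        kappa = g(paste0("kappa_", 1:4)),
                        r = g("r"), eta = g("eta"),
                        a = theta[.pair_names], sign = params$sign),
    field = field_params(c_diag = g("c_diag"), c_off = g("c_off"),
                         h = g("h"), upsilon = g("upsilon"),
                         L_patch = g("L_patch")),
    obs = obs_model(phi = g("phi"), q = g(paste0("q_", 1:4)),
                    alpha_u = g("alpha_u"), beta_u = g("beta_u"),
                    alpha_n = g("alpha_n"), beta_n = g("beta_n"),
                    colour = obs$colour, n_k = obs$n_k))
}

#' Read / write a flat parameter configuration
#'
#' Flat key-value configuration files (JSON or YAML by extension) with
#' the keys of [flatten_theta()]; unknown keys are rejected.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_cmc_config()` returns a named numeric vector (defaults
#'   filled in for absent keys); `write_cmc_config()` returns `path`
#'   invisibly.
#' @export
read_cmc_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: .", ext))
  vals <- unlist(vals)
  base <- flatten_theta()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base[names(vals)] <- as.numeric(vals)
  base
}

#' @rdname read_cmc_config
#' @param theta Named numeric vector to write.
#' @export
write_cmc_config <- function(theta, path) {
  ext <- tolower(tools::file_ext(path))
  lst <- as.list(theta)
  switch(ext,
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(lst, path, precision = 15),
    stop("unsupported config format: .", ext))
  invisible(path)
}
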