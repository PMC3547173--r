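# Point (neural-mass) dynamics of the four-population microcircuit.

#' Sigmoid firing-rate function
#'
#' Maps depolarisation to a normalised firing rate,
#' `sigma(v) = 1 / (1 + exp(r (eta - v)))`.
#'
#' @param v Depolarisation (mV); vectorised.
#' @param params A [cmc_params()] object supplying `r` and `eta`.
#' @return Firing rate in (0, 1); saturates smoothly for extreme `v`.
#' @export
cmc_sigmoid <- function(v, params = cmc_params()) {
  stats::plogis(params$r * (v - params$eta))
}

#' Gain of the sigmoid at a given depolarisation
#'
#' The derivative of [cmc_sigmoid()], `r e^{r(eta - v)} /
#' (1 + e^{r(eta - v)})^2`, evaluated by default at `v = 0` — the
#' linearisation point of the transfer function.  With `eta = 0` this is
#' `r/4`.
#'
#' @param params A [cmc_params()] object.
#' @param v Depolarisation at which to evaluate the gain (default 0 mV);
#'   vectorised.
#' @return Gain (1/mV).
#' @export
sigmoid_gain <- function(params = cmc_params(), v = 0) {
  s <- cmc_sigmoid(v, params)
  params$r * s * (1 - s)
}

# per-population gain vector under the selected linearisation point
gain_vector <- function(params, total_conn = NULL,
                        linearization = c("origin", "fixed_point")) {
  linearization <- match.arg(linearization)
  if (linearization == "origin") {
    rep(sigmoid_gain(params, 0), 4)
  } else {
    v0 <- steady_state(params, total_conn)
    sigmoid_gain(params, v0)
  }
}

#' Spatially homogeneous steady state of the field
#'
#' Solves the fixed point `V0 = B^-1 A K sigma(V0)` where `K` is the
#' signed integral of the connectivity kernel over space (see
#' [total_connectivity()]), by damped fixed-point iteration (damping
#' 0.5, at most 10000 iterations, residual below 1e-10).
#'
#' @param params A [cmc_params()] object.
#' @param total_conn 4 x 4 signed total-connectivity matrix.
#' @return Numeric 4-vector `V0` (mV).  Signals an error (class
#'   `cmcfield_divergence`, carrying the last iterate) if the iteration
#'   does not converge.
#' @export
steady_state <- function(params, total_conn) {
  stopifnot(is.matrix(total_conn), dim(total_conn) == c(4, 4))
  mk <- pop_m(params) / params$kappa
  v0 <- rep(0, 4)
  damp <- 0.5
  for (it in seq_len(10000L)) {
    v1 <- mk * as.vector(total_conn %*% cmc_sigmoid(v0, params))
    vn <- (1 - damp) * v0 + damp * v1
    if (max(abs(vn - v0)) < 1e-10) {
      # residual of the undamped map at the candidate point
      res <- max(abs(mk * as.vector(total_conn %*% cmc_sigmoid(vn, params)) - vn))
      if (res < 1e-10) return(vn)
    }
    v0 <- vn
  }
  cond <- structure(
    class = c("cmcfield_divergence", "error", "condition"),
    list(message = "steady-state iteration did not converge",
         call = sys.call(-1), last = v0))
  stop(cond)
}

#' Neural-mass transfer function
#'
#' The delay-free (point-model) limit of the field transfer function:
#' `T(omega) = (-omega^2 I - 2 i omega B + B^2 - A B K Gamma)^-1 G`,
#' with `K` the constant signed total-connectivity map, `Gamma` the
#' sigmoid gain and `G = (kappa_1 m_e, 0, 0, 0)`.
#'
#' @param params A [cmc_params()] object.
#' @param omega Temporal angular frequency (rad/ms); scalar.
#' @param total_conn 4 x 4 signed total-connectivity matrix.
#' @param gain Optional 4-vector of per-population gains; default is the
#'   sigmoid gain at `v = 0` for every population.
#' @return Complex 4-vector: transfer from the exogenous input to each
#'   population's depolarisation.  Signals an error (class
#'   `cmcfield_instability`) if the system matrix is singular at `omega`.
#' @export
mass_transfer <- function(params, omega, total_conn,
                          gain = gain_vector(params)) {
  B <- diag(params$kappa)
  A <- diag(pop_m(params))
  J <- A %*% B %*% total_conn %*% diag(gain)
  M <- -omega^2 * diag(4) - 2i * omega * B + B %*% B - J
  G <- c(params$kappa[1] * params$m_e, 0, 0, 0)
  out <- tryCatch(solve(M, G), error = function(e) e)
  if (inherits(out, "error")) {
    cond <- structure(
      class = c("cmcfield_instability", "error", "condition"),
      list(message = sprintf("singular system matrix at omega = %g", omega),
           call = sys.call(-1), omega = omega))
    stop(cond)
  }
  out
}
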