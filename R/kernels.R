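# Spatial connectivity kernels and their delay-aware Fourier transforms.
#
# One internal frequency convention is used throughout: angular spatial
# frequency k in rad/mm and angular temporal frequency omega in rad/ms,
# under the transform pair e^{-ikx + i omega t}.  With a conduction delay
# |x| * upsilon the transformed kernels carry the phase
# e^{+ i omega upsilon |x|}.  Interface-level spatial frequencies in
# cycles/mm convert as k = 2*pi*cycles.

#' Intrinsic (interlaminar) connectivity kernel
#'
#' Exponentially decaying synaptic density
#' `(1/2) a_ab exp(-c_ab |x|)`; even in `x`, maximal at the origin, with
#' total mass `a_ab / c_ab`.
#'
#' @param x Distance on the patch (mm); vectorised.
#' @param a_ab Amplitude (dimensionless, >= 0).
#' @param c_ab Spatial decay rate (1/mm), positive.
#' @return Synaptic density at `x`.
#' @export
intrinsic_kernel <- function(x, a_ab, c_ab) {
  stopifnot(c_ab > 0)
  0.5 * a_ab * exp(-c_ab * abs(x))
}

#' Extrinsic (patchy horizontal) connectivity kernel
#'
#' Two displaced exponentials peaked at the column separation,
#' `(1/2) c_aa (exp(-c_aa |x - h_a|) + exp(-c_aa |x + h_a|))`; even in
#' `x`, with total mass 2 for any `(c_aa, h_a)`.
#'
#' @param x Distance on the patch (mm); vectorised.
#' @param c_aa Spatial decay rate (1/mm), positive.
#' @param h_a Column separation (mm), non-negative.
#' @return Synaptic density at `x`.
#' @export
extrinsic_kernel <- function(x, c_aa, h_a) {
  stopifnot(c_aa > 0, h_a >= 0)
  0.5 * c_aa * (exp(-c_aa * abs(x - h_a)) + exp(-c_aa * abs(x + h_a)))
}

#' Fourier transform of the delayed intrinsic kernel
#'
#' Analytic transform of `(1/2) a e^{-c|x|}` with conduction delay
#' `upsilon |x|`:
#' `D(k, omega) = a (c - i upsilon omega) / ((c - i upsilon omega)^2 + k^2)`.
#' At `upsilon = 0`, `k = 0` this is the kernel mass `a/c`.
#'
#' @param k Spatial angular frequency (rad/mm); vectorised (with
#'   `omega` recycled).
#' @param omega Temporal angular frequency (rad/ms); vectorised.
#' @param a_ab Amplitude.
#' @param c_ab Spatial decay rate (1/mm), positive.
#' @param upsilon Inverse conduction speed (ms/mm), non-negative.
#' @return Complex value(s) of the transform.  Signals an error (class
#'   `cmcfield_resonance`) if the denominator is (near-)singular.
#' @export
intrinsic_ft <- function(k, omega, a_ab, c_ab, upsilon) {
  s <- c_ab - 1i * upsilon * omega
  den <- s^2 + k^2
  if (any(abs(den) < 1e-12 * (c_ab^2 + k^2 + 1e-12))) {
    cond <- structure(
      class = c("cmcfield_resonance", "error", "condition"),
      list(message = "near-singular intrinsic transform denominator",
           call = sys.call(-1), k = k, omega = omega))
    stop(cond)
  }
  a_ab * s / den
}

#' Fourier transform of the delayed extrinsic (patchy) kernel
#'
#' Analytic transform of the displaced-exponential kernel with
#' conduction delay `upsilon |x|`, in the package's angular frequency
#' convention (derived in closed form from the three pieces of the
#' integral over `x < 0 < x < h < x`; see the methods vignette).  At
#' `upsilon = 0`, `k = 0` this is the kernel mass 2; at `h = 0` it
#' reduces to the intrinsic transform with amplitude `2 c` and decay
#' `c`.
#'
#' @inheritParams intrinsic_ft
#' @param c_aa Spatial decay rate (1/mm), positive.
#' @param h_a Column separation (mm), non-negative.
#' @return Complex value(s) of the transform.
#' @export
extrinsic_ft <- function(k, omega, c_aa, h_a, upsilon) {
  s <- c_aa - 1i * upsilon * omega   # decay seen by the outward pieces
  p <- c_aa + 1i * upsilon * omega
  den_s <- s^2 + k^2
  den_p <- p^2 + k^2
  if (any(abs(den_s) < 1e-12 * (c_aa^2 + k^2 + 1e-12)) ||
      any(abs(den_p) < 1e-12 * (c_aa^2 + k^2 + 1e-12))) {
    cond <- structure(
      class = c("cmcfield_resonance", "error", "condition"),
      list(message = "near-singular extrinsic transform denominator",
           call = sys.call(-1), k = k, omega = omega))
    stop(cond)
  }
  ph <- exp(1i * upsilon * omega * h_a)
  t_inner <- (ph * (p * cos(k * h_a) + k * sin(k * h_a)) -
                exp(-c_aa * h_a) * p) / den_p
  t_outer <- ph * (cos(k * h_a) * s - sin(k * h_a) * k) / den_s
  t_mirror <- exp(-c_aa * h_a) * s / den_s
  c_aa * (t_inner + t_outer + t_mirror)
}

#' Signed total connectivity (spatial integral of the kernels)
#'
#' The signed integral over space of the full connectivity kernel:
#' intrinsic entries contribute `sign_ab a_ab / c_ab`; the extrinsic
#' kernel adds mass 2 on the diagonal.  Equals the kernel transforms at
#' `k = 0`, `upsilon = 0`.
#'
#' @param params A [cmc_params()] object.
#' @param field A [field_params()] object.
#' @return 4 x 4 signed real matrix.
#' @export
total_connectivity <- function(params = cmc_params(), field = field_params()) {
  p <- connection_pairs()
  K <- matrix(0, 4, 4)
  K[p] <- params$a / pair_decay(field, p[, "to"], p[, "from"])
  K <- K * params$sign
  diag(K) <- diag(K) + 2
  K
}

# 4 x 4 signed kernel-transform matrix D(k, omega) at a single k, for a
# vector of omegas; returns a 3-d array [4, 4, length(omega)] unless
# length(omega) == 1 (then a matrix).  Used by the matrix-route transfer.
kernel_transform_matrix <- function(k, omega, params, field) {
  p <- connection_pairs()
  nw <- length(omega)
  D <- array(0i, c(4, 4, nw))
  for (i in seq_len(nrow(p))) {
    a <- p[i, "to"]; b <- p[i, "from"]
    cab <- pair_decay(field, a, b)
    D[a, b, ] <- params$sign[a, b] *
      intrinsic_ft(k, omega, params$a[i], cab, field$upsilon)
  }
  for (a in 1:4) {
    D[a, a, ] <- D[a, a, ] +
      extrinsic_ft(k, omega, field$c_diag, field$h[a], field$upsilon)
  }
  if (nw == 1L) D[, , 1] else D
}
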