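---
title: "Methods: a canonical-microcircuit neural-field model of gamma spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a canonical-microcircuit neural-field model of gamma spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcfield)
```

## The model

`cmcfield` generates and inverts single-channel power spectra from a
neural field whose local circuitry is the canonical microcircuit (CMC):
four populations per cortical column — spiny stellate input cells (1),
inhibitory interneurons (2), deep pyramidal output cells (3) and
superficial pyramidal cells (4) — with a fixed sparse connection
topology.  The expected depolarisation $V(x,t) \in \mathbb{R}^4$ of the
four laminae at position $x$ on a one-dimensional cortical patch obeys a
second-order integro-differential (Amari-type) field equation

$$\ddot V + 2B\dot V + B^2 V
  = AB \int K(x-x')\,F\!\big(V(x',\,t - |x-x'|\upsilon)\big)\,dx' + GU,$$

where $B = \mathrm{diag}(\kappa_1,\dots,\kappa_4)$ are postsynaptic rate
constants (1/ms), $A = \mathrm{diag}(m_e, m_i, m_e, m_e)$ are maximum
postsynaptic depolarisations (mV), $F$ applies the sigmoid firing-rate
function $\sigma(v) = 1/(1 + e^{r(\eta - v)})$ to each population,
$G = (\kappa_1 m_e, 0, 0, 0)^{\mathsf T}$ injects the exogenous input
$U$, and $\upsilon$ (ms/mm) is the inverse conduction speed of spikes
along lateral connections.  Presynaptic input enters each population
with a fixed sign — negative for the connections $1\leftarrow 4$,
$1\leftarrow 2$ and $3\leftarrow 2$, positive otherwise, including
every self-connection.  We implement the sign map exactly as the model
defines it and store it in a configurable matrix, so a variant with
conventional inhibitory self-connections can be selected without
touching the core.

The connectivity kernel has an intrinsic (interlaminar) part and an
extrinsic (patchy horizontal) part,

$$k^{(i)}_{ab}(x) = \tfrac12 a_{ab}\, e^{-c_{ab}|x|}, \qquad
  k^{(e)}_{aa}(x) = \tfrac12 c_{aa}\big(e^{-c_{aa}|x-h_a|}
                                      + e^{-c_{aa}|x+h_a|}\big),$$

so $a_{ab}$ measures connection strength, $1/c_{ab}$ the lateral
dispersion (read as macrocolumn width on the diagonal), and $h_a$ the
separation of the columns reached by the patchy connections.  The patch
is one-dimensional with rotational symmetry assumed; kernels and
transforms are treated on the infinite line because they decay fast
relative to the 25 mm patch, and the finite patch enters only through
the discrete spatial-frequency grid of the lead field.

## Transfer function and predicted spectrum

Linearising about a spatially homogeneous state and Fourier
transforming (convention $e^{-ikx + i\omega t}$) gives the transfer
function from input fluctuations to laminar responses,

$$T(k,\omega) = \big({-\omega^2} I - 2i\omega B + B^2 -
  J(k,\omega)\big)^{-1} G, \qquad J = A\,B\,D(k,\omega)\,\gamma,$$

where $D(k,\omega)$ collects the signed spatiotemporal kernel
transforms and $\gamma$ is the sigmoid gain at the linearisation point.
A conduction delay $|x|\upsilon$ turns each spatial transform into a
complex function of $\omega$; for the intrinsic kernel

$$D^{(i)}_{ab}(k,\omega) =
  \frac{a_{ab}(c_{ab} - i\upsilon\omega)}
       {(c_{ab} - i\upsilon\omega)^2 + k^2},$$

and the extrinsic transform is derived analogously in closed form from
the three pieces of the integral split at the kernel's kinks.  One
internal frequency convention is used throughout — angular spatial
frequency in rad/mm, angular temporal frequency in rad/ms — and every
analytic transform is validated against an adaptive-quadrature oracle
in the test suite (relative error below $10^{-6}$, including
$\upsilon > 0$).  A reader comparing with the usual printed form of
these transforms should note that published versions mix ordinary
(cycles) and angular conventions across terms; re-deriving everything
in one convention and pinning it to the quadrature oracle removes that
ambiguity.  The same derivation fixes the delay phase to
$e^{+i\omega\upsilon|x|}$ and the intrinsic numerator to
$a_{ab}(c_{ab} - i\upsilon\omega)$ (not $a_{ab}c_{ab} - i\upsilon\omega$).

The package keeps two independent routes to $T$: the matrix route
above, and a closed-form route that assembles per-population numerators
$S_a$ over a common denominator $R$ from the auxiliary quantities
$Q_a = -\kappa_a^2 + \gamma D_{aa}\kappa_a m_a + 2i\kappa_a\omega +
\omega^2$ and $V_{ab} = D_{ab}D_{ba}\gamma^2\kappa_a\kappa_b m_a m_b$.
The closed form is exactly the determinant/cofactor expansion of the
matrix route under the CMC sparsity pattern — provided the $D_{ab}$
inside $S_a$ and $V_{ab}$ carry the connection signs — and the two
routes agree to machine precision over randomised parameters; the
closed form is fully vectorised over $\omega$ and is what the spectrum
and the fitter use.

A single (virtual) sensor sees the patch through a Gaussian lead field
with Fourier coefficients $L(k,\varphi) = e^{-2\pi^2\varphi^2k^2}$
($k$ in cycles/mm, $\varphi$ in mm).  The predicted neural spectrum is

$$g(\omega) = \sum_k |L(k,\varphi)|^2\,
  \big|\tilde q \cdot T(k,\omega)\big|^2\, g_u(\omega),$$

summed over the discrete symmetric grid $k_n = n/L_{\mathrm{patch}}$,
with the truncation order chosen so the lead-field weight at the
boundary is below $10^{-6}$ (order 9 at the default dispersion;
doubling the order changes the spectrum by less than 0.1%).  The
observed spectrum adds a channel-noise curve:
$g_y(\omega) = g(\omega) + g_n(\omega) + \varepsilon$.

## Parameters, units and defaults

Time is milliseconds internally; interfaces accept frequencies in Hz
($\omega = 2\pi f/1000$).  The default parameter values are the
package's prior expectations:

| parameter | meaning | default |
|---|---|---|
| $m_e, m_i$ | max postsynaptic depolarisation (mV) | 8, 32 |
| $\kappa_{1..4}$ | postsynaptic rate constants (1/ms) | 1/2, 1/2, 1/16, 1/28 |
| $a_{ab}$ | intrinsic amplitudes | 3200 ($a_{22},a_{33},a_{41}$); 800 ($a_{12},a_{44}$); 1600 ($a_{23},a_{32}$); 9600 ($a_{11}$); 4000 ($a_{14}$); 4800 ($a_{21}$) |
| $c_{ab}$ | kernel decay (1/mm) | 2 (diagonal), 0.6 (off-diagonal) |
| $h_a$ | column separation (mm) | 4.5 |
| $r, \eta$ | sigmoid gain (1/mV), inflection (mV) | 0.54, 0 |
| $\upsilon$ | inverse conduction speed (ms/mm) | 0.6 (speed ~1.5 m/s) |
| $\varphi$ | lead-field dispersion | 2/20 of the patch (2.5 mm) |
| $\tilde q$ | layer contribution weights | (10, 0, 10, 80) |

Two values deserve comment.  The dispersion 2/20 carries no unit in its
usual tabulation; we read it as a fraction of the 25 mm patch (2.5 mm),
since a 0.1 mm virtual-electrode dispersion would make the lead field
flat over all retained spatial frequencies and the field/mass
distinction vacuous.  The grouping of the amplitude priors is likewise
ambiguous as usually tabulated; the mapping above is a documented
choice and every amplitude is individually overridable.  The input and
channel-noise curves default to $\alpha + \beta/f$ ("white plus 1/f");
the literal linear-in-$\omega$ law is available as an option
(`colour = "linear"`), since a mixture of white and coloured
fluctuations is most naturally read as an inverse power law.

### Linearisation point

The transfer function needs the sigmoid gain $\gamma$.  The printed
definition evaluates it at $v = 0$ (giving $r/4$ at $\eta = 0$); a
homogeneous steady state is also defined by
$V_0 = B^{-1}A\,(\smallint K)\,\sigma(V_0)$.  The package defaults to
$v = 0$, as printed, and exposes `linearization = "fixed_point"`.  At
the default amplitudes the fixed point saturates every sigmoid (the
total kernel masses are in the thousands), so the fixed-point gain is
numerically zero and the linearised dynamics decouple; this makes the
origin linearisation the only non-degenerate default.  The steady
state itself is computed by damped fixed-point iteration (damping 0.5,
at most 10,000 iterations, residual $10^{-10}$) and is verified in the
tests against long-time integration of the mass ODE.

## Inversion

`cmc_dcm()` fits a spectrum by variational Laplace.  Free parameters
are log-scalings of the prior means,
$\theta = \bar\theta\, e^{\vartheta}$, with Gaussian priors
$\vartheta \sim N(0, v)$; a free parameter whose prior mean is exactly
zero ($\eta$) is offset additively, since a multiplicative scaling
could never move it.  The default free set contains the synaptic
parameters $\kappa_1$, $m_e$ and all ten amplitudes, the spatial
parameters $\upsilon$ and the two decay groups, and the sigmoid
parameters — 17 log-scalings.  The ten decays $c_{ab}$ are driven by
two group scalings (`c_diag`, `c_off`) because the diagonal decay is
the single "columnar width" quantity of interest and the off-diagonal
decays share one prior value.  Prior variances default to 1/8
(synaptic, amplitudes) and 1/16 (spatial, sigmoid) — conventional
weakly-informative shrinkage, configurable per parameter.

Observation noise is Gaussian per frequency bin with covariance
$e^{-\lambda}I$ and a Gaussian prior on $\lambda$; by default the prior
centres at the precision of a 5% relative-error guess derived from the
data scale.  The free energy is accuracy minus complexity:

$$F = \underbrace{-\tfrac n2\ln 2\pi + \tfrac n2\lambda
  - \tfrac12 e^{\lambda}\|y - g(\mu)\|^2}_{\text{accuracy}}
  - \mathrm{KL}\big(N(\mu, C)\,\|\,N(0, \Sigma_0)\big)
  - \mathrm{KL}_\lambda .$$

Optimisation is Gauss–Newton/Levenberg–Marquardt ascent on $F$ with
central-difference Jacobians (step $10^{-3}$ in log-scaling space) and
an inner Newton update of $\lambda$; steps that do not increase $F$ are
rejected and the damping raised, so the trajectory of accepted steps is
non-decreasing by construction.  Convergence is declared after four
consecutive accepted steps with $\Delta F < 10^{-2}$, at 128
iterations, or when no damped step improves $F$ (a local maximum
within numerical resolution).  Fits are on raw power by default
(the observation equation is additive in power); log-power fitting is
an option.

The neural-mass variant is the field model with conduction delays
shrunk to zero: $\upsilon$ pinned at 0 and the spatial-frequency grid
reduced to $\{0\}$.  Its fit is identical (to $<10^{-6}$ in $F$) to a
field fit with those settings imposed, which the tests assert.  Model
comparison reports $\Delta F = F_{\text{field}} - F_{\text{mass}}$ per
dataset with the conventional strong-evidence reading at
$|\Delta F| \ge 3$ (inclusive).

## Synthetic data: what it emulates and what it does not

`simulate_spectrum()` adds seeded Gaussian error per bin to the
noiseless prediction, floored at zero — the faithful reduction of
Gaussian error on real auto-spectra.  The default error scale is 3% of
the mean in-band power: the relative error of a spectral estimate
averaged over roughly a thousand degrees of freedom, as a multitaper
pipeline with ~180 trials and 7 tapers would produce.  We treat this as
"moderate" noise.  `simulate_timeseries()` synthesises a real series in
the frequency domain whose Welch spectrum (2 s Hann segments, 50%
overlap) converges to the analytic sensor spectrum — the package's
time-domain oracle; a 600 s simulation agrees within 10% RMS over
30–80 Hz, and the series variance matches the spectral integral
(Parseval).  `simulate_group_dataset()` draws multivariate-Gaussian
subject rows with a prescribed correlation matrix (Gaussian copula
only).  What the generators do *not* emulate: trial structure, spectral
leakage and taper bias, non-Gaussian or autocorrelated spectral errors,
head-model and beamformer effects, and any spatial sampling beyond the
single Gaussian lead field.  Passing tests therefore validate the
mathematics and the estimation machinery, not robustness to the many
ways real MEG deviates from the generative model.

`extract_gamma_peak()` fits a Gaussian (plus offset) to percentage
power change against a baseline, or to raw power, by
Levenberg–Marquardt least squares, and refuses spectra whose fitted
peak sits at the grid boundary or has no prominence above the residual
noise.

## Identifiability at the default operating point

A fact a user of the inversion should know: at the default (prior
mean) parameters the in-band 30–80 Hz spectrum is smooth and rising —
the system's resonance lies far above the band, because the
connectivity term $J$ dominates the temporal terms $B^2$, $\omega^2$
at these amplitudes.  Consequently the Jacobian of the 51-bin spectrum
with respect to the 17 free log-scalings has numerical rank of only
about 4–5: the spectral signature of any single parameter is (to
within $10^{-9}$ relative) a linear combination of the others', and
the signature of $a_{23}$ in particular is only ~0.1% of power per 0.4
log-units.  Individual parameter signs are therefore not identifiable
from a single in-band spectrum at this operating point — by any
inversion scheme, at any noise level: with self-generated data the
fitter reaches residuals below the noise floor at the minimum-norm
point of the data-compatible ridge rather than at the generating
parameters.  The test suite documents this honestly: a recovery
experiment perturbing `c_diag` (+0.4) and `a_23` (−0.4) recovers the
`c_diag` sign in most replicates (its broadband effect is ~11%) but the
`a_23` sign at chance level, so the joint-sign criterion fails while
the free-energy-monotonicity property holds in every run.  Inferences
about such parameters from real data should accordingly be read as
conditional on the prior and on group-level regularities, not as
per-subject point identification.

## Population statistics

`pearson_test()` refers $t = r\sqrt{(n-2)/(1-r^2)}$ to $t_{n-2}$;
`partial_correlation()` normalises the precision matrix of the
relevant submatrix and uses $df = n - 2 - \#\text{controls}$.  Tails
are an explicit argument everywhere — published analyses mix one- and
two-tailed reports, so nothing is inferred silently; one-tailed
p-values are taken in the direction of the observed sign.

`fit_path_model()` fits recursive standardised path models to a
correlation matrix by normal-theory maximum likelihood, treating the
correlation matrix as a covariance with divisor $n-1$ (the Wishart
form): the discrepancy $\ln|\Sigma(\theta)| + \mathrm{tr}(S
\Sigma(\theta)^{-1})$ is minimised by BFGS with a Nelder–Mead polish,
non-positive-definite candidates rejected; $\mathrm{AIC} = -2\ln L +
2k$.  Model-implied correlations come from standardising the implied
covariance — equivalent to path tracing for these recursive models.
The bundled group correlation matrix (n = 32, variables `width`,
`v1_size`, `a23`, `f`) ships as a plain-text fixture, and the model
space generator `gamma_path_models()` toggles the four edges into
`a23` and `f` over a fixed `v1_size -> width` backbone; the described
winning structure is `model8()`.

## Numerical choices

Fixed-point damping 0.5; kernel-transform denominators guarded at
$10^{-12}$ relative (a pole raises a classed condition with its
$(k,\omega)$ location); Jacobian step $10^{-3}$; LM damping multiplied
by 8 on rejection and 0.5 on acceptance; convergence $\Delta F <
10^{-2}$ four times in a row or 128 iterations; SEM candidates with an
implied-covariance eigenvalue below $10^{-10}$ rejected.  Problem
sizes used in the shipped experiments — 51 frequency bins, a 19-point
spatial grid, 20-replicate recovery and 10-replicate model-comparison
experiments, 600 s / 120 s time-series oracles — were chosen as the
smallest sizes at which the corresponding statistics are stable.

## Known limitations

One-dimensional isotropic kernels with a single fixed delay per unit
distance; real auto-spectra from one virtual channel (no cross-spectra
or multi-channel lead fields); linearised spectral predictions only;
no hierarchical (group-level) inversion; SEM restricted to observed
variables with AIC as the only comparison index.
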