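#' Stejskal-Tanner acquisition protocol
#'
#' Gradient timing and amplitude for the two-pulse spin-echo diffusion
#' sequence, from which the diffusion weighting is derived:
#' \eqn{q = \gamma G \delta} and \eqn{b = q^2 (\Delta - \delta/3)}.
#'
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1); default is the water
#'   proton value 2.6752e8.
#' @param G Diffusion gradient amplitude (T mm^-1).
#' @param delta Gradient pulse duration \eqn{\delta} (s).
#' @param Delta Gradient pulse separation \eqn{\Delta} (s); must satisfy
#'   `delta <= Delta`.
#' @return An object of class `"acquisition_protocol"`.
#' @export
acquisition_protocol <- function(gamma = 2.6752218744e8, G, delta, Delta) {
  stopifnot(gamma > 0, G >= 0, delta > 0, Delta > 0)
  if (delta > Delta) stop("delta must not exceed Delta")
  structure(list(gamma = gamma, G = G, delta = delta, Delta = Delta),
            class = "acquisition_protocol")
}

#' Effective diffusion time of the two-pulse sequence
#'
#' \eqn{t = \Delta - \delta/3}; e.g. \eqn{\Delta} = 41.2 ms, \eqn{\delta} =
#' 30.6 ms gives 31 ms.
#'
#' @param protocol An [acquisition_protocol()].
#' @return Effective diffusion time (s).
#' @export
effective_diffusion_time <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  protocol$Delta - protocol$delta / 3
}

#' @rdname b_value
#' @export
q_value <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  protocol$gamma * protocol$G * protocol$delta
}

#' Diffusion weighting of a protocol
#'
#' `q_value()` returns the spatial-frequency weighting \eqn{q = \gamma G \delta}
#' (mm^-1 when `G` is in T/mm); `b_value()` returns
#' \eqn{b = q^2(\Delta - \delta/3)} (s/mm^2). The two satisfy \eqn{b = q^2 t}
#' with `t` the [effective_diffusion_time()].
#'
#' @param protocol An [acquisition_protocol()].
#' @return `q` in mm^-1 or `b` in s/mm^2.
#' @export
b_value <- function(protocol) {
  q_value(protocol)^2 * effective_diffusion_time(protocol)
}

#' Length scale probed by a diffusion weighting
#'
#' The reciprocal spatial frequency \eqn{1/q} with \eqn{q = \sqrt{b/t}} (no
#' \eqn{2\pi} factor; this is the convention under which b = 4000 s/mm^2 at
#' t = 31 ms probes ~2.8 um and b = 500 probes ~7.9 um).
#'
#' @param b b-value (s/mm^2), > 0.
#' @param t Effective diffusion time (s), > 0.
#' @return Length (mm); vectorized over `b`.
#' @export
probe_length_scale <- function(b, t) {
  stopifnot(t > 0)
  if (any(b <= 0)) stop("length scale undefined at b = 0")
  1 / sqrt(b / t)
}

#' Net diffusion displacement
#'
#' Root-mean-square displacement \eqn{\sqrt{2 D t}} of free 1-D diffusion;
#' ~8 um for D = 1.0e-3 mm^2/s at t = 31 ms.
#'
#' @param D Diffusivity (mm^2/s), >= 0.
#' @param t Diffusion time (s), >= 0.
#' @return Length (mm).
#' @export
net_displacement <- function(D, t) {
  stopifnot(all(D >= 0), all(t >= 0))
  sqrt(2 * D * t)
}

#' Decay curve container
#'
#' One voxel's (or ROI's) diffusion decay: b-values and signal magnitudes.
#' Points are sorted by b; b must be non-negative without duplicates and
#' signals strictly positive.
#'
#' @param b b-values (s/mm^2).
#' @param signal Signal magnitudes (arbitrary units), same length as `b`.
#' @param s0 Reference signal at b = 0; defaults to the measured `signal` at
#'   `b == 0` when present, else the signal at the smallest b.
#' @return An object of class `"decay_curve"` with elements `b`, `signal`,
#'   `s0`.
#' @export
decay_curve <- function(b, signal, s0 = NULL) {
  stopifnot(is.numeric(b), is.numeric(signal), length(b) == length(signal))
  if (length(b) < 2L) stop("a decay curve needs at least 2 points")
  if (any(!is.finite(b)) || any(!is.finite(signal)))
    stop("non-finite values in decay curve")
  if (any(b < 0)) stop("b-values must be non-negative")
  if (any(signal <= 0)) stop("signals must be strictly positive")
  o <- order(b)
  b <- b[o]; signal <- signal[o]
  if (anyDuplicated(b)) stop("duplicate b-values")
  if (is.null(s0)) s0 <- if (b[1] == 0) signal[1] else signal[1]
  stopifnot(is.numeric(s0), length(s0) == 1L, s0 > 0)
  structure(list(b = b, signal = signal, s0 = s0), class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("decay curve: %d points, b in [%g, %g] s/mm^2, s0 = %g\n",
              length(x$b), min(x$b), max(x$b), x$s0))
  invisible(x)
}

#' Diffusion signal models
#'
#' Normalized signal decay S/S0 as a function of the diffusion weighting b
#' (s/mm^2):
#' \describe{
#'   \item{`model_mono`}{monoexponential \eqn{\exp(-bD)} (Gaussian
#'     diffusion).}
#'   \item{`model_mlf2`}{two-parameter Mittag-Leffler form
#'     \eqn{E_\alpha(-bD)} for time-fractional subdiffusion
#'     (\eqn{0 < \alpha \le 1}); reduces to `model_mono` at \eqn{\alpha = 1}.}
#'   \item{`model_mlf3`}{three-parameter form
#'     \eqn{E_\alpha(-(bD)^{\beta/2})} covering sub- and superdiffusion
#'     (\eqn{1 < \beta \le 2}); reduces to `model_mlf2` at \eqn{\beta = 2} and
#'     to the stretched exponential \eqn{\exp(-(bD)^{\beta/2})} at
#'     \eqn{\alpha = 1}.}
#'   \item{`model_dki`}{diffusional-kurtosis expansion
#'     \eqn{\exp(-bD + \frac{1}{6} b^2 D^2 K_{app})}; its exponent has an
#'     apex at \eqn{b^* = 3/(D K_{app})} beyond which the model increases
#'     with b, so the formula is computed as written and range policing is
#'     left to the fitting layer.}
#' }
#' The power \eqn{(bD)^{\beta/2}} is computed as
#' \eqn{\exp(\frac{\beta}{2}\ln bD)} with b = 0 short-circuited to 1.
#'
#' @param b b-values (s/mm^2); vectorized.
#' @param D Diffusivity (mm^2/s), > 0.
#' @param alpha Time-fractional order in (0, 1].
#' @param beta Space-fractional order in (1, 2].
#' @param K_app Apparent excess kurtosis (dimensionless).
#' @param config [mlf_config()] passed to the Mittag-Leffler evaluator.
#' @return Normalized signal values.
#' @name signal_models
NULL

#' @rdname signal_models
#' @export
model_mono <- function(b, D) {
  stopifnot(D > 0, all(b >= 0))
  exp(-b * D)
}

#' @rdname signal_models
#' @export
model_mlf2 <- function(b, D, alpha, config = mlf_config()) {
  stopifnot(D > 0, all(b >= 0))
  mittag_leffler(alpha, -b * D, config)
}

#' @rdname signal_models
#' @export
model_mlf3 <- function(b, D, alpha, beta, config = mlf_config()) {
  stopifnot(D > 0, all(b >= 0), beta > 1, beta <= 2)
  arg <- numeric(length(b))
  nz <- b > 0
  arg[nz] <- -exp((beta / 2) * log(b[nz] * D))
  mittag_leffler(alpha, arg, config)
}

#' @rdname signal_models
#' @export
model_dki <- function(b, D, K_app) {
  stopifnot(D > 0, all(b >= 0), is.finite(K_app))
  exp(-b * D + (b * D)^2 * K_app / 6)
}

#' Characteristic functions of the CTRW propagator
#'
#' The spatial Fourier transform p(q, t) of the displacement propagator in
#' the three closed-form regimes:
#' \describe{
#'   \item{`cf_general`}{\eqn{E_\alpha(-D_{\alpha,\beta} |q|^\beta t^\alpha)},
#'     arbitrary orders; `gd` supplies the generalized diffusion constant.}
#'   \item{`cf_subdiffusion`}{\eqn{E_\alpha(-D_{\alpha,2} q^2 t^\alpha)},
#'     time-fractional, \eqn{\beta = 2}.}
#'   \item{`cf_superdiffusion`}{\eqn{\exp(-D_{1,\beta} |q|^\beta t)},
#'     space-fractional, \eqn{\alpha = 1}.}
#' }
#' All equal 1 at q = 0 and collapse to the Gaussian
#' \eqn{\exp(-D q^2 t)} at \eqn{\alpha = 1, \beta = 2}.
#'
#' @param q Spatial frequency (mm^-1); vectorized.
#' @param t Diffusion time (s), >= 0.
#' @param gd A [generalized_diffusivity()].
#' @param D_a2,D_1b Generalized diffusion constants of the restricted forms
#'   (mm^2/s^alpha and mm^beta/s respectively).
#' @param alpha Order in (0, 1]; `beta` order in (1, 2].
#' @param beta Space-fractional order in (1, 2].
#' @param config [mlf_config()] for the Mittag-Leffler evaluations.
#' @return Characteristic-function values.
#' @name characteristic_functions
NULL

#' @rdname characteristic_functions
#' @export
cf_general <- function(q, t, gd, alpha, beta, config = mlf_config()) {
  stopifnot(inherits(gd, "generalized_diffusivity"), t >= 0,
            beta > 1, beta <= 2)
  mittag_leffler(alpha, -gd$D_ab * abs(q)^beta * t^alpha, config)
}

#' @rdname characteristic_functions
#' @export
cf_subdiffusion <- function(q, t, D_a2, alpha, config = mlf_config()) {
  stopifnot(D_a2 > 0, t >= 0)
  mittag_leffler(alpha, -D_a2 * q^2 * t^alpha, config)
}

#' @rdname characteristic_functions
#' @export
cf_superdiffusion <- function(q, t, D_1b, beta) {
  stopifnot(D_1b > 0, t >= 0, beta > 1, beta <= 2)
  exp(-D_1b * abs(q)^beta * t)
}

#' Generalized diffusion constant with its unit-preserving scales
#'
#' The generalized constant \eqn{D_{\alpha,\beta}} (mm^beta/s^alpha) relates
#' to the classical diffusivity \eqn{D_{1,2}} (mm^2/s) through the heuristic
#' length and time scales \eqn{\mu}, \eqn{\tau}:
#' \eqn{D_{\alpha,\beta} = D_{1,2}\, \tau^{1-\alpha} \mu^{\beta-2}}
#' (dimensional analysis fixes the exponent signs; \eqn{\mu} and \eqn{\tau}
#' enter only as a ratio against \eqn{D_{1,2}}). \eqn{\mu} and \eqn{\tau} are
#' user-supplied here; their independent estimation is outside this package.
#'
#' @param D_ab Generalized diffusion constant (mm^beta/s^alpha), > 0.
#' @param mu Length-scale parameter (mm), > 0.
#' @param tau Time-scale parameter (s), > 0.
#' @return An object of class `"generalized_diffusivity"`.
#' @export
generalized_diffusivity <- function(D_ab, mu = 1, tau = 1) {
  stopifnot(D_ab > 0, mu > 0, tau > 0)
  structure(list(D_ab = D_ab, mu = mu, tau = tau),
            class = "generalized_diffusivity")
}

#' Convert a generalized diffusion constant to classical units
#'
#' Applies \eqn{D^{\beta/2} = D_{\alpha,\beta}\, t^{\alpha - \beta/2}} (the
#' b-space reparameterization that makes the three-parameter signal model
#' depend only on D, alpha, beta) and then extracts
#' \eqn{D = (D^{\beta/2})^{2/\beta}} in mm^2/s. At \eqn{\alpha = 1,
#' \beta = 2} this returns \eqn{D = D_{1,2}} unchanged, and at
#' \eqn{\beta = 2, \tau = t} the two- and three-parameter model arguments
#' coincide.
#'
#' @param gd A [generalized_diffusivity()].
#' @param alpha Order in (0, 1]; `beta` order in (1, 2].
#' @param beta Space-fractional order in (1, 2].
#' @param t Effective diffusion time (s), > 0.
#' @return List with `D_pow` (\eqn{D^{\beta/2}}, (mm^2/s)^(beta/2)) and `D`
#'   (mm^2/s).
#' @export
generalized_to_classical <- function(gd, alpha, beta, t) {
  stopifnot(inherits(gd, "generalized_diffusivity"),
            alpha > 0, alpha <= 1, beta > 1, beta <= 2, t > 0)
  D_pow <- gd$D_ab * t^(alpha - beta / 2)
  list(D_pow = D_pow, D = D_pow^(2 / beta))
}

#' Classical diffusivity to the generalized constant
#'
#' Inverse companion of [generalized_to_classical()]:
#' \eqn{D_{\alpha,\beta} = D_{1,2}\,\tau^{1-\alpha}\mu^{\beta-2}}.
#'
#' @param D_12 Classical diffusivity (mm^2/s), > 0.
#' @param alpha Order in (0, 1]; `beta` order in (1, 2].
#' @param beta Space-fractional order in (1, 2].
#' @param mu Length scale (mm); `tau` time scale (s).
#' @param tau Time-scale parameter (s), > 0.
#' @return A [generalized_diffusivity()].
#' @export
generalized_from_classical <- function(D_12, alpha, beta, mu = 1, tau = 1) {
  stopifnot(D_12 > 0, alpha > 0, alpha <= 1, beta > 1, beta <= 2,
            mu > 0, tau > 0)
  generalized_diffusivity(D_12 * tau^(1 - alpha) * mu^(beta - 2),
                          mu = mu, tau = tau)
}
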