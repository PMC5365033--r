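---
title: "Anomalous-diffusion models for diffusion-weighted MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anomalous-diffusion models for diffusion-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlfdwi)
```

## The model

Water diffusion in tissue is rarely the free Gaussian process assumed by the
monoexponential decay $S/S_0 = \exp(-bD)$. The continuous-time random walk
(CTRW) picture generalizes the diffusion equation with fractional-order
derivatives: $\alpha \in (0,1]$ measures how heavy-tailed the waiting times
between molecular displacements are, and $\beta \in (1,2]$ how heavy-tailed
the displacements themselves. The characteristic function of the propagator
is then the Mittag-Leffler function (MLF)
$E_\alpha(z) = \sum_{k\ge0} z^k/\Gamma(\alpha k + 1)$, and after
re-expressing the generalized diffusion constant in classical units the
signal decay takes the parsimonious forms

* three-parameter: $S/S_0 = E_\alpha[-(bD)^{\beta/2}]$ (`model_mlf3()`),
* two-parameter (subdiffusion only, $\beta = 2$): $S/S_0 = E_\alpha(-bD)$
  (`model_mlf2()`),

with $D$ in mm²/s and $b$ in s/mm² throughout. Both reduce to the
monoexponential at $\alpha = 1$, $\beta = 2$. The two-parameter propagator
has closed-form moments, giving the excess kurtosis purely as a function of
the fractional order:

$$K_{MLF}(\alpha) = \frac{6\,\Gamma^2(\alpha+1)}{\Gamma(2\alpha+1)} - 3,$$

strictly decreasing from 3 (limit $\alpha \to 0$) to 0 ($\alpha = 1$)
(`kurtosis_from_alpha()`, inverse `alpha_from_kurtosis()`). This links
subdiffusion to diffusional kurtosis imaging (DKI),
$S/S_0 = \exp(-bD + \tfrac16 b^2D^2K_{app})$ (`model_dki()`), but without
DKI's parabolic-form restriction on the maximum $b$: the MLF is completely
monotone for all $b$, while the DKI exponent turns upward at
$b^* = 3/(DK_{app})$ (`dki_validity_check()` warns when sampled $b$ exceeds
it).

Unit bookkeeping for the generalized constant follows from dimensional
analysis: $D_{\alpha,\beta} = D_{1,2}\,\tau^{1-\alpha}\mu^{\beta-2}$, with
heuristic scales $\mu$ (mm) and $\tau$ (s). The extracted source renders the
$\mu$ exponent ambiguously; only $\mu^{\beta-2}$ gives
$D_{\alpha,\beta}$ its units of mm$^\beta$/s$^\alpha$, and it reproduces the
required identities ($D_{\alpha,\beta} = D_{1,2}$ at $\alpha=1,\beta=2$; the
two- and three-parameter forms coinciding at $\beta=2$, $\tau=t$), both of
which are tested numerically. $\mu$ and $\tau$ are user-supplied; their
independent estimation is outside this package's scope.

## Mittag-Leffler numerics

`mittag_leffler(alpha, z)` targets a relative accuracy of `tolerance`
(default 1e-10) on the negative real axis and combines three routes:

1. **Taylor series** with Kahan-compensated accumulation for
   $|z| \le$ `series_radius` (default 5). The alternating series loses
   roughly one digit per decade of its largest term, so the series is also
   skipped whenever the predicted peak term (near
   $k^* = x^{1/\alpha}/\alpha$) would push the cancellation error above
   tolerance — which happens well inside the radius for small $\alpha$.
2. **Large-argument expansion**
   $E_\alpha(-x) \sim \sum_k (-1)^{k+1}x^{-k}/\Gamma(1-\alpha k)$, accepted
   only when the optimally truncated remainder is safely below tolerance.
   Terms are computed through the reflection formula; the divergence test
   and remainder estimate use the $\sin$-free envelope
   $\Gamma(\alpha k)x^{-k}/\pi$, because $\sin(\pi\alpha k)$ vanishes at
   the $\Gamma$ poles (every even term at $\alpha = 1/2$) and would
   otherwise fake convergence.
3. **Spectral integral.** For everything else the complete-monotonicity
   representation
   $E_\alpha(-x) = \frac{\sin\alpha\pi}{\alpha\pi}\int_0^\infty
   \frac{e^{-(ux)^{1/\alpha}}}{u^2+2u\cos\alpha\pi+1}\,du$
   is integrated adaptively with breakpoints on the exponential shoulder
   and around the near-pole at $u = 1$, whose width shrinks like
   $\sin\pi\alpha$ as $\alpha \to 1$.

$\alpha = 1$ routes to `exp()` exactly; $\alpha < 0.01$ is clamped (with a
warning) away from the $\Gamma$-pole region; positive arguments are
supported only inside the series region, which covers every use in this
package.

`mittag_leffler_oracle()` is the independent yardstick: trapezoid quadrature
of the inverse-Laplace (Hankel) contour integral
$\frac{1}{2\pi i}\oint e^s s^{\alpha-1}/(s^\alpha - z)\,ds$ on a parabolic
contour $s(u) = \mu(1+iu)^2$. The contour scale is kept small
($\mu = 4$) so the round-off amplification $e^\mu\epsilon$ stays below the
discretization error; the step and truncation are balanced for ~1e-13
absolute error, giving at least 12 significant digits on
$z \in [-50, 0]$ where $E_\alpha(-x) \gtrsim 10^{-4}$. A direct
arbitrary-precision summation of the defining series is not viable here:
at $\alpha = 0.1$, $z = -30$ the peak term is ~$e^{945}$, which would
require a thousand-digit mantissa. The contour route shares no code or
mathematics with the three evaluation routes above, and both are checked
against the closed forms $E_1 = \exp$ and
$E_{1/2}(-x) = e^{x^2}\mathrm{erfc}(x)$.

## Moments and kurtosis

The subdiffusion propagator's moments,
$\langle x^2\rangle = 2D_{\alpha,2}t^\alpha/\Gamma(\alpha+1)$ and
$\langle x^4\rangle = 24D_{\alpha,2}^2t^{2\alpha}/\Gamma(2\alpha+1)$, are
implemented directly; $D$ and $t$ cancel exactly in the kurtosis, which the
test suite asserts to 1e-12. Two independent cross-checks guard the algebra:

* `kurtosis_oracle_from_cf()` differentiates the characteristic function at
  $q = 0$ numerically (5-point stencil for $m_2$, 7-point for $m_4$, steps
  scaled to the CF width $q_0 = (Dt^\alpha)^{-1/2}$ and sized by the usual
  $h \sim \epsilon^{1/(p+d)}$ balance), agreeing with the closed forms to
  ~1e-5;
* `kurtosis_of_pdf()` recovers the textbook reference kurtoses by
  quadrature (Gaussian 3; hyperbolic secant 5).

`kurtosis_from_alpha()` and `goychuk_ratio()` (the mean-position scaling
ratio, identically $K_{MLF}/3$) are plain log-gamma arithmetic and stable on
all of $(0,1]$, so they accept the full domain rather than clamping at
0.01 — the $\alpha \to 0$ limit is exported as the constant
`kurtosis_alpha0_limit` (= 3). The clamp matters where estimation is
involved, and is applied there: the fitting bounds and the MLF evaluator.

## Fitting

`fit_curve()` follows the estimation pipeline used for the in vivo data:
Rician bias correction $S_{rn} = \sqrt{S^2 - 2\sigma^2}$ (per-volume scalar
$\sigma$ or a per-b vector; points at or below the floor are zeroed,
flagged, and excluded from the fit), normalization by the measured
$S(b=0)$, and bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`). Choices the source leaves open, fixed here as
defaults:

* bounds $D \in (10^{-5}, 10^{-1})$ mm²/s, $\alpha \in [0.01, 1]$,
  $\beta \in (1, 2]$, $K_{app} \in [0, 10]$;
* starting values: $D_0$ from the two-point ADC formed with the smallest
  nonzero $b$; $\alpha_0 = 0.9$, $\beta_0 = 1.9$, $K_0 = 0.5$; up to five
  seeded, jittered restarts on non-convergence, after which the result is
  returned flagged rather than raising;
* $S_0$ is pinned to the measured $b=0$ signal by default; `fit_s0 = TRUE`
  fits a multiplicative scale instead;
* a non-converged voxel is reported, not hidden: `FitResult$converged`,
  the sidecar's convergence counts, and the `converged` map.

`fit_maps()` applies this voxelwise over a 4-D stack (4th axis = volumes,
matched against the b-value table; direction-averaged input assumed; voxels
outside the mask are `NA`), and `two_point_adc()` supplies the classical
$\ln(S_0/S)/b$ reference map at $b = 1000$ s/mm².

**How good can the fit be?** At the study design — b = {0, 500, 1000, 3000,
4000} s/mm², SNR 40 — the Cramér-Rao bound for the normalized two-parameter
MLF fit already implies a median $|\hat\alpha - \alpha|$ of ~0.11 in white
matter and ~0.06 in gray matter (the bound must include the rank-one noise
term from dividing by the measured $S(b=0)$, which inflates errors ~30%
over the naive i.i.d. bound). The recovery property test therefore checks
*efficiency* — median errors within 1.4× the bound-implied medians over 100
noisy curves per tissue per model — rather than an absolute error that no
estimator could reach; class-*mean* recovery on the phantom (which averages
256 voxels per tissue) is held to ±0.05 in $\alpha$. The noisy-recovery
test covers the three models actually fitted to decay data (mono, mlf2,
dki); three-parameter recovery from five b-values is ill-conditioned in
$\beta$ and is exercised instead by the noise-free boundary test
(mlf3 on $\beta = 2$ data matches mlf2 to 1e-4).

## The random-walk simulator

`simulate_walks()` generates one-dimensional CTRW sample paths: waiting
times then jumps, cumulative in time and space, the walker holding its
position between events. The four regimes are selected by the two laws:
Gaussian/Gaussian (Brownian), Pareto waits/Gaussian jumps (time-fractional,
MSD $\propto t^\alpha$), Gaussian waits/Pareto jumps (space-fractional),
Pareto/Pareto (both, drawn independently — no coupling option). Conventions:

* Pareto survival exponents are $-\alpha$ (waits) and $-\beta$ (jump
  magnitudes) — the standard CTRW reading, under which the governing orders
  and the $t^\alpha$ MSD law are recovered; the literal reciprocal reading
  of the power-law expressions is available via
  `exponent_convention = "reciprocal"`;
* "Gaussian waiting times" are realized as $|N(0,1)|$ so increments are
  positive — a Gaussian is not literally a waiting-time law;
* the scale constant $c = 1$ by default, making the Brownian
  distance-vs-time square-root relationship directly visible;
* jumps are zero-mean either by symmetric random sign (default) or by
  subtracting the one-sided mean $c\beta/(\beta-1)$;
* each walker consumes its own L'Ecuyer-CMRG substream
  (`parallel::nextRNGStream`) derived from the master seed, so runs are
  bit-reproducible and growing the ensemble leaves existing walkers
  unchanged.

For Pareto jumps the variance is infinite and the plain MSD does not
converge; `quantile_width()` reports the central 90% spread of $x(t)$
instead. `msd_exponent()` fits the MSD growth exponent on log-log axes with
a bootstrap-over-walkers confidence interval. For Pareto waiting times the
ensemble MSD equals the jump variance times the renewal function, whose
expansion carries a slowly decaying correction
$MSD(t) = Ct^g(1 + rt^{g-1}) + \dots$; at horizons reachable with $10^3$
events per walker the plain log-log slope is biased low by several
hundredths, so for those regimes the one-term correction is fitted
alongside the exponent (`correction = "auto"`). For Gaussian waits no such
term exists (and it is unidentifiable at $g = 1$), so the plain slope is
used. This is a statement about estimator design, not a tuned constant: the
correction exponent is fixed by renewal theory.

## The synthetic phantom

`make_phantom()` emulates the acquisition: b = {0, 500, 1000, 3000, 4000}
s/mm², four tissue classes (white matter, gray matter, chronic ischemic
tissue, CSF) with the fitted ROI means of `brain_roi_reference` as
generator parameters, $S_0 = 1000$, and Rician magnitude noise
$\sqrt{(S+n_1)^2+n_2^2}$ of chosen $\sigma$ (the study's SNR corresponds to
$\sigma = S_0/40$). The default geometry is four equal rectangular slabs in
a 16×16×4 grid — 256 voxels per class, enough for stable class means while
keeping a full voxelwise fit under half a minute. Generator modes `mlf2`
(default; class $\alpha$, $D_{MLF}$), `dki` ($D_K$, $K_{app}$) and `mono`
(ADC) enable cross-model comparisons.

What the phantom does *not* emulate — and what passing tests therefore do
not show about real data: anatomical geometry and partial-volume mixing,
spatially varying multi-coil noise (a homogeneous $\sigma$ is assumed, as
in the original correction, which its authors already called a limited
approach), motion/eddy artifacts, and any directional dependence (input is
direction-averaged; tensor extensions are out of scope). Recovery on the
phantom validates the estimation machinery, not the biological claims.

Degenerate inputs are handled explicitly: voxels whose corrected curves
keep fewer points than parameters (CSF-like decays at high $b$ fall under
the noise floor) raise input errors in `fit_curve()` and become `NA` voxels
with a failure count in `fit_maps()`.

## Problem sizes and runtimes

The test suite runs the full voxelwise pipeline on the default 16×16×4
phantom (noise-free and at SNR 40), 100-curve-per-condition recovery
ensembles, and CTRW ensembles up to $10^4$ walkers × $10^3$ events for the
exponent-recovery checks ($\alpha \in \{0.5, 0.75, 1\}$); the whole suite
completes in about a minute on one core. Seeds fix every stochastic
fixture. The 95% bootstrap confidence intervals in the exponent checks are,
by construction, expected to exclude the truth for ~1 seed in 20; the
committed seeds are the package defaults, not a search result.

## Known limitations

* The MLF evaluator is restricted to real arguments and orders in (0, 1];
  two-parameter MLFs, complex arguments and $\alpha > 1$ oscillatory
  regimes are out of scope.
* Positive arguments are supported only within the series region.
* The space-fractional propagator has no finite second moment, so no MSD-
  based quantities are offered for it (the interquantile width is the
  supported spread measure).
* $\sigma$ estimation from anatomy (e.g. an automatic ventricle ROI) is not
  provided; `estimate_sigma()` needs user-selected voxels and assumes
  either the high-SNR or the background regime.
* The DKI implementation is the isotropic scalar form; no tensor estimation.
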