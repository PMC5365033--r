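# mlfdwi

Anomalous-diffusion modelling of diffusion-weighted MRI signal decay, for
researchers fitting multi-b-value brain data beyond the monoexponential
regime. In tissue, water diffusion is hindered by microstructure and the
decay of the (direction-averaged) signal with the diffusion weighting
*b* is non-Gaussian. The continuous-time random walk (CTRW) framework
captures this with two fractional orders — α ∈ (0, 1] for heavy-tailed
waiting times (subdiffusion) and β ∈ (1, 2] for heavy-tailed jumps
(superdiffusion) — and the Mittag-Leffler function (MLF)
E<sub>α</sub>(z) = Σ<sub>k</sub> z<sup>k</sup>/Γ(αk + 1) as the
characteristic function of the propagator.

The package implements the parsimonious fitting forms

* **mlf3**: S/S₀ = E<sub>α</sub>[−(bD)<sup>β/2</sup>]
* **mlf2** (subdiffusion, β = 2): S/S₀ = E<sub>α</sub>(−bD)
* **dki**: S/S₀ = exp(−bD + ⅙ b²D² K<sub>app</sub>)
* **mono**: S/S₀ = exp(−bD)

together with the analytic bridge between subdiffusion and kurtosis,

&nbsp;&nbsp;&nbsp;&nbsp;K<sub>MLF</sub>(α) = 6 Γ²(α+1)/Γ(2α+1) − 3,

which maps a fitted α directly to the excess kurtosis of the propagator
(0 at α = 1, → 3 as α → 0) with no maximum-b restriction — unlike DKI,
whose parabolic exponent turns upward at b\* = 3/(D·K<sub>app</sub>).

What's inside:

* a validated MLF evaluator (series / asymptotic / spectral-integral
  routes) plus an independent Hankel-contour reference implementation for
  testing (`mittag_leffler()`, `mittag_leffler_oracle()`);
* pulse-sequence arithmetic for the two-pulse Stejskal-Tanner experiment:
  b = (γGδ)²(Δ − δ/3), q-values, probed length scales, net displacement;
* propagator moments, kurtosis conversions and their numerical oracles;
* Rician noise correction, bounded Levenberg-Marquardt curve fits and
  voxelwise parameter maps from 4-D NIfTI (`fit_curve()`, `fit_maps()`);
* a 1-D CTRW Monte Carlo simulator with Pareto waiting-time/jump laws and
  MSD exponent estimation (`simulate_walks()`, `msd_exponent()`);
* a synthetic multi-b-value brain phantom with WM/GM/ischemic/CSF tissue
  classes for end-to-end validation without patient data
  (`make_phantom()`).

## Worked example

Generate a noisy four-tissue phantom at the study acquisition
(b = 0, 500, 1000, 3000, 4000 s/mm², S₀ = 1000, Rician σ = 25, i.e.
SNR 40), fit the two-parameter MLF model voxelwise, and summarize by
tissue class:

```r
library(mlfdwi)

spec    <- phantom_spec(sigma = 25, seed = 42)
phantom <- make_phantom(spec)
maps    <- fit_maps(phantom$stack, spec$b_values, model = "mlf2",
                    noise = noise_model(25), seed = 42)
maps
#> parameter maps: model mlf2, grid 16x16x4, 1024 voxels fitted (28 failed)
#>   alpha  mean 0.7209  sd 0.252
#>   D      mean 0.002312  sd 0.00181
#>   K_mlf  mean 0.9154  sd 0.82
#>   adc    mean 0.001766  sd 0.00106

class_summary(maps, phantom$truth, labels = brain_roi_reference$roi)[,
  c("class", "alpha_mean", "alpha_sd", "D_mean", "K_mlf_mean")]
#>   class alpha_mean alpha_sd   D_mean K_mlf_mean
#> 1    WM      0.474    0.181 0.000733      1.768
#> 2    GM      0.769    0.098 0.000981      0.752
#> 3   IT      0.822    0.256 0.003748      0.565
#> 4   CSF      0.830    0.249 0.003963      0.535
```

The white- and gray-matter class means recover the generator values
(α = 0.49 / 0.77, D = 0.72e-3 / 0.97e-3 mm²/s) to a few hundredths; the
fast-diffusing classes (ischemic tissue, CSF) lose their high-b points to
the noise floor — their curves drop under σ by b = 3000 s/mm² — which is
why their α means drift and the 28 unfittable voxels are reported rather
than hidden. The derived kurtosis column is the analytic conversion of the
fitted α:

```r
kurtosis_from_alpha(0.77)   # 0.7433
alpha_from_kurtosis(1.75)   # 0.4897
```

Protocol arithmetic for the acquisition timing (Δ = 41.2 ms,
δ = 30.6 ms):

```r
p <- acquisition_protocol(G = 4e-5, delta = 30.6e-3, Delta = 41.2e-3)
effective_diffusion_time(p)        # 0.031 s
probe_length_scale(4000, 0.031)    # 2.78e-3 mm  (~2.8 um at b = 4000)
probe_length_scale(500, 0.031)     # 7.87e-3 mm  (~7.9 um at b = 500)
net_displacement(1.0e-3, 0.031)    # 7.87e-3 mm  (~8 um)
```

A thin command-line front end covers the same pipeline
(`fit`, `phantom`, `simulate`, `protocol`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mlfdwi.R", package = "mlfdwi"))')
Rscript $CLI fit --dwi dwi.nii.gz --bvals bvals.txt --mask mask.nii.gz \
                 --model mlf2 --sigma 25 --out maps/
```

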