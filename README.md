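# pcct

Statistical iterative reconstruction (SIR) for grating-based X-ray
phase-contrast computed tomography, with a full synthetic acquisition
chain: Talbot-Lau phase-stepping simulation, weighted least-squares
signal retrieval with variance propagation, analytic filtered
backprojection baselines, and an absorption-derived bone prior that
suppresses phase-wrapping ("bone") streak artifacts.

## The problem

A grating interferometer delivers three perfectly registered signals per
ray — absorption, differential phase contrast (DPC), and dark field —
by fitting the phase-stepping curve
`I(x_g) = a0 + a1 cos(2*pi*x_g/k + phi1)` in every detector pixel and
normalizing against a flat-field scan. DPC tomography maps the
refractive index decrement `delta` with far better soft-tissue contrast
than attenuation, but the measured fringe phase is confined to
`[-pi, pi)`. At bone rims the phase gradient wraps, and behind bone the
beam is starved so noise wraps measurements statistically; filtered
backprojection turns both into streaks that bury soft-tissue detail.

## The estimator

`reconstruct_sir()` minimizes a penalized weighted least-squares
objective over the phase volume `rho`:

```
Phi(rho) = sum_rays w (s - D A rho)^2
         + lambda_Q sum_j sum_{k in N(j)} (rho_j - rho_k)^2          (whole volume)
         + lambda_H sum_{j in soft} sum_{k in N(j)} psi_t(rho_j - rho_k)
         + lambda_B sum_{j in bone} (rho_j - c rho_a_j)^2
```

with `A` the parallel-beam projector, `D` the detector-axis derivative,
`psi_t` the Huber potential, and `rho_a` the absorption reconstruction.
The weights `w = m / sigma^2` combine the per-ray variances from the
stepping-curve fit with a modification `m` in `[0, 1]` built from the
absorption image (segment dense material, take the boundary-gradient
magnitude, forward-project, normalize, invert), so rays likely to be
phase-wrapped are removed from the data term. The bone mask couples the
phase values inside dense material to the absorption image through the
`delta/mu` constant `c`. A Polak-Ribiere+ nonlinear conjugate-gradient
solver with Armijo backtracking guarantees a monotone objective trace.

## Worked example

```r
library(pcct)

ph    <- default_phantom(96)                       # water bath, soft body, 2 bone inserts
cfg   <- acquisition_config(n_angles = 144, seed = 1)
scans <- simulate_stepping_scan(ph, cfg)           # Poisson stepping frames + flat field
sig   <- extract_signals(scans$sample, scans$reference)

mu    <- fbp_absorption(-log(pmax(sig$transmission, 1e-6)), sig$geometry)
prior <- bone_prior(mu, sig$geometry)              # masks + weight modification m
fbp   <- fbp_dpc(sig$dphase, sig$geometry)         # Hilbert-filter FBP baseline

fit <- reconstruct_sir(sig, control = sir_control(
         bone_coupling = default_bone_coupling(cfg), max_iters = 100),
       prior = prior, rho_a = mu)
fit
#> Statistical iterative phase-contrast CT reconstruction
#>   image: 96 x 96 pixels; 144 views
#>   lambda_q = 30, lambda_h = 1000 (t = 0.02), lambda_b = 1000
#>   100 iterations, objective 203767 -> 21219.7

roi <- default_soft_roi(96)
c(sigma_fbp = sd(fbp$values[roi$i, roi$j]),
  sigma_sir = sd(coef(fit)[roi$i, roi$j]))
#>  sigma_fbp  sigma_sir
#> 0.01736498 0.00610708
```

The ROI standard deviations quantify streak + noise in a homogeneous
soft-tissue patch: here SIR reduces it by a factor 2.8 while
`plot(fit)` shows the bone inserts restored instead of blown out. `to_delta(fit$rho,
calibration = 1/cfg$fringe_scale)` converts the volume to refractive
index decrement units, adding the water-bath offset back
(soft tissue then sits in the usual `delta = [4.07, 5.07] x 1e-7`
display window).

The same pipeline runs from the shell over file artifacts (TIFF + JSON
sidecars, YAML config):

```sh
Rscript inst/cli/pcct.R pipeline --out run1 --seed 1
Rscript inst/cli/pcct.R report --out run1
```

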