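# speckletrack

Wave-optics simulation and sub-pixel tracking of x-ray near-field speckle.

Speckle-based x-ray phase-contrast imaging (XPCI) senses the phase shift a
sample imprints on an x-ray wavefront by watching how it displaces a random
speckle pattern created by a diffuser (stacked sandpaper). In single-shot
speckle tracking, one reference image `I_r` (no sample) and one sample image
`I_s` are compared to recover the per-pixel transverse displacement
`u(x, y)` in detector pixels, which is proportional to the refraction angle
`alpha = u p / d` (pixel pitch `p`, effective sample-to-detector distance
`d`) and hence to the phase gradient via
`(dPhi/dx, dPhi/dy) = (2 pi / lambda) alpha`.

The package is aimed at people developing or benchmarking speckle-tracking
algorithms: it contains the whole loop, so every tracker can be scored
against exact ground truth.

* **Simulator** — angular-spectrum wave propagation, projection-approximation
  objects, a stacked-sandpaper diffuser model, divergent-beam geometry via
  the Fresnel scaling theorem, source blur, detector PSF and pixel
  integration (`imaging_geometry()`, `diffuser_spec()`, `simulate_pair()`).
* **Deformation datasets** — piecewise-bilinear sub-pixel displacement
  fields in [-1, 1] px, cubic-interpolation warping, patchwise 50–100%
  transmission, Poisson noise, manifest-driven reproducible dataset
  building (`generate_deformation()`, `warp()`, `build_dataset()`).
* **Trackers** — windowed zero-normalized cross-correlation with Gaussian
  sub-pixel peak fitting, windowed least-squares UMPA with closed-form
  transmission and paraboloid refinement (`speckle_track()`), and CADE, a
  full-resolution convolutional displacement network with a multiscale
  endpoint-error loss, trained by a self-contained base-R engine
  (`cade_network()`, `cade_train()`, `predict()`).
* **Evaluation** — constant-shift accuracy (bias, RMSE), star-pattern
  limiting spatial resolution at 10% bias, noise and window-size sweeps,
  timing, and a sine-wave PMMA refraction phantom
  (`accuracy_sweep()`, `spatial_resolution()`, `run_phantom_validation()`).

## Worked example

```r
library(speckletrack)

geom <- imaging_geometry()            # 30 keV, diffuser 1 m, detector 3 m, 12 um px
pair <- simulate_pair(geom, diffuser_spec(seed = 7), shape = c(128L, 128L), seed = 7)
pair
#> <speckle_pair 128 x 128, visibility 0.239, no sample>

ref <- pair$reference
field <- constant_field(c(128L, 128L), ux = 0.3, uy = -0.15)   # ground truth
sam <- add_poisson_noise(warp(ref, field), 1e4, seed = 1)

fit <- speckle_track(add_poisson_noise(ref, 1e4, seed = 2), sam, method = "zncc")
fit
#> <speckle_track ZNCC, 128 x 128, 51.7% valid, window 31x31>
#>   ux: mean 0.2962  sd 0.0190   uy: mean -0.1484  sd 0.0165 (valid px)

rmse(fit$displacement, field, mask = fit$valid_mask)
#>         ux         uy   combined
#> 0.01942606 0.01659606 0.01806656
```

The printed `ux`/`uy` means recover the applied (0.3, -0.15) px shift to
better than 0.005 px; the per-pixel RMSE of ~0.018 px is the combined
sub-pixel interpolation and photon-noise error at this fluence — the same
error regime the accuracy protocol reports over the full 0–1 px sweep.

`summary(fit, truth = field)`, `residuals(fit, field)` and `plot(fit)` give
the usual model-object views; `run_phantom_validation()` produces the
end-to-end refraction comparison for the sine phantom.

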