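# fluctrack

Fluorescence fluctuation spectroscopy and vesicle tracking for two-photon
time-lapse microscopy — with a synthetic-data engine so every estimator in
the chain can be validated against known ground truth.

## What it does

Sterol-carrying vesicles in living cells move by a mixture of anomalous
subdiffusion (crowded cytoplasm, cytoskeletal caging) and directed,
motor-driven transport. Quantifying that motion from photon-limited
two-photon movies takes several complementary tools, all of which this
package implements:

- **Synthetic data** (`simulate_fbm_trajectories()`,
  `simulate_vesicle_ensemble()`, `simulate_binding_diffusion()`,
  `simulate_monomer_stack()`, `render_raster_stack()`,
  `render_vesicle_spots()`, `render_trajectory_stack()`) — exact
  fractional Brownian motion (FBM) with optional constant drift, a
  Brownian-dynamics reaction–diffusion simulation of monomers binding to
  slow vesicle-like structures, and photon-count renderers for snapshot
  and raster-scan acquisition with Poisson shot noise.
- **Image correlation spectroscopy** — temporal autocorrelation and
  diffusion fitting (TICS: `temporal_autocorrelation()`,
  `fit_tics_diffusion()`, `tics_diffusion_map()`), raster-scan spatial
  autocorrelation and model fitting (RICS: `rics_autocorrelation()`,
  `fit_rics()`), number & brightness moment analysis
  (`number_and_brightness()`), and photobleaching quantification
  (`bleach_curve()`).
- **Particle tracking** — registration (`register_translation()`),
  denoising (`denoise_stack()`), Laplacian-of-Gaussian spot enhancement
  and sub-pixel detection (`spot_enhance()`, `detect_spots()`), greedy
  gap-bridging linking (`link_trajectories()`, `interpolate_gaps()`), and
  vesicle sizing by 2D Gaussian fitting (`fit_spot_gaussian()`,
  `fit_spots()`).
- **MSD analysis** — time-averaged and ensemble mean square displacement
  (`compute_msd()`, `ensemble_msd()`), the combined model
  `MSD(t) = 4 D_α t^α + v² t²` with weighted multistart fitting
  (`fit_subdiffusion_ballistic()`), log-log slopes (`loglog_slope()`),
  end-to-end distances and displacement covariance.
- **Pipeline & I/O** — 16-bit TIFF stacks with plain-text metadata
  sidecars (`write_stack()`/`read_stack()`), schema-versioned trajectory
  CSVs (`write_trajectories()`/`read_trajectories()`), red/green temporal
  overlays (`temporal_overlay()`), and a seeded, logged
  simulate → render → track → fit pipeline (`run_pipeline()`).

Results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods, so everything drops straight into a tidyverse
workflow.

## Worked example: recover motion parameters from a simulated ensemble

```r
library(fluctrack)

p  <- motion_params(D_alpha = 1.95e-3, alpha = 0.62, v = 5.52e-3,
                    h = 1.05, n_steps = 100)
tr  <- simulate_vesicle_ensemble(200, p, seed = 42)
fit <- fit_subdiffusion_ballistic(ensemble_msd(tr))
fit
#> <anomalous_fit> MSD(t) = 4 D_a t^a + v^2 t^2
#>   D_alpha = 0.001991 um^2/s^a (std 6.6e-06)
#>   alpha   = 0.6247 (std 0.0019)
#>   v       = 0.005319 um/s (std 2.3e-05)
#>   91 lags in [1.05, 95.5] s, weights: 1/stderr^2

broom::tidy(fit)
#> # A tibble: 3 × 5
#>   term    estimate        std ci95_lower ci95_upper
#>   <chr>      <dbl>      <dbl>      <dbl>      <dbl>
#> 1 D_alpha  0.00199 0.00000659    0.00198    0.00200
#> 2 alpha    0.625   0.00195       0.621      0.629
#> 3 v        0.00532 0.0000231     0.00527    0.00536

autoplot(ensemble_msd(tr), fit = fit)   # log-log MSD with model overlay
```

The full chain — render the ensemble as a noisy photon-count movie, track
the spots back out of it, and refit the motion model — runs with one
call:

```r
report <- run_pipeline(list(seed = 11, out_dir = "run1"))
report$status              # "ok"
report$n_tracks_recovered  # 32 of 40
report$fit                 # alpha ~ 0.69, D_alpha ~ 2.1e-3, v ~ 5.7e-3
list.files("run1")
#> ground_truth.csv  movie.tif  movie.tif.meta  msd.csv  report.json
#> run.log  tracked.csv
```

Everything in `run1/` is reproducible bit for bit from the seed recorded
in `report.json`.

## Documentation

The methods vignette (`vignettes/fluctrack-methods.Rmd`) describes the
models, default parameters and units, the numerical choices behind each
estimator, and their limitations. Every exported function has reference
documentation with the estimator equations.
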