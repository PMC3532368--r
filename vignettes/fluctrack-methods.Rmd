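---
title: "Models and methods in fluctrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fluctrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctrack)
```

fluctrack quantifies the intracellular motion of fluorescent vesicles and
monomers from two-photon time-lapse movies. This vignette documents the
underlying models, the default parameters and their units, the numerical
choices behind each estimator, and the limits within which each method is
reliable. Units are micrometers and seconds throughout; images are photon
counts (dimensionless non-negative integers).

## 1. Motion model

Vesicle motion is modeled as two independent components,

$$\mathrm{MSD}(t) \;=\; 4\,D_\alpha\, t^{\alpha} \;+\; v^2 t^2,$$

a 2D fractional-Brownian-motion (FBM) term with anomalous exponent
$\alpha$ and generalized diffusion constant $D_\alpha$
(units $\mu m^2/s^{\alpha}$), plus directed transport at constant
velocity $v$. For $\alpha < 1$ the first term is subdiffusive; the
$t^2$ term dominates at late lags, so the log-log slope of the MSD
crosses over from $\alpha$ toward 2 — superdiffusion driven by active
transport.

### Exact FBM simulation

`simulate_fbm_trajectory()` draws fractional Gaussian noise exactly via
the Cholesky factor of the increment covariance
$\gamma(k) = \tfrac12\big(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\big)$ with
Hurst exponent $H = \alpha/2$, independently per axis, scaled so the 2D
MSD is exactly $4 D_\alpha t^\alpha$ at every lag. Cholesky is $O(n^3)$
in the number of steps but exact; typical tracks (hundreds of steps)
factor in milliseconds, and the factor is reused across an ensemble.
Drift is added afterwards as a deterministic shift $v\,t$ along a unit
direction (`add_drift()`); `simulate_vesicle_ensemble()` draws a random
direction per track unless one is fixed.

`motion_presets()` ships three parameter sets (a control and two
cytoskeleton-disruption conditions) used by the examples, the pipeline
defaults and the validation suite.

### MSD estimation and fitting

`compute_msd()` is the overlapping time-averaged estimator
$\mathrm{MSD}(nh) = \frac{1}{N-n}\sum_i (\mathbf r_{i+n}-\mathbf r_i)^2$;
`ensemble_msd()` averages it across tracks and reports the across-track
standard error. Overlapping squared displacements are correlated, so the
per-track `stderr` is a dispersion diagnostic, not an exact standard
error — which is why the ensemble fit weights by the *across-track*
scatter.

`fit_subdiffusion_ballistic()` fits the combined model by
Levenberg–Marquardt least squares with weights $1/\mathrm{stderr}^2$
(uniform when no errors are available, e.g. analytic curves). Because
$D_\alpha$ and $\alpha$ are strongly correlated, the optimizer is
multistarted over $\alpha \in \{0.4, 0.7, 1.0\}$ and the lowest weighted
SSE wins deterministically. Parameter spread is reported as `std`,
derived from the 95% confidence interval as
$(CI_{97.5} - \hat\theta)/1.96$. Limitations: lags comparable to the
track length are noisy and should be excluded (`lag_range`); $v$ and
$D_\alpha$ become degenerate when $\alpha \to 2$.

`loglog_slope()` fits $\log \mathrm{MSD}$ vs $\log t$ over the last
third of the lag axis by default, exposing the superdiffusive crossover.

## 2. Photon-count image formation

All renderers share one detection model: a particle with brightness
$\varepsilon$ (photons per particle per pixel dwell at beam center)
contributes a 2D Gaussian intensity profile, and the recorded count in a
pixel is Poisson with that mean. The two-photon excitation profile
$\exp(-4 r^2/\omega_0^2)$ is equivalent to a Gaussian with
$\sigma = \omega_0 / (2\sqrt2)$; the default beam waist
$\omega_0 = 0.24\,\mu m$ corresponds to a measured point-spread-function
FWHM of $0.28\,\mu m$ via $\omega_0 = \mathrm{FWHM}/\sqrt{2\ln 2}$.

- `render_snapshot_stack()` samples the whole frame at one instant —
  appropriate for camera-like acquisition and for TICS.
- `render_raster_stack()` advances every particle's Brownian position to
  the exact acquisition time of *each pixel* (`scan_params()`: pixel time
  `tau_p`, line time `tau_l`, frame time), so the rendered frames carry
  the pixel-clock correlations that RICS exploits. The scan timing must
  satisfy `tau_p < tau_l < frame_time` and `tau_l >= ncol * tau_p`
  (otherwise the pixel clock would overrun the line).
- `render_vesicle_spots()` and `render_trajectory_stack()` draw spots of
  specified FWHM — for sizing and tracking validation, where the spot
  width stands for vesicle size convolved with the PSF.
- `simulate_monomer_stack()` combines Brownian monomers (optionally with
  spatially varying $D(x, y)$ and exponential bleaching) with the
  snapshot renderer.

Particles are simulated on a margin larger than the field of view so
that in/out fluxes at the frame edge are approximately balanced.

## 3. Fluctuation spectroscopy

### TICS

`temporal_autocorrelation()` computes
$r(\tau) = \langle \delta i(t)\,\delta i(t+\tau)\rangle /
\big(\langle i(t)\rangle\langle i(t+\tau)\rangle\big)$ over all frame
pairs of a region. `fit_tics_diffusion()` fits the two-photon 2D decay
$r(\tau) = g_0/(1 + 8 D \tau/\omega_0^2) + c$, excluding lag zero (shot
noise is temporally white and contaminates only $r(0)$); the offset $c$
absorbs an immobile fraction. `tics_diffusion_map()` tiles the frame and
fits per tile, masking background tiles. Limitations: the lag resolution
is the frame time, so TICS constrains $D$ only when the characteristic
time $\omega_0^2/8D$ spans several frames; fast processes need RICS.

### RICS

`rics_autocorrelation()` computes the spatial autocorrelation of
intensity fluctuations of a raster-scanned stack with per-pixel temporal
mean subtraction (removing immobile structures), using zero-padded FFTs
for the unbiased (overlap-normalized) linear correlation. The model
(`rics_model_surface()`, `fit_rics()`) is

$$G(\xi,\eta) = \frac{\gamma}{N}\,\theta^{-p}
\exp\!\left(-\frac{2\delta r^2(\xi^2+\eta^2)/\omega_0^2}{\theta}\right),
\qquad \theta = 1 + \frac{8 D\,|\xi\tau_p + \eta\tau_l|}{\omega_0^2},$$

with $p = 1$ for motion confined to the focal plane (default) or
$p = 3/2$ for 3D diffusion, and $\gamma = 2^{-3/2}$ the two-photon
beam-geometry factor. Fits are weighted by the number of contributing
pixel pairs and exclude the zero lag. Limitations: the per-pixel mean
subtraction over a finite number of frames removes a little genuine
correlation and biases $D$ upward by a few percent at 50 frames; slow
diffusion ($8 D \tau_l/\omega_0^2 \ll 1$ at useful lags) leaves the decay
dominated by the spatial PSF term and unconstrained. TICS and RICS probe
complementary time windows; on simulations of the same physics rendered
in each modality's native acquisition mode they agree within better than
a factor of two.

### Number & brightness

`number_and_brightness()` computes per pixel the apparent brightness
$B = \sigma^2/\langle k\rangle = \varepsilon + 1$ and apparent number
$N = \langle k\rangle^2/\sigma^2$. Immobile Poisson emitters give
exactly $B = 1$; mobile or aggregated emitters give $B > 1$. The
identities $B - 1 \equiv \varepsilon$ and
$N \cdot B \equiv \langle k\rangle$ hold by construction and are pinned
by tests. Fewer than ~50 frames makes the moment maps noisy (a warning
is raised). `bleach_curve()` fits a monoexponential to the mean frame
intensity; a rate compatible with zero indicates negligible bleaching.

## 4. Tracking

The detection chain is `register_translation()` (FFT cross-correlation
with sub-pixel quadratic refinement and bilinear resampling) →
`denoise_stack()` (small-σ Gaussian, optional 3×3 median prefilter) →
`spot_enhance()` (scale-normalized Laplacian-of-Gaussian, zero response
on flat input; use `scale_um = FWHM / (2\sqrt{2\ln 2})`) →
`detect_spots()` (8-neighbor strict maxima above threshold, distance-based
non-maximum suppression, quadratic sub-pixel refinement clamped to
±0.5 px).

`link_trajectories()` assigns detections to open tracks greedily in
ascending squared displacement with a gate `max_disp_um * (gap + 1)` and
optional gap bridging; ties break deterministically after canonical
sorting, so the result is independent of detection order. Bridged gaps
leave missing frames — `interpolate_gaps()` fills them by linear
interpolation so MSD estimation sees a uniform grid. Greedy assignment
is not globally optimal (no Hungarian/JV step): at high density or when
displacements per frame approach the inter-particle spacing,
mis-assignments appear; keep `max_disp_um` below half the typical
spacing.

`fit_spot_gaussian()` sizes spots by least squares of an elliptical 2D
Gaussian plus offset in a window around the detection, reporting per-axis
FWHM and their geometric mean. Sub-resolution objects return the PSF
width — fitted FWHM is a size proxy only above the resolution limit.

## 5. Binding reaction–diffusion simulation

`simulate_binding_diffusion()` propagates point monomers (Brownian,
reflective box) among slowly diffusing binder disks. Binding uses a
residence rule: a monomer must be inside a binder's capture radius at two
consecutive step endpoints, and then binds with probability
$1 - e^{-k_{on}\,dt}$. This makes fast-diffusing monomers — whose RMS
step exceeds the capture radius — out-run the binding zone, so the bound
fraction *decreases* with $D_{free}$, as expected from diffusion-limited
escape. (With a naive instantaneous contact test and release at the
binding position, the steady state is exactly independent of $D_{free}$ —
a detailed-balance property worth knowing before trusting any such
simulation.) Unbinding occurs with probability $1 - e^{-k_{off}\,dt}$ and
ejects the monomer to a release radius slightly outside the capture
radius, preventing immediate recapture artifacts. Rates with
$k\,dt > 0.1$ trigger a warning, since the per-step probabilities then
approximate the continuous process poorly.

## 6. Pipeline and I/O

`run_pipeline()` chains simulate → render → track → fit with a single
seed; each stage is logged, failures are recorded in the JSON report
without destroying earlier outputs, and a rerun with the same
configuration is bit-identical. Stacks are stored as 16-bit multi-page
TIFF with a plain-text `<file>.meta` sidecar (schema-versioned; counts
above 65535 refuse to write rather than clip). Trajectories are CSV with
a schema-version header comment; readers reject unknown major versions.

## 7. Validation strategy

Every estimator is tested against an independent brute-force oracle
(naive double-loop MSD, frame-pair-loop TICS, quadruple-loop RICS),
against closed-form identities (N&B moments, zero-lag amplitudes,
noiseless model refits to $10^{-6}$), and by parameter recovery from
end-to-end simulations at fixed tolerances. See
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.
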