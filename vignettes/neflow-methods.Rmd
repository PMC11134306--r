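---
title: "Models and methods behind neflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neflow)
```

`neflow` analyzes two-channel two-photon movies in which a green GPCR-based
sensor (GRAB-NE2h) reports extracellular norepinephrine (NE) and a red
indicator (jRGECO1a) reports neuronal calcium. The pipeline turns a raw movie
into (i) per-cell standardized traces of calcium, perineuronal ("local") NE
and field-wide ("global") NE; (ii) spatial-autocorrelation profiles of the NE
field; (iii) NE-synchrony traces and high/low-synchrony regimes; (iv) a
catalog of release and reuptake events extracted by Horn–Schunck optic flow;
and (v) per-cell regression models linking calcium to the NE fields, with
mixed-effects comparisons across drug conditions. Because suitable raw
in vivo recordings are rarely shareable, the package includes a synthetic
movie generator with full ground truth; every stage is validated against it.

## The synthetic field model

The NE concentration field is

$$F(x, t) \;=\; E(x)\,\Big[\,b + g(t) + \sum_i A_i(t)\,
  \exp\!\big(-\lVert x - c_i\rVert^2 / 2\sigma_i(t)^2\big)\,\Big],$$

a tonic baseline $b$, a shared slow drive $g(t)$, and a sum of event plumes
centered on axonal varicosities $c_i$, all scaled by a sensor-expression map
$E(x)$ (uniform unless an expression gradient is requested).

A **release plume** appears at its onset with spatial scale
$\sigma_0$ (`diffusion_sigma_um`, default 12 µm) and peak `release_amp`. It
then spreads diffusively, $\sigma(t)^2 = \sigma_0^2 + 2Dt$, with mass
conserved for `spread_s` seconds (the spatial integral is constant during
this phase — a testable invariant), after which first-order clearance with
time constant `reuptake_tau_s` takes over. **Reuptake dips** are negative
plumes of the same form. With probability `colocation_p` (default 0.8) a
release schedules a reuptake dip at the same site after a random delay;
releases occur in bouts (a duty-cycled Poisson process), so reuptake activity
predominates between bouts. This gives the generator the co-location and
temporal anticorrelation structure that the event-level statistics are meant
to detect — as a tunable mechanism, since the data only constrain the
resulting correlations, not their cause.

The shared drive $g(t)$ is a smoothed Ornstein–Uhlenbeck process
(`global_drive_tau_s` = 20 s): slow, smooth shared variability without
committing to any specific behavioral covariate.

**Desipramine condition.** Blocking the NE transporter is modeled as (i)
clearance slowed by `desi_clearance_factor` (default 8×), (ii) reuptake dips
attenuated to `desi_reuptake_factor` (0.2×), (iii) the shared fast drive
attenuated to `desi_drive_factor` (0.3×), and (iv) an additive tonic ramp
reaching `desi_ramp_amp` baseline units by the end of the run. The result is
the phenomenology the drug produces: monotone NE accumulation and flattened
local structure.

The paper-scale amplitudes are not identifiable from published values; the
defaults (events of order the baseline, drive about half that) are chosen so
that events are clearly visible yet do not saturate the z-scored movies.
They are documented, not asserted as biological.

## The cell model

Each cell couples to the **phasic** component of its perineuronal NE — the
plume-only annulus mean, excluding baseline and shared drive:

$$y_i(t) = \beta_{\text{local}}\,\tilde.x_i(t)
  + \beta_{\text{globalCa}}\, s(t)
  + \beta_{\text{int}}\, G(t)\, \tilde l_i(t)\tilde g_i(t)
  + \sigma_\varepsilon\,\varepsilon_i(t),$$

convolved with a causal single-exponential calcium kernel (1 s decay). Here
$s(t)$ is a shared population latent (OU, 3 s) that the analysis proxies by
the mean calcium of the other cells; $\varepsilon_i$ is private rate noise
(OU, 4 s); and the optional interaction term is gated by $G(t)$, the field's
own high-coherence state (computed with the same 30 s sliding local:global
correlation the analysis uses). Coupling to the phasic component — rather
than the full annulus trace — is what makes reuptake blockade weaken the
measured local-NE coefficient: desipramine removes phasic structure, and a
cell that listens to phasic NE loses its measurable coupling. Matched drug
pairs share one physical gain by passing the saline run's phasic SD as
`phasic_ref_sd` to the desipramine config.

Several choices keep the planted coefficients equal to the *estimand* of the
analysis (OLS on detrended, 1 s-smoothed, z-scored traces):

* the private noise is slow (4 s), so standardization attenuates noise and
  signal comparably — white noise would be suppressed by smoothing and
  inflate every standardized coefficient;
* the interaction product is built from standardized traces exactly as the
  analysis builds its predictor (products do not commute with smoothing);
* the phasic annulus traces are computed on the same overlap-trimmed annuli
  the geometry builder produces.

Residual biases that remain are the causal calcium kernel's lag against the
unlagged NE predictors (a few percent down on `beta_local`) and a small
negative weight pushed onto global NE by the collinearity of annulus and
field plume signals; both are visible in the validation suite's tolerances
and discussed below.

## Rendering and its artifacts

The green channel is the NE field; the red channel is a neuropil background
carrying a diluted population-calcium signal (`neuropil_ca_gain`) with
calcium painted into soma disks. Somata are dark and NE-static in green (the
sensor expresses on neuropil). Cross-channel bleed-through mixes a fraction
`bleedthrough_frac` of each channel into the other; Gaussian noise of SD
`noise_sd` approximates shot noise at high photon counts (`noise_sd` = 0.1
is deliberately realistic: the per-pixel bleed-through regression relies on
pixel noise dominating the cross-channel covariance, and an unrealistically
clean movie makes that regression remove true signal). Optional rigid drift
at `drift_px_per_min` exercises the registration stage against known shifts.

## Preprocessing

Frames are median-filtered per pixel over 3 frames and mean-binned 2:1
(~30 → ~15 Hz). Registration is rigid translation: FFT cross-correlation of
each frame against the temporal mean of the first 5 minutes, with parabolic
sub-pixel refinement; shifts above 10% of the FOV are clamped and flagged.
Bleed-through is corrected by replacing each pixel's series with the
residual of an OLS fit on the other channel's series at the same pixel;
residual orthogonality is exact and tested.

Field geometry: each cell's local-NE field is a disk of `radius_um` (default
15 µm — the radius used by the models; the Methods' "15–20 µm diameter"
phrasing is resolved in favor of the modeling definition) minus the soma and
minus pixels already claimed by earlier cells (overlaps excluded, not
split); the global field is everything else. Trace standardization is linear
detrend → Gaussian smoothing (σ = 1 s) → z-score, in that order. Linear
detrending is the simplest reproducible reading of "detrended"; the smoothing
kernel's shape is not stated in the source description, and a Gaussian with
σ equal to the stated width is used for the 1 s modeling kernel.

## Spatial autocorrelation

The FOV is tiled into 10 µm patches; patch-mean traces are correlated
pairwise and binned by center distance (1 µm rounding). The binned profile
is fit with $r(d) = a_1 e^{-d/\lambda_1} + a_2 e^{-d/\lambda_2}$
(`minpack.lm`, multi-start, $\lambda_1 \le \lambda_2$). For a Gaussian plume
of scale $\sigma$, patch correlations decay as $e^{-d^2/4\sigma^2}$, whose
$1/e$ distance is $2\sigma$; `estimate_plume_scale()` therefore reports half
the fitted curve's $1/e$ distance, which recovers the generator's
`diffusion_sigma_um` within a quarter on default settings.

## Synchrony

NE synchrony is the Pearson correlation of a cell's local and global NE
traces in a centered 30 s sliding window, computed densely (stride of one
frame) with running sums; edge frames where the window does not fit are NA.
The low-synchrony regime is the set of frames where the cell-averaged
synchrony trace falls below its own temporal mean; high/low masks partition
the defined frames exactly.

## Optic flow and event calling

The NE channel is blurred spatially (σ = 12 px for the main pathway; the
noise-control pathway uses the 4 µm variant — both knobs are exposed because
the two stated values cannot be reconciled into one), smoothed temporally,
detrended, and z-scored per pixel. Two deliberate choices depart from the
naive reading and are load-bearing:

* **The 5 s temporal kernel is interpreted as a full width at half maximum**
  (Gaussian σ ≈ 2.1 s). With σ = 5 s, consecutive events at realistic
  densities merge into one smooth bump and onset localization degrades
  beyond use (measured recall drops from ~1.0 to ~0.5 on planted events).
* **The per-pixel z-score is variance-moderated**: each pixel's SD is pooled
  in quadrature with half the median SD across pixels. Without the floor,
  near-static pixels (field edges, quiet regions) are amplified into huge
  z-values that drag flow critical points toward the border.

Optic flow between consecutive frames is the classic Horn–Schunck iteration
(smoothness weight α = 1, ≤ 200 sweeps, tolerance 1e-4 on the mean update),
implemented in C++. Note that 200 sweeps suffice for critical-point
*geometry*; recovering accurate velocity *magnitudes* on large structures
needs a few thousand sweeps because the smoothness term relaxes diffusively
— the validation against the phase-correlation oracle runs the solver to
2,000 iterations.

Critical points are grid cells where both velocity components change sign;
the local Jacobian classifies them (sources, sinks, saddles, spirals by
eigenvalue signs) with closed-form sub-pixel refinement. Per-frame points of
one type are linked into *episodes* by track-following (distance to the
track's last position, small frame gaps allowed); an episode reports its
position and fluorescence z at the frame of peak |divergence|, where the
pattern is strongest and best localized. High-fluorescence (z > +1) source
episodes pair greedily with the nearest subsequent high sink within 20 µm
and 30 s to form release events; low/low pairs form reuptake events;
unpaired episodes are reported, never dropped. Event onset is the source
episode's peak-expansion frame: with zero-phase temporal smoothing this is
an unbiased estimate of a step onset, whereas the first linked frame would
be early by roughly the kernel width.

Event maps are Gaussian-splatted (σ = 2 px) before correlation — point
events on a pixel grid would make the Pearson correlation between maps
degenerate. The expression control residualizes both maps on the time-mean
fluorescence image and correlates the residuals. The processed-noise control
builds each null movie by permuting every pixel's series over time
independently (matching per-pixel mean, SD and distribution exactly) and
runs the full flow → events → correlation pipeline on it; p-values use the
add-one permutation convention.

## Models

The per-cell "GLM" is Gaussian-identity OLS — the regression sense of the
term — of the standardized calcium trace on local NE, global NE, population
calcium, and the product of the standardized local and global NE traces, all
forced in. Standard errors are plain OLS; residual autocorrelation is *not*
corrected, so single-cell p-values are optimistic — population-level claims
rest on across-cell t tests. The radius sweep rebuilds annuli at 5–100 µm
and refits; with coupling planted at 25 µm the population profile peaks at
25 ± 10 µm. The drug comparison fits
`correlation ~ drug + (drug || mouse) + (drug || cell_id)` by REML with
Satterthwaite degrees of freedom (`lmerTest`); with a single mouse the mouse
term is dropped with a warning.

## Validation scales and what passing shows

The validation suite and `scripts/acceptance.R` run everything on reduced
problem sizes chosen to resolve each quantity on a single CPU: event
recovery on 128 × 128 px × 2,000 frames with 20 planted events; coefficient
recovery on 96 × 96 px × 9,000 frames with 25 cells; direction checks
(co-location, regime splits, drug contrast) on 64–96 px fields over 5–10
seeds; the noise control at n = 100 nulls with the calibration done by
exchangeability (null draws scored against the shared null set) rather than
re-running the full pipeline 100 × 101 times. The generator reproduces the
statistical structure the analysis assumes — shared drive, diffusive
plumes, co-located offset reuptake, NE-coupled cells, bleed-through, noise,
drift — but not nonrigid tissue motion, behavioral covariates, sensor
kinetics, or spatially structured noise; passing these tests shows the
estimators are correct and calibrated under the stated model, not that the
model exhausts real data.

## Known limitations

* Velocity magnitudes from the default 200 Horn–Schunck sweeps are
  underestimates on large smooth structures (geometry is unaffected).
* The causal calcium kernel biases the standardized local-NE coefficient a
  few percent low; the bleed-through correction plus plume collinearity
  biases the global-NE coefficient slightly negative when its true value is
  zero. Both are within the validation tolerances and documented here
  rather than hidden.
* Event calling degrades gracefully with imaging noise but has not been
  characterized against nonrigid motion, which is out of scope.
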