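---
title: "MSD-based motion analysis of enzyme-powered micromotors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSD-based motion analysis of enzyme-powered micromotors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromotion)
```

This vignette documents the models behind `micromotion`, the choices made
where the design was genuinely open, and what validation on synthetic data
does and does not establish about real recordings.

## The physical model

A micron-sized sphere functionalized with an enzyme self-propels when
surface catalysis sets up an asymmetric solute gradient. At the level of its
center-of-mass motion we model it as a two-dimensional **active Brownian
particle** (ABP): it advances at constant speed $v$ along a heading
$\theta(t)$, the heading diffuses with rotational coefficient $D_r$, and
translational diffusion $D_t$ acts independently:

$$
\dot\theta = \sqrt{2 D_r}\,\xi_\theta,\qquad
\dot x = v\cos\theta + \sqrt{2 D_t}\,\xi_x,\qquad
\dot y = v\sin\theta + \sqrt{2 D_t}\,\xi_y .
$$

Its exact ensemble MSD (available as `msd_abp_theory()`) is

$$
\mathrm{MSD}(t) \;=\; 4 D_t t \;+\; 2 v^2 \tau_r^2
\left( t/\tau_r + e^{-t/\tau_r} - 1 \right),
\qquad \tau_r = 1/D_r,
$$

which reduces to the **propulsive-regime parabola**
$\mathrm{MSD}(t) = 4 D_t t + v^2 t^2$ for $t \ll \tau_r$ and to an enhanced
diffusion $(4D_t + 2v^2\tau_r)\,t$ for $t \gg \tau_r$.

The rotational scale is not fitted: for a sphere of radius $r$ in a solvent
of viscosity $\eta$ at absolute temperature $T$, Stokes–Einstein gives

$$
D_r = \frac{k_B T}{8\pi \eta r^3}, \qquad
D_t = \frac{k_B T}{6\pi \eta r},
$$

implemented in `rotational_diffusion()` and `translational_diffusion()`.
Defaults describe the reference particle — $r = 1.00\ \mu m$,
$T = 297.15$ K (24 °C), $\eta = 0.9107\times 10^{-3}$ kg m⁻¹ s⁻¹ — for which
$D_r = 0.1792\ \mathrm{s^{-1}}$, $\tau_r = 5.579$ s and
$D_t = 0.239\ \mu m^2 s^{-1}$. Key assumptions: the particle is a rigid
sphere far from walls (no Faxén corrections), the solvent is Newtonian, and
propulsion does not alter the thermal diffusivities.

## The MSD estimator

`compute_msd()` computes the **time-averaged, overlapping-window** MSD: for
integer lag $k$ at sampling interval $\Delta$,

$$
\widehat{\mathrm{MSD}}(k\Delta) = \frac{1}{N-k}\sum_{s=1}^{N-k}
\left[ (x_{s+k}-x_s)^2 + (y_{s+k}-y_s)^2 \right],
$$

using all $N-k$ start positions. Overlapping averaging is the field standard
and maximizes data use; its cost is strong correlation between neighbouring
lags, which matters for inference (below). The test suite pins these
semantics to an independent brute-force double loop over all (start, start +
lag) pairs, bit for bit. Degenerate inputs are rejected early: fewer than
two samples is an error, and a non-uniform time base is an error that names
the offending gap (tolerance $10^{-9}$ s), because a silent gap would
corrupt every lag.

`ensemble_msd()` averages per-particle curves lag by lag (unweighted) and
reports the across-particle standard error of the mean, the dispersion
measure used throughout; when particles have unequal lengths only the common
lag grid is kept.

## The propulsive fit

`fit_propulsive()` regresses the MSD on $\{4t, t^2\}$ without intercept over
lags $t \le w\,\tau_r$; the linear coefficient is $D_t$, the quadratic one
$v^2$, and $v = \sqrt{\max(v^2, 0)}$ with a delta-method standard error.
Design choices that were genuinely open:

* **Window fraction** `window_frac` defaults to $w = 0.2$ (lags up to
  ≈ 1.1 s at the reference $\tau_r$). The exact ABP MSD falls below the
  parabola as the heading decorrelates, so a finite window biases $v$ low —
  a few percent at $w = 0.2$ — while shrinking the window inflates the
  variance.
  0.2 is our bias–variance compromise; the parameter is exposed and
  sensitivity can be checked directly.
* **Negative curvature** is not an error: purely Brownian controls must
  yield a speed estimate, so $\hat v^2 \le 0$ maps to $v = 0$ with a
  `"non-propulsive"` flag.
* **Per-particle vs ensemble-first.** Both modes exist because both are
  defensible: `fit_particles()` + `speed_summary()` mirrors the
  "mean ± s.e.m. of per-particle speeds" reporting convention; fitting the
  `ensemble_msd()` curve once avoids the positive bias that the
  $\sqrt{\max(\cdot,0)}$ clipping adds to each noisy per-particle speed, and
  is preferable when the true speed is small.
* **No lag weighting** by default (plain OLS, transparent);
  `weight_by_pairs = TRUE` offers pair-count weighting.

**Inference caveat.** The OLS standard errors treat lags as independent,
which overlapping averaging violates; they are rough scales only. The
condition-level propulsion call in `speed_summary()` therefore ignores them
and runs a one-sided $t$-test across the per-particle $\hat v^2$ values —
particles are independent replicates, so this test has honest size (a
Brownian condition is called propulsive in ≈ 5% of cases at the default
$\alpha = 0.05$).

**Precision limit at low speed.** With 20 particles × 30 s at 25 FPS, the
sampling error of the windowed fit is ≈ 10% of $v$ when
$v \approx 0.4\ \mu m\,s^{-1}$ (the $v^2 t^2$ term is then only ~20% of the
MSD at the window edge). Ensemble estimates at such speeds frequently fall
outside a ±10% band — a property of the information in the data, not of the
implementation — whereas at $2\ \mu m\,s^{-1}$ recovery within 10% is
essentially certain. The acceptance suite measures both regimes.

## The synthetic-data generator

`simulate_abp()` integrates the Langevin equations by Euler–Maruyama with
`substeps` internal steps per frame (default 10, i.e. δ = 4 ms at 25 FPS).
Because the heading has no positional feedback the scheme is exact for
$\theta$ and the only discretization error is the piecewise-constant heading
within δ; at the default parameters the per-step heading kick
($\sqrt{2 D_r \delta} \approx 0.04$ rad) and advance (≈ 8 nm) are far below
the PSF and pixel scales, and halving δ shifts ensemble MSDs by less than
Monte-Carlo error (tested). Headings initialize uniformly on $[0, 2\pi)$ so
the ensemble is isotropic, as the MSD model assumes. Acquisition defaults
emulate the reference experiment: 25 frames s⁻¹, 30 s, 20 particles per
condition. `add_localization_noise()` adds i.i.d. Gaussian position error,
which inflates every MSD value by the additive plateau $4\sigma^2$.

What the generator deliberately does **not** emulate: inter-particle and
wall interactions, hydrodynamic or phoretic fields, 3-D excursions and
defocus, drift (an optional constant-drift hook exists for robustness
checks), photobleaching, and heavy-tailed localization errors. Passing
tests on this synthetic data therefore validates the *estimators* under the
model's assumptions; they cannot certify tracking robustness against real
imaging artefacts.

## The kinetics layer

The observed phenomenology to encode: speed rises with substrate, declines
again at excess substrate, collapses under a competitive inhibitor, and is
linear in measured enzymatic activity. We use the textbook rate law

$$
\mathrm{rate}(S, I) = \frac{v_{\max} S}
{K_m\,(1 + I/K_i) + S\,(1 + S/K_s)},
$$

unimodal in $S$ with peak at $\sqrt{K_m K_s (1+I/K_i)}$, exactly
Michaelis–Menten when $I = 0,\ K_s = \infty$; speed couples linearly,
$v = c \cdot \mathrm{rate}$. The high-substrate speed decline could equally
be a viscosity effect of concentrated substrate solutions; at the level of a
fitted speed the two mechanisms are observationally equivalent, so the
generator models the decline through the single $K_s$ knob rather than
asserting a mechanism.

The `urease_kinetics()` preset ($K_m = 30$ mM, $K_s = 400$ mM,
$K_i = 0.1$ mM, coupling 2.07 µm s⁻¹) is **illustrative, not fitted to any
experimental curve**; the constants were chosen once to reproduce the
qualitative shapes: a dose–response peak near
$\sqrt{30 \cdot 400} \approx 110$ mM substrate, and — because titrations are
run at excess substrate (500 mM), where competitive inhibition is only felt
once $K_m I / K_i$ rivals $S(1+S/K_s) \approx 1125$ mM — a sub-mM $K_i$ is
required for single-digit-mM inhibitor to halve the rate (hydroxamate
inhibitors of urease indeed bind at µM scale). With $K_i = 0.1$ mM the
preset gives a 61% rate drop at 6 mM and 93% at 50 mM inhibitor.
`measure_activity()` emulates a colorimetric assay readout as the relative
rate with 5% CV multiplicative Gaussian noise.

## Tracking

The tracker is a functional stand-in validated purely against synthetic
ground truth, so it is deliberately simple:

* **Detection**: 8-neighbourhood local maxima above a threshold (`"auto"` =
  frame median + 25% of the dynamic range), maxima closer than `min_sep_um`
  merged into the brighter, then a background-subtracted intensity-weighted
  centroid over a window of radius $3\sigma_{PSF}$. On noiseless rendered
  spots this localizes to well within 0.05 px; the centroid is only unbiased while
  the window is untruncated, so accuracy degrades within a window-radius of
  the frame edge. A Gaussian fit would be marginally better but is not
  needed for spots spanning many pixels.
* **Linking**: frame-to-frame candidate pairs within
  `max_disp_um × gap`, resolved per frame pair by minimal total squared
  displacement — exact matching on each connected component of the candidate
  graph (components beyond 6 tracks fall back to greedy with a warning; ties
  resolve to the lowest particle id, deterministically). Unmatched
  detections seed new tracks; `memory` frames of disappearance are bridged
  by persisting the last position so output sampling stays uniform; tracks
  shorter than `min_track_length` (250 frames = 10 s, so every kept track
  supports multi-second MSD lags) are dropped.
* **`max_disp_um` default 0.8**: the per-frame displacement of the fastest
  expected particle (2.07 µm s⁻¹ → 0.083 µm) plus five standard deviations
  of the per-frame diffusive step at the reference $D_t$
  ($\sigma = \sqrt{2 D_t/\mathrm{fps}} \approx 0.14$ µm per axis). A tighter
  radius severs a few percent of genuine links per frame and fragments every
  track; 0.8 µm keeps genuine links while remaining far below typical
  inter-particle distances in well-separated fields.

The renderer draws isotropic Gaussian spots (amplitude, background, σ_PSF
configurable; optional Gaussian or Poisson pixel noise) with the convention
that the center of pixel (1,1) is (0,0) µm; stacks round-trip through 16-bit
multi-page TIFF with a JSON sidecar carrying fps, pixel size and intensity
scale. Pixel size (0.1 µm px⁻¹) and localization precision are stated
assumptions of the synthetic setup, not measured instrument values.

## Pipeline reproducibility

`run_sweep()` derives each condition's seed as
`condition_seed(master, label)` — a label hash folded into the master seed —
so per-condition results are independent of condition order and stable under
subsetting; a failing condition yields `NA`s plus an error message without
aborting the sweep. The video mode renders and re-tracks one particle per
stack, mirroring recordings that follow one motor at a time and avoiding
spot collisions. `correlate_speed_activity()` reports the adjusted
$R^2 = 1 - (1-R^2)(n-1)/(n-2)$ of speed on activity across condition means;
`percent_speed_drop()` reports $100(1 - v/v_{ref})$.

## Problem sizes used in validation

Unit tests run on reduced designs (ensembles of 3–8 particles, 1–15 s
tracks) chosen so each property is still decisively testable; statistical
checks use 3-standard-error bands. The acceptance suite runs the reference
design itself: 500-trajectory simulator validation against the closed-form
MSD, 200-replicate × 20-particle recovery studies at 0.43 and
2.07 µm s⁻¹ plus Brownian null calibration, a three-particle
render-track-fit loop, and 200-seed titration correlations. These sizes are
the package's validation choices; all are reproducible from fixed seeds.

## Known limitations

* Estimator variance at low speeds (above) makes per-ensemble speeds below
  ≈ 0.5 µm s⁻¹ indicative rather than precise at the 20 × 30 s design;
  increasing particles or duration is the remedy.
* $D_t$ is weakly identified when the $v^2 t^2$ term dominates the window;
  its estimate should then be read as a nuisance parameter.
* The tracker targets sparse, bright, similar-sized spots; dense fields,
  overlapping spots or strong intensity fluctuations need a dedicated
  multi-hypothesis tracker.
* The kinetics preset is qualitative; fitting $K_m$, $K_i$, $K_s$ to real
  dose–response data is explicitly out of scope.
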