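---
title: "Wall-distance coding in tactile virtual reality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall-distance coding in tactile virtual reality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactileVR)
```

# The system being modeled

A head-fixed mouse runs on a ball between two motorized walls. The walls are
coupled to locomotion so that the animal experiences a winding corridor: if
it runs at speed $v$ (cm/s) at run angle $\phi$ in a corridor bending at
angle $\psi$, the snout-to-wall distance $u$ (mm) updates as

$$\Delta u = \gamma\, v \sin(\epsilon)\, \Delta t, \qquad \epsilon = \phi - \psi,$$

with $\gamma$ a dimensionless gain and $\Delta t$ the update step. The
product $v \sin(\epsilon) \Delta t$ is in cm and is converted to mm inside
`updateWallPosition()`. At the corridor center both walls are 19 mm from the
snout — just within whisker reach — and the walls never come closer than
4 mm. Closed-loop trials are 200 cm long; the behavioral performance metric
is the **angle error**, the absolute difference between the run angle and
the corridor turn angle at the end of the turn.

Interleaved **open-loop** trials move the contralateral wall on a fixed
schedule regardless of locomotion: the default electrophysiology schedule is
4 s (1 s move-in, 2 s hold, 1 s move-out), the imaging schedule 8 s
(2 s / 4 s / 2 s). Open-loop trials sample wall distance uniformly and
repeatably, which is why all tuning analyses are built on them.

In **illusory-corridor** trials the walls are replaced by closed-loop
photostimulation of layer-4 barrel cortex: laser power scales linearly from
0 mW at the corridor center to 4.5 mW at the edge, and only the hemisphere
opposite the virtual wall is stimulated (`illusoryPower()`).

## The tracking policy is a stand-in for the animal

The corridor is closed-loop, so something must steer. `TrackingPolicy`
provides three controllers: `ideal` runs exactly along the corridor
($\phi = \psi$, hence $\Delta u = 0$ — a useful exactness oracle),
`proportional` steers against the lateral offset it senses as wall-distance
asymmetry (in closed loop this converges to $\phi \to \psi$, mimicking
trained wall tracking), and `noisy` adds an angular random walk. These are
explicitly synthetic: none of them is a model of mouse behavior beyond the
feedback structure of the task. Policy speed is constant within a trial;
`speedSd` draws per-trial speeds so that speed-dependent analyses (median
splits, speed tuning) have across-trial variance to work with.

# Ground-truth neurons

`NeuronModel` encodes the response families seen in barrel cortex during
wall tracking, as parametric rate functions of wall distance $u$:

* `monotonic_decreasing` — rate rises as the wall approaches (logistic in
  $u$); the dominant family.
* `monotonic_increasing` — rate is suppressed as the wall approaches,
  returning to baseline when the wall is out of reach (logistic, amplitude
  capped at baseline so rates stay non-negative).
* `unimodal` — Gaussian preference for a particular distance.
* `multimodal` — sum of two Gaussians.
* `untuned` — constant baseline.

Every family returns exactly the baseline far from the wall, so
out-of-reach epochs measure the true baseline. Direction sensitivity is a
multiplicative gain applied while the wall moves toward the animal
(wall velocity $< 0$); stationary-wall epochs use factor 1. Speed
sensitivity is a multiplicative model (`none` or `linear`). Spikes are
drawn as an inhomogeneous Poisson process on the behavior clock
(counts $\sim$ Poisson(rate $\cdot \Delta t$), times uniform within the
bin), seeded and reproducible.

`makePopulation()` draws populations per tuning family. Preferred distances
default to 4–40 mm with a small-distance bias (a beta(1.2, 2) shape),
matching both the range of wall distances an open-loop session actually
samples and the observation that preferred distances tile whisker reach
with a bias toward near distances. We deliberately do not draw preferred
distances beyond the sampled range: a ground-truth peak the stimulus never
visits cannot be recovered by any analysis, so it would only make recovery
statistics unreadable.

## The calcium forward model

Spikes map to fluorescence through a difference-of-exponentials kernel

$$k(t) \propto (1 - e^{-t/\tau_r})\, e^{-t/\tau_d},$$

with $\tau_r = 200$ ms and $\tau_d$ solved numerically (`uniroot` on the
post-peak half-decay) so that the response decays to half its peak 600 ms
after the peak — GCaMP6s-like dynamics. The kernel is normalized so an
isolated spike peaks at 0.3 dF/F. The model is linear and time-invariant by
construction; it ignores indicator saturation and nonlinearity, which is a
stated non-goal.

`renderMovie()` turns dF/F traces into a movie: each soma is a disc whose
resting brightness is `roiContrast` (default 30%) above the background, and
fluorescence dynamics multiply the local resting brightness. A shared
neuropil trace with a spatial profile models out-of-focus contamination,
per-frame integer rigid shifts model brain motion, and additive Gaussian
noise models the detector. Two choices matter:

* **Somata have resting contrast.** Without it the resting scene is
  featureless and registration is ill-posed — in real data ROIs are drawn
  on the mean image precisely because cells are visible at rest.
* **The ROI fixture grid is jittered.** A perfectly periodic lattice of
  identical cells makes rigid registration ambiguous up to the lattice
  period; real tissue is aperiodic, so the fixture must be too.

Default synthetic movies are 64–128 px square at 7 Hz, a desk-scale
stand-in for 512 x 512 three-plane acquisitions.

# Spike-train analyses

Spike times are binned at 2 ms and aligned to the behavior clock
(`binSpikeRate`). All analyses are restricted to running
(speed $> 3$ cm/s, strict), when the animal is actively whisking.

`distanceTuning()` builds the wall-distance tuning curve: per-trial mean
response in 3-mm bins of wall distance, then mean ± SE across trials,
keeping only trials whose mean speed exceeds 3 cm/s and bins with at least
3 contributing trials. The **baseline** is the mean response during running
while the wall is beyond the out-of-reach threshold (default 30 mm — the
corridor geometry places whisker contact within roughly 19–30 mm, and the
threshold is configurable). Significance is a one-way fixed-effects ANOVA
across distance bins with trials as replicates (`anovaTuningTest`), with
two conventions: globally zero variance gives $p = 1$; perfect separation
(zero within-bin variance, distinct bins) gives $p = 0$.

From curve and baseline, `tuningSummary()` computes
activation $=$ peak $-$ baseline, suppression $=$ baseline $-$ minimum, and
the **modulation index** (activation $-$ suppression) / (activation $+$
suppression): $+1$ for purely activated units, $-1$ for purely suppressed,
near 0 for mixed, undefined (NA) when both are zero.

The companion ratio indices follow the same template:

* **direction** (`directionSummary`): trial-averaged rate profiles over the
  1-s wall-approach and wall-withdrawal windows (epochs detected from the
  sign of the wall velocity with a ±1 mm/s dead band); range $=$ max $-$
  min of each profile; index on the ranges.
* **laterality** (`lateralityIndex`): contralateral vs ipsilateral curve
  ranges.
* **open vs closed loop** (`openClosedIndex`): mean rates over the shared
  wall-distance range.
* **speed gain** (`speedGainIndex`): trials split at the median trial
  speed; $g$ is the closed-form least-squares gain mapping the slow curve
  onto the fast curve, and the index is $\ln g$.

All indices are bounded in $[-1, 1]$ whenever defined and antisymmetric
under swapping their inputs.

# Imaging pipeline

`registerMovie()` estimates each frame's global integer shift from the peak
of an FFT cross-correlation against a reference image (means subtracted so
the flat background does not dominate) and shifts the frame back, filling
exposed borders with the frame median. Subpixel and nonrigid registration
are non-goals. On noiseless synthetic movies the injected shifts are
recovered exactly.

Fluorescence processing per trace: baseline $F_0$ is the 20th percentile of
a 160-s centered rolling window (truncated at the session edges);
$\Delta F/F = (F - F_0)/F_0$; neuropil contamination is estimated in an
annulus 3–8 px outside the ROI boundary (excluding all ROI pixels),
processed identically, and subtracted with coefficient 1.0 (configurable).
The composition dF/F ∘ rolling-baseline is invariant to rescaling $F$ by
any positive constant.

`pixelwiseMap()` regresses every pixel's time series on an indicator basis
of 3-mm distance bins over running frames (equivalent to per-bin means; the
binned basis is used rather than a single linear term because preferred
distances are non-monotonic across the field of view). Preferred distance
is the bin with the maximum fitted response; $r^2 = 1 - SS_{res}/SS_{tot}$,
set to 0 for constant pixels. `writeMapPng()` renders the standard display:
hue = preferred distance, brightness = $r^2$.

`classifyRoi()` applies the two classification rules: an ROI is **active**
if the 90th percentile of its corrected dF/F exceeds 1.0, and **tuned** if
the tuning ANOVA has $p < 0.05$ *and* the tuning-curve range exceeds
0.3 dF/F; tuned takes precedence.

`smoothTuning()` fits a cubic smoothing spline to the binned means
(weighted by trials per bin) and evaluates it at the bin centers. The
original analysis stack used a "univariate spline, smoothing factor 1",
which does not translate numerically to R's `smooth.spline`; the smoothing
strength is therefore an exposed parameter. The default (`spar = NULL`)
selects smoothness by generalized cross-validation, which preserves curve
shape (flat curves are fixed points; on smooth curves no bin moves by more
than its SE). For rank-based monotonicity checks heavy smoothing
(`spar = 1`) is appropriate: GCV tracks bin noise in the flat tails of
monotonic curves, where tiny wiggles break rank monotonicity without being
scientifically meaningful.

# Session orchestration

`sessionConfig()` collects every parameter and threshold —
coupling, trial schedule, policy, population, analysis thresholds
(3 cm/s, 3-mm bins, $\alpha = 0.05$, active 1.0, range 0.3, out-of-reach
30 mm, min 3 trials/bin), imaging geometry — into one object that
round-trips through YAML. `runPipeline()` executes
simulate-behavior → simulate-neurons → analyze (→ optionally render and
analyze an imaging session) → report, deterministic given the config seed;
`writeReport()` emits JSON population statistics plus a CSV per-unit table.
External formats are CSV (tables, behavior, spikes), JSON (reports,
manifests, movie sidecars), YAML (config) and multi-frame TIFF (movies):
the plain-text/standard-container subset of the usual neurophysiology
stack.

# Numerical and statistical choices

* **Units.** Degrees at interfaces, radians internally; cm/s for run speed,
  mm for wall distance (the coupling rule converts); seconds everywhere on
  the clock.
* **Clamping.** The lateral offset is clamped so both walls stay in
  [4, 34] mm and corridor width is conserved exactly
  ($u_L + u_R = 38$ mm); clamp events are recorded per sample.
* **Wall velocity.** Discrete derivative within trial boundaries; the first
  sample of each trial is set to 0 so trial transitions do not create
  spurious wall movement.
* **Peak recovery criterion.** "Within one 3-mm bin" is evaluated bin-wise:
  the estimated peak bin must be the bin containing the true preferred
  distance or an adjacent bin. Comparing bin centers against continuous
  ground truth would conflate discretization (up to 1.5 mm even for a
  perfect estimator) with estimation error.
* **Extreme-value bias of the modulation index.** With $n = 30$ open-loop
  trials, per-bin rate estimates carry enough Poisson noise that the
  minimum over ~14 bins sits roughly 1.3 SD below baseline, inflating the
  spurious suppression term of activation-only units and capping their
  indices near 0.85. The estimator itself is unbiased in the limit: on
  noise-free rate series recovered indices exceed 0.98 in absolute value.
  The tests assert the exact limit on the noise-free path and sign plus
  median dominance on the Poisson path. Real sessions (hours, hundreds of
  trials) sit far closer to the noise-free regime.
* **Indicator lag.** The slow calcium kernel (~1 s to half-decay) smears
  responses toward larger distances during the move-out sweep, so a small
  fraction of dF/F-based peak locations land one bin outward of ground
  truth. This is a property of the indicator, not of the pipeline, and is
  why spike-based and dF/F-based peak histograms should not be compared
  bin-by-bin.
* **Degenerate inputs.** Zero-variance ANOVA input returns $p = 1$ and is
  logged; both-zero ratio indices return NA ("undefined") rather than 0;
  empty masks, empty trial groups, non-positive baselines and non-finite
  inputs raise errors.

# Problem sizes

The test suite and validation experiments use desk-scale sessions chosen so
the full suite runs comfortably on one CPU: 30 open-loop trials per session
(10 hold distances tiling 4–40 mm, 3 repetitions), 2-ms spike clocks,
50-unit recovery cohorts, a 1000-unit type-I calibration, and a
128 x 128 x ~1700-frame end-to-end imaging session with 20 ROIs. These are
the package's validation conditions, not claims about experimental scale.

# What passing tests do and do not show

The synthetic generator reproduces the *structure* of the experiments —
closed-loop coupling, open-loop schedules, tuning families, Poisson
spiking, GCaMP-like kernels, rigid drift, neuropil contamination — but not
the full phenomenology of real data: no whisker mechanics, no indicator
nonlinearity or saturation, no slow drift in baseline fluorescence, no
correlated network variability, Gaussian rather than shot noise, and
manually drawn ROIs are replaced by known discs. Parameter recovery on
these synthetics validates the analysis code and its statistical
calibration; it does not by itself validate the biological conclusions one
would draw from real recordings.

# Known limitations

* Registration is integer-pixel and rigid; movies with subpixel jitter will
  show residual motion.
* The neuropil model is spatially uniform by default; strongly structured
  neuropil with contrasting somata leaves a small residual after
  subtraction with coefficient 1.
* Open-loop direction epochs assume the schedule's single approach and
  withdrawal per trial; free-form wall trajectories would need the
  dead-band epoch detector to be revisited.
* The ANOVA is a fixed-effects test on per-trial bin means; it is
  well-calibrated for the balanced-ish designs here but is not a mixed
  model and does not propagate within-trial autocorrelation.
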