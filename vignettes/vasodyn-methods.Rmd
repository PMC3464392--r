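---
title: "Quantifying electroporation-induced vascular dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying electroporation-induced vascular dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(vasodyn)
```

## The measurement problem

Delivering electric pulses to skin (electropermeabilization, EP — here the
high-voltage/low-voltage combination used for plasmid-DNA electrotransfer)
perturbs the microvasculature in three ways that intravital fluorescence
angiography can quantify: vessels constrict, blood flow transiently stops
("vascular lock"), and vessel walls become leaky to a high-molecular-weight
FITC-dextran tracer. In the dorsal window chamber the same field of skin
vasculature is imaged repeatedly: a series every 20 s for 2 min after
tracer injection, and after EP a series every 20 s for 8 min followed by
every 2 min for 22 min. All analysis in this package operates on such
timestamped stacks plus two event times (injection, EP; seconds relative to
EP, injection possibly negative).

The original measurements come from live animals and no raw data are
deposited, so validation is by **parameter recovery**: a synthetic
generator renders sequences whose ground truth is set to the reported
effect magnitudes, and the pipeline must recover them.

## The synthetic angiography generator

`generate_network()` draws a connected branching network: a tortuous
venular trunk crossing the field, further venules branching off existing
segments, and straighter arterioles. Class calibers are sampled uniformly
inside windows that respect the conventional ranges for this preparation
(arterioles 10–100 µm, venules 20–250 µm); the default windows (arterioles
12–28 µm, venules 20–45 µm on a 192×192 px field at 2 µm/px) keep the
vascular fraction near 25–30%, typical of such fields. Candidate segments
are re-drawn (up to 40 times) until their centerline keeps a
ribbon-overlap-free clearance from all existing segments outside the
branching junction; analysts likewise select non-overlapping vessels for
measurement. Each centerline also stays one radius plus a guard margin away
from the field border.

`render_sequence()` composes each frame from per-segment distance fields:
a pixel's vascular coverage is `clamp(r + 0.5 − d, 0, 1)` (sub-pixel soft
edges), and the frame is `w·I_vasc(t) + (1 − w)·I_tissue(t)` followed by a
Gaussian point-spread blur (σ = 1 px), additive Gaussian noise and
quantization to the configured bit depth. Fixed seeds give byte-identical
stacks.

The dynamics model (`dynamics_model()`) has these components:

* **Filling** — single-exponential saturation
  `f(t) = 1 − exp(−u(t)/τ_fill)` with default τ_fill = 35 s, chosen so that
  95% of plateau is reached within 2 min of injection, the control
  behaviour of this preparation. `u(t)` is the *perfused* time since
  injection.
* **Vascular lock** — perfusion is suspended on `[EP, EP + lock_release]`;
  `u(t)` simply excludes that interval. This is the simplest model
  reproducing the observed delayed filling curves. The default release of
  480 s makes filling complete ~10 min after an injection given 0.5 min
  post-EP, matching the reported lock duration.
* **Constriction** — per vessel class, an instantaneous drop to
  `(1 − amplitude)·baseline` right after EP, recovering linearly (default)
  or exponentially over `recovery_s`. Defaults in the `"ep-constrict"`
  preset: arterioles amplitude 0.70 without recovery inside the 30-min
  window, venules amplitude 0.30 recovering by 840 s — the reported
  magnitudes. Effects apply strictly *after* the EP time because the frame
  timestamped at EP is acquired immediately before the pulses.
* **Leakage** — the tissue intensity grows linearly at
  `leak_rate_per_min` (fraction of the pre-leak tissue level per minute)
  for `leak_linear_s` (default 480 s) after tracer and pulses are both
  present, then plateaus — the reported linear-then-plateau shape.
* **Imaging** — background 0.15 and vascular plateau 0.75 of full scale.
  The background sits 2.5 noise standard deviations above zero at the
  default SNR 10 (defined as plateau amplitude over noise sd), emulating a
  camera offset plus tissue autofluorescence; a lower background would clip
  the noise at zero and bias the tissue mean, which real cameras avoid by
  design. Photobleaching is available (default 0). Bit depth, blur width
  and field of view are configurable defaults, not asserted properties of
  any particular microscope.

A per-animal **vasomotor tone factor** (multiplying all post-EP diameters;
default 1) models slow between-animal tone drift; the cohort simulator
draws it from N(1, 0.01). It makes the between-animal differences
persistent in time, which is what longitudinal diameter data from live
animals look like — without it, consecutive timepoints would be
independent null draws, which real cohorts are not.

Everything the pipeline estimates is emitted as ground truth: the
rendering mask, per-frame noiseless compartment intensities (both the pure
model values and the raster means over the mask), per-segment true
diameters per frame, the lock release and the leakage breakpoint.

What the generator does **not** emulate: flowing erythrocyte texture,
vessel wall contrast, focal drift, breathing motion (the chamber is assumed
perfectly fixed), depth attenuation, and spatially heterogeneous leakage.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated imaging model, not robustness to every
real-world artifact.

## Segmentation

`build_mask()` follows a deliberately parameter-light recipe: temporal
max-projection over a user-designated post-fill window → Gaussian smoothing
(σ = 2 px) → optional white top-hat background removal → Otsu threshold →
removal of components < 20 px → hole filling. The threshold is
data-adaptive, so adding a constant offset to all frames leaves the mask
unchanged. An all-background projection (99th percentile within 5 robust
noise units of the median, noise estimated from below-median pixels only)
yields an empty mask with a warning rather than an error. An optional
user-supplied exclusion mask removes artifacts such as hairs or
reflections.

`extract_traces()` excludes a 3-px dilation ring around the vascular mask
from the tissue compartment. The ring width covers three PSF sigmas of the
default imaging model: with a narrower margin, blurred vascular signal
bleeds into the tissue mean and follows the filling curve, measurably
inflating leakage-rate estimates.

## Kinetic metrics

* `I_max` is the mean of the last three post-injection frames by default
  (a 95th-percentile estimator is available); the filling curve is
  `100·I_v(t)/I_max`.
* "Complete" filling is the first post-injection frame at or above the 95%
  threshold *that stays there for all later frames* (sustained rule;
  threshold configurable). A transient crossing does not count. If the
  level is never sustained the completion time is `NA`, not an error.
* The maximal variation per second uses forward differences with the
  actual per-interval Δt (20 s early, 120 s late), never an assumed
  cadence.
* "Relative variation" is interpreted as the fractional change from a
  reference frame. The reference is the last pre-EP frame when the tracer
  was injected before EP, and the first post-injection frame otherwise.
  The per-minute rate is the OLS slope over the first 8 min after the
  reference (all frames used, less noise-sensitive than endpoint
  differencing, which is also provided); only this window is used because
  extravasation is linear in time there.
* The segmented fit is a continuous two-piece model through the reference
  point, `ΔI(t) = s·(min(t, b) − t_ref)/60`: for each candidate breakpoint
  the slope is a closed-form least-squares solution, candidates run over
  the frame times, and the best is refined continuously between its
  neighbors. A best breakpoint at the candidate-range boundary flags
  "no breakpoint detected" (single-regime data).
* Optional pre-injection background subtraction exists and defaults to
  off, recorded in the call parameters.

## Diameter morphometry

The diameter estimator is the FWHM of the intensity profile perpendicular
to the local centerline direction — standard for fluorescence angiography
and invariant to intensity scaling. Details that matter:

* profiles are sampled with bilinear sub-pixel interpolation at 0.25 px
  steps, half-length three times the expected radius;
* sampling positions sit on the distal 30–90% of the segment, away from
  the branching junction where the parent vessel pollutes profiles;
* the background is estimated per side from the outer 20% of the profile
  and each side's crossing uses its own half-max level, so a bright
  neighbor (or the field border) on one side cannot distort the other;
* a profile whose peak rises less than 10% above the local background is
  "unmeasurable" (an unfilled vessel during the lock), never a spurious
  small diameter; a segment needs at least half its positions measurable;
* the segment diameter is the median over positions (the per-position
  choice is not dictated by the source protocol; the median is robust and
  documented);
* the baseline is the frame nearest to (at or before) the EP time — in
  the standard protocol, 2 min after injection — and the normalized series
  is diameter/baseline, exactly 1 at the baseline frame.

`qc_stable_segments()` mirrors the analyst's vessel selection: segments
whose measured diameter is unavailable or unstable (CV > 5%) over the
filled pre-EP window are excluded before averaging. `classify_vessel()`
implements the morphological convention — narrow, straight, sparsely
branching segments are arterioles, the rest venules — with user labels
taking precedence and conflicting evidence flagged low-confidence.

## Group statistics

The unit of replication is the animal: per-animal means of ≥ 5 vessels per
class, as in the underlying experimental design (n = 3 animals per group);
per-vessel analysis is possible but is pseudoreplication and is not the
default anywhere.

* `timepoint_ttest()` uses the classic equal-variance two-sample t test by
  default (small n, matched design; Welch switchable). Quantized data can
  produce zero-variance groups: equal means then give p = 1, unequal means
  p = 0 with a degeneracy flag. No correction is applied across timepoints
  in this track, mirroring how such per-timepoint comparisons are
  conventionally reported.
* `recovery_time()` operationalizes "diameters returned to pre-EP values
  at time T": the first post-EP grid time that is non-significant *and
  stays non-significant* (a single dip does not count). It is monotone in
  α by construction.
* `oneway_anova()` wraps the standard one-way F test with the same
  degenerate-input conventions.
* `holm_sidak()` implements the step-down procedure: sort ascending,
  compare `p_(i)` against `1 − (1 − α)^{1/(m−i+1)}`, stop at the first
  failure; adjusted p-values are the running maximum of
  `1 − (1 − p_(j))^{m−j+1}`, clamped to [0, 1]. It rejects a superset of
  Bonferroni and a subset of unadjusted testing.

## The two experiment designs and their drivers

`experiment_design()`/`run_experiment()` cover the single-sequence designs:
tracer 2 min before EP (permeability kinetics; segmentation reference
window defaults to the last pre-EP minute, when vessels are filled and
still unconstricted) or tracer at a delay after EP (lock; reference window
defaults to the last three frames). `run_delay_sweep()` runs the resealing
experiment over delays {0.5, 1, 5, 10, 30} min with n = 3 replicates per
condition plus a no-EP control **acquired on the same post-injection
grid** — this matters: the filling phase contributes a small
partial-volume trend to the tissue trace, and measuring control on the
same grid makes that contribution cancel in the condition-vs-control
comparisons. Its true leakage rates default to elevated at 0.5/1/5 min
(0.04/0.035/0.02 per min), intermediate at 10 min (0.008) and
control-level at 30 min (0), with a lognormal between-animal CV of 10% —
a realistic decay consistent with the reported significance pattern. The
lock-duration summary is the smallest tested delay whose completion time
is not significantly different from control (t test, α = 0.05); the
permeability summary is the analogue for the per-minute rate.

## Numerical choices and degenerate inputs

* All times are seconds relative to EP; pixel coordinates are 0-based,
  row-major, pixel centers at integers.
* TIFF stacks round-trip losslessly: frames are quantized to the output
  bit depth at render time and the sidecar stores exact timestamps.
* Frame/timestamp count mismatches, non-increasing timestamps and missing
  pixel sizes abort before any computation.
* Empty vascular masks abort trace extraction (no vascular compartment);
  empty projections only warn.
* Renders where constriction would push a ribbon below 1 px warn and clamp
  at 1 px.
* Ties in the segmented-fit grid resolve to the grid candidate unless the
  continuous refinement strictly improves the residual.

## Problem sizes

The shipped tests and the acceptance script run the simulations at desk
scale: 128–192 px fields, 2–6 segments for kinetics runs, 5 measured
vessels for morphometry runs, 10 seeds for recovery averages, 5 cohort
seeds (6 animals each) for the recovery-time rule, and 1,000 replicates
for the statistical size checks. These sizes were chosen so the whole
validation runs in minutes on a laptop while keeping recovery errors well
inside the stated tolerances; nothing in the method depends on them.

## Known limitations

* The FWHM estimator inherits a blur-induced widening for vessels narrower
  than about four PSF sigmas; constriction amplitudes recovered from very
  thin arterioles are biased low for that reason (the validation uses
  40–60 µm arterioles, where the bias is within tolerance).
* The segmentation is intensity-based; it assumes the chamber is fixed and
  one mask serves the whole sequence, as in the underlying protocol.
* The lock model is a hard gate on perfusion; partial flow during the lock
  is not modeled.
* The leakage model is spatially homogeneous; perivascular gradients are
  ignored by design since the metrics are compartment means.
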