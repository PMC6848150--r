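---
title: "Methods: responder screening in stimulus-locked calcium imaging and nucleated-patch recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: responder screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdrnscreen)
```

This vignette is the package's own account of the models and procedures it
implements, the tunable parameters that matter, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The screening problem

Wide-field calcium imaging of acute slices, with bath electric field
stimulation, gives single-cell resolution over hundreds of neurons at once.
Frames are acquired at 0.1 Hz with every second exposure time-locked to a
stimulus (0.05 Hz), so the recording is a sequence of (resting, stimulated)
frame pairs. The per-cycle activity statistic for a somatic ROI is the
instantaneous ΔF/F, `(F2 − F1) / F1`. A drug applied mid-session (here a
secosteroid at sub-nanomolar concentration; pharmacology is carried as a
condition label only) may increase the stimulus-evoked calcium influx in a
minority of cells; the screen must find those cells against per-cycle noise
and slow nuisance trends, and report the responding fraction with a
defensible denominator.

The companion modality records HVA calcium currents from nucleated somatic
patches under voltage clamp. There the confound is rundown — a progressive
loss of current typical of L-type channels during prolonged recordings —
which the analysis must separate from a genuine drug-evoked increase.

## 2. Imaging pipeline

**Preprocessing.** Frames are registered by FFT cross-correlation against
the first frame (sub-pixel via parabolic peak interpolation; frames with no
variance are flagged and left untouched). Background is the grayscale
opening of the frame with a ball structuring element (default radius 50 px,
the conventional setting at this magnification), i.e. the upper envelope of
a sphere rolled beneath the intensity surface.

Two numerical choices here deserve explanation:

- *Fast mode.* At radii ≥ 8 px the opening is computed on a block-minimum
  downsampled image and bilinearly upsampled (the same strategy ImageJ's
  background subtraction uses). This is accurate when the true background
  is much smoother than the ball, which is the regime the radius is chosen
  for. `method = "exact"` computes the full-resolution morphology.
- *Temporal binning* (`bg_temporal_bin`, default 10 frames). The background
  is a slowly varying nuisance (shading, bleach), but a per-frame estimate
  carries per-frame noise: a minimum filter over noisy pixels fluctuates
  from frame to frame, and that fluctuation enters every ROI mean in the
  frame without being averaged down by mask size. At desk-scale image sizes
  this measurably inflates the per-cycle ΔF/F noise floor (from ~0.006 to
  ~0.015 in the synthetic world). Estimating the background on the mean of
  each bin of consecutive registered frames removes most of this while
  tracking bleach comfortably (a 100-s bin sees < 2% intensity change at
  the default bleach rate). Set the bin to 1 for strictly per-frame
  behaviour.

Note that the rolling-ball *subtraction* is exactly idempotent only when
the residual is itself ball-open: for features sharper than the ball, a
second pass removes a further sliver of height up to
`r − sqrt(r² − ρ²)` (ball sag over a feature of half-width ρ). The opening
operator itself is idempotent exactly; the test suite asserts both facts on
their proper domains.

**ΔF/F, baselining, responder criterion.** Cycles pair each unstimulated
frame with the immediately following stimulated frame; a cycle with
nonpositive F1 is invalid and is dropped, never re-paired. The pre-drug
window (≥ 5 min enforced) is summarised by a flat or sloping baseline;
the sloping model is kept only when the slope t-test is significant at
`alpha` (default **0.01**). This is the one deliberate departure from the
obvious 0.05 convention: a noise-selected slope is extrapolated across the
whole post-drug epoch, so at 0.05 roughly 5% of null cells acquire a
drifting detrended series that systematically crosses a k-SD threshold —
the end-to-end false-positive rate then exceeds the rate the screen is
designed for by an order of magnitude. Genuine slow drifts produce far
smaller p values and are still caught at 0.01.

A cell is a responder when its detrended post-drug ΔF/F exceeds
`k_sd × baseline SD` (default 3) for at least `min_consecutive` cycles
(default 3, i.e. 60 s at 0.05 Hz — the persistence rule separates onsets
from single-cycle excursions). The onset is the first cycle of the first
qualifying run; the percent change averages the detrended deviation from
onset to the end of the recording, relative to the baseline mean. With a
noiseless baseline (SD 0) any sustained positive deviation qualifies and
the threshold is reported as 0.

**QC and denominators.** The counterstain channel (an astrocyte dye that
does not label the neurons of interest) is the focal-plane monitor: a
sustained (≥ 2 frames) change of more than 10% in high-frequency energy
relative to the first frame excludes the whole session, and the first such
frame is reported. Electrical responsiveness requires the baseline-window
mean ΔF/F to exceed twice the pooled per-cycle noise SD (estimated from
cycle-to-cycle differences of resting fluorescence, which carry no stimulus
signal). The responding percentage divides responders — counted only among
counterstain-negative, electrically responsive, in-focus cells — by *all*
in-focus responsive cells regardless of counterstain label. This
denominator can only underestimate the true neuronal responding fraction
(the suite asserts the inequality), which is the safe direction for a
screening claim.

## 3. Synthetic imaging world

The generator renders what the analysis assumes, plus the artifacts it must
survive; every planted parameter is recorded for recovery testing.

- Somata are circular Gaussian profiles (radius 5 px, profile normalised so
  its disk mean is exactly 1) on a planar background — a plane is removed
  exactly by the rolling ball, so background handling is testable to
  machine precision. Cells sit on a jittered grid whose pitch prevents
  overlap; a field too small for the requested count is an error.
- Responder ΔF/F ramps logistically (10–90% rise in 60 s) from the
  planted baseline value to `baseline × (1 + amplitude/100)`. A ramp, not
  a step, makes onset estimation nontrivial.
- Default effect sizes are the stated world of the screen: responder
  fraction 7.3%, amplitudes ~N(24, 14²) clipped to [10, 66.5] %, onsets
  ~N(6.7, 3.6²) min clipped to [2, 15] min after application. The clip at
  10% reflects what the 3-SD criterion can in principle resolve (≈ 7%
  changes at the calibrated noise); amplitudes below that are not
  "responders" in any operational sense. Means and spreads are calibration
  to the reported phenomenology, not blind targets.
- Pixel noise (SD 4.5 camera units against cell amplitudes of ~100) is
  calibrated so that three baseline SDs correspond to roughly a 7% ΔF/F
  change for a typical cell; photobleaching is 2×10⁻⁴ per frame. Resting
  fluorescence and baseline ΔF/F distributions are documented defaults
  (clipped normals), not claims about any particular dataset.
- z-drift events blur and attenuate the counterstain structures from a
  given frame onward; the indicator channel is untouched, since the
  counterstain is the drift monitor.
- One seeded RNG stream per session, per-cell draws consumed in cell-index
  order: identical (config, seed) gives bit-identical stacks.

What a green recovery test establishes: that the pipeline recovers planted
responder identity, amplitude and onset under the stated noise, trend and
drift model. What it does not establish: performance under real optics
(PSF, scattering, photon noise), overlapping or moving somata, inaccurate
ROIs, or non-stationary noise — none of which the generator emulates.

## 4. Ephys pipeline and synthetic sweeps

The generator's macroscopic current is `g_max · m(t)^p · (V − E_rev)` with
Boltzmann steady state (`v_half`, `slope_k`) and first-order activation
(τ = 1.5 ms default); defaults (g_max 8 nS, v_half −10 mV, k 6 mV, p = 2,
E_rev +60 mV) give a bell-shaped I–V peaking near +10 mV with ~340 pA at
0 mV, a plausible HVA phenotype with barium as charge carrier. Sweeps add
linear leak `g_leak (V − V_hold)`, biexponential capacitive transients at
the step edges (τ 0.2 and 1 ms, amplitude linear in the jump — exactly the
linearity P/N subtraction assumes), geometric per-sweep rundown
(memoryless, hence closed-form testable), a saturating drug gain with time
constant 100 s (so a 1.33× gain reaches its asymptote to double precision
within the plateau window of a long noise-free run), and white current
noise. Channel deactivation after the step is not modelled (tail currents
are outside scope), and P/N sub-sweeps contain only the linear components.

Analysis: P/N average scaled by the step-amplitude ratio and subtracted;
peaks taken sign-aware after 2-ms boxcar smoothing, excluding the first
2 ms after step onset where residual capacitive transient can survive
subtraction (the peak estimator is otherwise unstated in common practice —
this one is documented and fixed). The drug-response time course uses the
mean pre-drug peak magnitude (default 6 sweeps = 2 min) as baseline, calls
the onset at the first of ≥ 2 consecutive post-drug sweeps beyond ±2
baseline SDs, and takes the plateau as the last third of the post-drug
epoch (motivated by peak responses arriving within ~8 min). Because
rundown co-occurs with genuine responses, classification is decided
against the extrapolated pre-drug linear trend: plateau above trend beyond
noise → responder; otherwise a significantly negative overall slope →
rundown; else flat. Percent change is computed on magnitudes and is
invariant to amplifier gain rescaling.

## 5. Statistics and reporting

Welch's unpaired two-tailed t test (Welch–Satterthwaite df) is implemented
directly and checked against both closed forms and the reference
implementation; SEM is `s/√n`. p values are rendered to two significant
figures, with `p < 0.0001` as a threshold in the text report only. No
multiple-testing correction is applied (stated in the report footer). The
report emits both slice-level aggregation (mean ± SEM of slice responding
percentages) and pooled cell counts, labelled, since which unit enters a
given comparison is a choice the analyst must see.

## 6. Degenerate inputs, tie-breaks, conventions

- Zero-variance frames: no defined shift; flagged, uncorrected.
- F1 ≤ 0: cycle invalid, excluded from every window.
- Baseline SD = 0 with nonzero post values: responder by convention,
  threshold 0. Zero variance in both Welch samples with equal means:
  statistic undefined, reported `NA`.
- Peak ties resolve to the earliest sample (`which.max` semantics).
- Masks are 1-based column-major linear indices and centers are (row, col)
  1-based — R-native conventions; the on-disk run-length format is
  explicit about rows and columns, so nothing depends on the in-memory
  convention.
- Percentages are rounded to 1 decimal at the reporting boundary only.

## 7. Known limitations

- The rolling-ball fast mode assumes background smoothness at the ball
  scale; pathological backgrounds (sharp shading edges) need
  `method = "exact"`.
- Registration is translation-only, as in routine slice-imaging practice;
  rotation or non-rigid drift is out of scope.
- The ephys generator is macroscopic and deterministic apart from white
  noise: no stochastic gating, no series-resistance error, no capacitance
  compensation beyond the linear P/N assumption.
- Responder classification with strong simultaneous rundown relies on a
  linear rundown extrapolation; strongly non-linear rundown would need a
  different trend model, and in that regime the reported percent change
  (relative to the pre-drug mean) understates the drug effect.
- The synthetic world's cell density, resting-fluorescence scale and noise
  are documented defaults for a scaled-down field, not measurements.
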