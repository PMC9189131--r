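---
title: "Methods: sleep bout segmentation, ALA calcium dynamics and sleep homeostasis"
author: "WormSleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep bout segmentation, ALA calcium dynamics and sleep homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WormSleep)
```

## Background

During lethargus -- the developmentally timed sleep state that precedes
each molt -- *C. elegans* alternates between locomotor quiescence (sleep
bouts) and active locomotion (motion bouts). Sleep bouts are
homeostatically regulated: longer motion bouts are followed by longer
sleep bouts. The interneuron ALA shows a characteristic calcium signature
across this cycle -- intracellular Ca^2+^ ramps up during motion bouts and
decays rapidly at the motion-to-sleep (MS) transition -- making it a
candidate encoder of sleep pressure. This package implements the complete
analysis chain for such recordings, from raw video to homeostasis
statistics, together with a synthetic-data generator that provides inputs
with known ground truth.

## Locomotor scoring by frame subtraction

`calibrateThreshold()` pools the absolute pixel differences of all
consecutive frame pairs of a worm-free chamber recording and sets the
pixel threshold to their mean plus five standard deviations. We use the
population SD; at the 2000 calibration frames typical of a session the
difference from the sample SD is negligible, and the choice is stated here
so it is not an accident of implementation.

`classifyActivity()` counts, per consecutive frame pair, the pixels whose
absolute difference strictly exceeds the calibrated threshold, and judges
the worm locomotor active at a time point iff that count strictly exceeds
100 pixels. Both inequalities are strict, reading "exceeded" literally.
Absolute (not signed) differences are used: movement produces intensity
changes of both signs, and the calibration pools magnitudes.

N frames yield N-1 subtracted images. We assign the state of pair
(i, i+1) to frame i+1 and let frame 1 inherit frame 2's state, so the
activity trace has exactly one entry per frame and stays aligned with the
stack. The sources this analysis follows are silent on this point; the
convention is documented and consistent throughout.

For freely crawling worms in artificial-dirt chambers,
`quiescenceByBodySize()` instead marks a frame quiescent when the
changed-pixel count is strictly below 1% of the worm's body size.
Body size is not measured by any published rule, so `estimateBodySize()`
defines one: Otsu's threshold on the pooled intensities, a
foreground/background separation check (at least 4 background SDs between
the class means -- an empty chamber fails it and raises an error), and the
median foreground area over frames.

## Bout segmentation

`segmentBouts()` partitions the binary activity trace: a maximal quiescent
run is a sleep bout iff its duration is strictly greater than 6 s (5 s in
the optogenetics protocol); every other frame -- active runs and short
quiescent runs alike -- is merged into motion bouts. At 10 fps this means
61 or more quiescent frames; a run of exactly 6.0 s is motion. Intervals
are half-open `[start, end)` in seconds and exact rational multiples of
1/fps, so bout durations sum to the recording length exactly, kinds
alternate strictly, and re-segmenting the reconstructed state vector is
the identity. These invariants are enforced by the `BoutSeries` validity
method and fuzz-tested against an independent run-length oracle.

For bout-level calcium analyses, `filterBouts()` drops bouts of 12 s or
shorter and bouts touching either end of the session. We read "shorter
than 12 s were excluded" as strictly-shorter exclusion in the operation's
worked convention (12.0-s bouts are dropped by the default `> 12` filter;
the `inclusive` argument flips the boundary, since the original boundary
handling is unknowable). Note the deliberate asymmetry with the 6-s sleep
rule, which is strictly-greater-than on the *kept* side.

`fractionOfQuiescence()` uses non-overlapping windows anchored at t = 0
(1.5 min for imaging, 10 min for plate behaviour); a trailing partial
window is reported with its own frame count. Overlapping windows would
smooth the curves but not change any downstream statistic; the
non-overlapping choice is simpler and configurable by passing any window
length.

`detectLethargus()` is deliberately conservative because the published
definition defers to prior work "with modifications" that are not
enumerated: it seeds spans of windows at quiescence fraction >=
`enterThreshold` (default 0.05), extends them while the fraction stays >=
`exitThreshold` (default 0.05), and returns the longest span if it covers
at least `minSpan` (default 20 min). All three knobs are exposed.

## Ratiometric calcium traces

`computeRatioTrace()` implements the fractional change of the GCaMP/RFP
ratio, `(R - R0)/R0`, with `R0` the session mean of `R`. Two algebraic
identities follow and are tested: the session mean of dR/R0 is zero to
numerical precision, and the trace is invariant under scaling either raw
channel by a positive constant. Missing frames are excluded from both
means rather than interpolated, and no detrending or bleach correction is
applied.

The published motion-active criterion -- motion-bout mean dR/R0 exceeding
the session mean "by 20%" -- is degenerate read multiplicatively, because
the session mean of dR/R0 is identically zero. `classifyMotionActive()`
therefore uses an absolute margin: motion-bout mean dR/R0 strictly greater
than 0.20. The margin is an argument, and the degenerate algebra is the
reason the default is absolute.

## Event-aligned analyses

`alignAndAverage()` aligns per-bout traces at the bout start on the native
frame grid and reports mean, SEM and n per time point, omitting points
where n is 10 or fewer (strict `<=`, read literally from "10 or less").

`normalizedProfile()` rescales each bout's duration to 1 and linearly
resamples its trace onto a fixed grid. The grid points sit at bin
midpoints `(i - 0.5)/gridSize` (default 100): with midpoints, the mean of
a linear ramp over the first and fourth quarters of normalized time equals
the continuous values 0.125 and 0.875 exactly, which makes the
quarter-comparison oracle exact rather than grid-size dependent. We read
the published "quadrant" comparison as quartiles of normalized time
(Q1 = [0, 0.25), Q4 = [0.75, 1]); per-bout Q1/Q4 means feed a paired
one-sided Wilcoxon test for the rising-ramp signature.

`transitionTriggered()` computes per-event means over the 12 s before and
after SM or MS transitions, requiring both windows to lie fully inside the
flanking bouts (guaranteed by the 12-s bout filter). `cumulativeLocomotor()`
reports running sums of changed pixels within motion bouts plus a
straight-line R^2 diagnostic for the near-constant locomotor rate.

`peakLatencyCorrelation()` smooths each motion bout's trace with a
centered 1-s moving average (window forced odd; edges truncated, not
padded), takes the peak (earliest frame on ties) and its latency from the
bout start, and fits peak value on latency by OLS with a Pearson
correlation and 95% confidence band. On noise-free linear ramps the
truncated smoothing window shifts every peak by the same constant, so the
fitted slope equals the ramp rate and r = 1 exactly -- the property the
unit tests pin down.

Hypothesis tests themselves (Wilcoxon, Mann-Whitney, t, KS, two-way ANOVA)
are delegated to `stats::`; this package defines which samples enter which
test. Sidak-corrected pairwise contrasts use `1 - (1 - p)^m` directly.

## Sleep homeostasis

`pairSleepWithPriorMotion()` pairs every sleep bout with its immediately
preceding motion bout; pairs involving edge-truncated bouts are excluded
(a truncated duration is not interpretable). `binnedHomeostasisTest()`
groups sleep durations by bins of prior motion duration -- by default two
bins split at the pooled median, since the published bin edges are not
printed and the median split is the natural default; `binEdges` overrides
it. Pairs are pooled across animals by default, matching how bout counts
are reported in this literature; a genotype term adds the two-way ANOVA
with a genotype x bin interaction and per-bin Sidak-corrected contrasts.

## Synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions every validation in this package runs under.

* **Bout schedules** (`simulateBoutSchedule()`): motion durations are
  log-normal with arithmetic mean 30 s and log-SD 0.6 -- positive and
  right-skewed, the shape seen in observed bout-duration histograms; the
  published work characterizes the distribution only through such
  histograms, so the family is a modeling decision exposed in the
  arguments. Sleep duration is `sleepBase + gain x priorMotion + noise`
  (defaults 10 s, 0.5, SD 2 s), floored at 7 s so every simulated sleep
  bout clears the 6-s rule. A 20-min default recording at 10 fps matches
  a 2000-frame imaging session order of magnitude.
* **Calcium** (`simulateCalcium()`): latent signal ramps at 0.08 units/s
  during motion and decays with tau = 3 s during sleep, observed through
  GCaMP (baseline 100, gain 100) and RFP (level 200) with channel noise
  SD 2. The ramp default puts the motion-bout mean dR/R0 near 0.29,
  clearly above the 0.20 motion-active margin, with peak dR/R0 around
  0.8 -- inside the dynamic range GCaMP6s reports for ALA. Integration
  uses exact per-frame updates (linear increment; multiplicative
  `exp(-dt/tau)`), so noise-free traces match the analytic ramp and decay
  closed forms at any frame rate, which the transition-window oracle
  exploits to 1e-6.
* **Video** (`renderVideo()`): a 600-pixel disc (blob realism is
  irrelevant to frame differencing) on a 64 x 64 frame, background 30,
  blob 200, pixel noise SD 2, moving 3 px per motion frame in a random
  cardinal direction. Steps that would cross a border are redirected to a
  direction that fits (reflection is the fallback for frames too small for
  any full step), so the displacement magnitude -- and hence the
  changed-pixel count, about 160 px per motion frame against a calibrated
  false-positive rate below one pixel per frame -- is stable.
* **Optogenetics** (`simulateOptogenetics()`): per-second MS hazard 0.1,
  multiplied by 4 during a 10-s window after stimulation for treated
  trials, 3-s stimulation, 2 fps, latencies geometric on the frame grid.
  Treated and control draws are independent so the null (multiplier 1) is
  exchangeable with nominal type-I error. Per-animal trial limits are a
  property of the acquisition protocol, not the analysis, and are outside
  the simulator's scope.

Every simulator takes a required-by-default `seed` and restores the
caller's RNG state; identical seeds give bit-identical output.

What the generator does *not* emulate: body posture and undulatory
kinematics, pharyngeal pumping, photobleaching or focus drift in the
fluorescence channels, tracking dropouts (the trace functions accept NA
but the generator does not produce them), and multi-neuron structure.
Passing the validation suite therefore shows that the analysis chain is
correct under its stated assumptions -- not that those assumptions
exhaust real recordings.

## Numerical choices and degenerate inputs

* Boundary comparisons (6-s sleep rule, 100-pixel rule, 1%-of-body-size
  rule, 12-s filter, 5-s optogenetics rule, 20% margin, 10-sample
  omission) are all strict; each has a dedicated boundary test.
* Peak ties resolve to the earliest frame; moving-average windows are
  forced odd and truncated at edges.
* Zero-variance inputs degrade explicitly: regressions are reported as
  undefined rather than fitted, zero-variance t tests return NA, an
  all-active trace yields a censored latency.
* Validity methods on the S4 containers enforce tiling, alternation, the
  threshold identity `mean + 5 sd`, and the zero-mean dR/R0 identity at
  construction time.

## Validation problem sizes

The shipped validation suite runs the segmentation oracle on 1000 random
traces (50-5000 frames at 2, 6.67 or 10 fps), the dR/R0 identities on 500
random dual-channel traces, the video pipeline end to end on a 120-s
rendering with a 2000-frame calibration stack, 100 ramp sessions plus
1000 null sessions for the normalized-profile comparison, about 500
homeostasis pairs for gain recovery with 100 + 1000 replicates for the
binned test, and 100 + 500 optogenetic replicates of 100 trials per
group. These sizes give the binomial calibration checks useful power
while keeping the suite quick to run on one core.

## Known limitations

* Lethargus detection is a thresholded heuristic; recordings without a
  clear quiescence block return nothing rather than a best guess.
* The motion-active margin is absolute because the multiplicative reading
  is degenerate; comparisons with analyses that resolved the ambiguity
  differently need the `margin` argument.
* The homeostasis ANOVA treats pooled bouts as independent; the
  per-animal mixed alternative is a deliberate non-default (genotype
  labels enable per-genotype tests, not a random-effects model).
* Censored optogenetic latencies are flagged and excluded from the rank
  tests, which is conservative when censoring is rare (as under the
  default hazards) but not a survival analysis.
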