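---
title: "Phase models, timing ratios and compensation flags: how rehabmm assesses a movement"
author: "rehabmm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase models, timing ratios and compensation flags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabmm)
```

This vignette is the package's own account of its method: the models and
their assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open and a choice
had to be made.

## The phase model

A therapeutic exercise decomposes into successive phases — for hip
abduction of the right leg: beginning pose (state 0), moving up (1),
holding the leg up (2), lowering (3). `rehabmm` models these phases as
the hidden states of an HMM whose observations are per-frame kinematic
features. The joint probability factorizes as
$p(h_1)\,p(o_1\mid h_1)\prod_{i\ge 2} p(h_i\mid h_{i-1})\,p(o_i\mid h_i)$
with an initial distribution $\pi$, a row-stochastic transition matrix
$T$, and one diagonal-covariance Gaussian emission per state.

Assumptions worth stating explicitly:

* **Diagonal Gaussians.** The canonical feature sets are two-dimensional
  and approximately unimodal per phase; mixture emissions are
  deliberately out of scope.
* **Ergodic topology.** No left-to-right constraint is imposed: faulted
  executions revisit phases (a balance wobble re-enters the activity
  state), and the model must be able to represent that.
* **Phases are temporal.** Initialization exploits it: state $l$'s
  emission is initialized from the $l$-th temporal slice of each
  training sequence, $\pi$ is concentrated on state 0 (0.9), and
  transitions start sticky (0.9 self-transition). This biases EM towards
  the phase semantics without constraining it.

Baum–Welch runs until the total log-likelihood gain falls below `tol`
(default `1e-4`) or 200 iterations, with multi-sequence sufficient
statistics, a variance floor of `1e-6`, and re-seeding of any state that
claims less than one expected frame (the only use of the RNG — fits are
deterministic given their seed). Because EM is label-symmetric, fitted
states are then relabeled. Two relabeling conventions are used, chosen
per model role:

* *temporal* (default, used for the 4-state hip model): states ordered
  by average first appearance in the decoded training paths, which pins
  rest = 0 and hold = 2;
* the 3-state trunk model also receives temporal relabeling; its decoded
  morphology on correct trials is rest, then an activity bump, a quiet
  hold, a second bump, and rest — the bump state is visited exactly
  twice, which is the signature later used to detect extra movements.

The forward algorithm and Viterbi decoding run in log space (compiled
recursions) with streaming log-sum-exp, so sequences of $10^5$ frames do
not underflow; Viterbi ties break towards the lower state index, making
decoding deterministic. State-count selection is available as a
cross-validated BIC scan, $k\ln N - 2\ln L$ on held-out frames with
$k = (n-1) + n(n-1) + 2nd$ free parameters.

## Feature representation

All features derive from a body-anchored **personal coordinate system**:
the left–right axis is the hip line projected onto the floor plane, up
is the floor normal (oriented towards the body), front–back is their
cross product, and the origin is the hip midpoint's projection onto the
floor. Positions expressed in this frame are invariant under rotations
about the floor normal and translations along the floor — the subject
may stand anywhere, facing anywhere.

One subtlety matters: **speed features use camera-frame displacements**,
projected onto the per-frame PCS axes (signed channels) or taken as
magnitudes (unsigned channels). Re-expressing positions in the PCS
*before* differentiating would subtract the body's own translation —
and a drifting pelvis, precisely the compensation the method must
detect, would become invisible.

Angles are computed by the law of cosines on inter-joint distances; the
frontal hip angle is measured between the upper-leg vector and the
downward body vertical in the frontal plane, so a standing rest pose
reads 0°. All exposed angles are degrees, angular speeds degrees/s,
linear speeds m/s.

Speeds are denoised with a **trailing buffer** of 15 frames (0.25 s at
the nominal 60 Hz; the length scales as `round(0.25 * frame_rate)` at
other rates): the buffer drops its oldest instantaneous value and adds
the newest each frame, and the stream becomes available once the buffer
fills — the first `buffer_len - 1` outputs are masked. The trailing
(causal) convention matches a real-time pipeline but shifts speed
onsets late by up to a quarter second; the consequences for clipping are
discussed below.

The canonical four-channel vector (hip-center speed, shoulder-center
speed, right-hip frontal angular speed, right-hip frontal angle) is
provided as `abduction_preset()`, alongside auxiliary channels: signed
left/right and up/down pelvis speeds (for error direction) and the
shoulder-center sway excursion (for clipping). The full blueprint of
which feature feeds which model is configurable through `feature_spec()`
and registry entries; only the trunk and right-hip-frontal models (3 and
4 states) plus the pelvis-drift model ship as canonical.

## The assessment blueprint

A trained registry holds one HMM per movement aspect plus the training
statistics that calibrate all thresholds. Assessment of a new trial
computes, per model:

* the **sliding-window forward likelihood** (window 60 frames, stride
  15 by default), per-frame normalized; the minimum-value window is the
  error locus;
* the **Viterbi phase path**, compared against the training-set state
  profile (visit counts and segment durations);
* the **movement clip** from the trunk path: the clip runs from the end
  of the opening rest segment to the start of the closing rest segment,
  and its peak is the deepest valley of the shoulder-center sway
  excursion — the point of maximum amplitude, where the movement
  direction inverts and speed is about zero;
* the **symmetry ratio** (time-to-peak over time-from-peak) and the
  **synchronicity ratio** (trunk-clip lengths on either side of the hip
  hold-phase midpoint, right over left, so values below 1 mean the trunk
  moved early). For averaging, ratios above 1 are replaced by their
  reciprocals, an orientation-invariant `(0, 1]` scale.

### Flag rules and their calibration

Fault flags are deliberately conservative; each rule exists to kill a
specific false-alarm mode observed during design:

* **Low likelihood.** A model flags when at least two windows fall below
  its flag threshold. The threshold is the *training envelope* — the
  worst per-trial minimum window log-likelihood over the training set —
  widened by the larger of the envelope's own spread and a novelty
  margin of 3 nats/frame. Training minima are scored *cross-fold* in
  leave-one-subject-out training (each trial under the registry that
  held its subject out), because in-sample likelihoods are optimistic.
  In this regime healthy held-out subjects stay within a couple of
  nats/frame of the envelope while injected faults overshoot it by an
  order of magnitude, so the operating point is wide rather than
  knife-edge; the test suite asserts the resulting operating
  characteristics (at least 80% of faulted trials flagged, at most 10%
  of clean ones). Requiring two windows reflects the 75% overlap of
  adjacent windows: any real fault spans several.
* **Transition anomalies.** Visit counts only flag for states whose
  training counts are consistent (range at most 1) — the trunk bump
  state's "exactly two visits" is a signature precisely because it never
  varies; ramp states with variable counts carry no count semantics.
  Visits count only segments of at least 15 frames (0.25 s): shorter
  segments are decode blips. Durations are judged on a state's longest
  segment, with the training range widened by a factor 1.25.
* **Ratio anomalies.** Symmetry or synchronicity below the minimum
  training (cross-fold) normalized ratio minus 0.05 flags the trunk or
  hip model respectively.
* **Error direction.** The pelvis-drift model carries signed
  directional-speed features; in each of its flagged windows the
  observed mean of each directional channel is compared with the
  Viterbi-aligned state's emission mean, and the largest absolute
  deviation names the direction ("left", "down", ...).

The **outcome** aggregates: `good` needs zero flags and every model's
worst window at or above the 25th percentile of training minima; `fair`
tolerates one flag with all worst windows above the flag threshold;
anything else is `bad`. Lowering any likelihood or adding any flag can
only worsen the outcome.

### Clipping bias

Because the speed buffer is trailing, decoded rest boundaries sit
slightly late, and slightly differently on the rise and fall sides; a
perfectly symmetric noise-free movement decodes to a symmetry ratio of
roughly 0.9 rather than 1.0 through the full pipeline. On the true phase
segmentation the ratio is exactly 1 (the test suite asserts both). This
bias is common-mode across trials of a cohort, so the ratio *bands*
(calibrated on training trials through the same pipeline) absorb it.

## The synthetic world

No recorded patient data ship with the package, so the generator states
a world explicitly. It emulates a standing subject abducting the right
leg: a raised-cosine angle profile through rest–rise–hold–fall–rest, a
2% settle so the maximum amplitude is attained exactly at the hold
midpoint, trunk lean and pelvis weight-shift towards the stance leg
proportional to the (optionally time-shifted) leg angle, fixed limb
lengths, quaternions consistent with the leg direction, and band-limited
positional jitter.

Defaults, with the reasoning behind each:

| parameter | default | why |
|---|---|---|
| frame rate | 60 Hz | nominal depth-camera skeleton rate |
| phase durations | 1.5 / 2 / 1 / 2 / 1.5 s | a deliberate, slow therapeutic repetition |
| peak abduction | 40° | healthy standing hip-abduction range (35–45° across subjects) |
| trunk sway | 0.05 m | visible but moderate lean over the stance leg |
| pelvis shift | 0.02 m | the weight transfer that accompanies single-leg stance |
| jitter sd | 0.002 m | post-tracking jitter scale; smoothed with a Gaussian kernel (sd 0.25 s) because tracker output is band-limited — white 60 Hz noise would put a velocity-noise floor above every genuine trunk speed |
| wobble | 0.04 m pulse, sd 0.15 s | a caught balance loss: out-and-back sway at the hold midpoint |
| end drift | 0.08 m | leftward pelvis deviation over the movement's final second (adduction compensation) |
| trunk shift | 30 frames | 0.5 s of trunk lead (incoordination) |
| asymmetry | ×1.6 | fall takes 60% longer than rise |
| reduced ROM | ×0.5 | half the prescribed amplitude |

Cohorts add per-subject idiosyncrasies (phase durations ±15%, peak angle
35–45°, sway and jitter levels) and auto-generate three-rater labels:
clean trials are good on all aspects; a faulted trial is rated fair or
bad by fault magnitude on the aspect its fault affects (range of motion,
coordination, or compensation). Fault injection is localized: frames
outside a fault's support are bit-identical to the unfaulted trial at
the same seed.

**What the generator does not emulate** — and therefore what a green
test does *not* establish: loose-clothing tracking corruption, occlusion,
real anthropometric variation (one template skeleton is used), muscle
dynamics and fatigue, exercises with genuinely different kinematic
structure (other exercises ship as parameter presets of the same
abduction kinematics), and rater disagreement (simulated raters agree).
Green tests establish that the pipeline recovers the structure this
world states — phase segmentations, timing ratios, fault signatures —
not that it would achieve the same rates on clinical recordings.

One stated-world finding is worth flagging: trunk-lead faults of
0.3–0.6 s are *not* reliably separable from healthy synchronicity
scatter (the published healthy per-trial ratios themselves range from
0.46 to 1.0 on the normalized scale). The cohort-level detection
criterion is met by the other four fault kinds, which are detected
essentially always.

## Numerical choices

* Log-space forward/backward/Viterbi with streaming log-sum-exp;
  probabilities are clamped at `1e-300` before taking logs so structural
  zeros stay representable.
* Variance floor `1e-6` on every emission variance, applied at
  construction and after every M-step.
* EM stops on a log-likelihood gain below `1e-4` or 200 iterations;
  the monotonicity of the trace (within `1e-8`) is asserted in tests.
* Viterbi ties break towards the lower state index; `which.min` ties in
  clipping take the earliest frame.
* Degenerate inputs raise classed errors (`rehabmm_*_error`): coincident
  joints, vertically stacked hips, all-rest paths, ratios with empty
  denominators, observation/model arity mismatches.
* Every stochastic entry point takes an explicit integer seed and
  restores the caller's RNG state; trial seeds drawn inside cohorts stay
  below $2^{30}$.

## Open design decisions

Decisions taken where the problem statement left the design open, in the
package's own judgement:

* **Synchronicity orientation.** The ratio is right-length over
  left-length of the trunk clip about the hold midpoint, so that values
  below 1 mean the trunk moved early; the reciprocal-normalized form
  used for averages is identical under either orientation.
* **Clipping signal.** The trunk "signal" whose valley marks the
  movement center is the negated absolute lateral excursion of the
  shoulder center: its extremum is the point of maximum amplitude where
  speed vanishes, which a speed magnitude cannot mark.
* **Threshold design.** Percentile thresholds at 5% per model were
  rejected after they produced a familywise false-alarm rate far above
  the intended operating point in leave-one-subject-out use; the
  envelope-plus-margin rule above replaced them. The good/fair boundary
  keeps the 25th-percentile convention.
* **The pelvis-drift model.** The canonical trunk and hip models use
  unsigned speeds, which cannot name a direction; a third registry
  entry with signed pelvis speeds exists solely to localize and label
  directional compensations. Like all registry slots it is
  configuration, not hard-wired.
* **Hold-segment choice.** When a faulted trial has several hold
  segments, the synchronicity midpoint uses the longest one — the
  dominant hold phase.
* **Label consensus.** A trial counts as correct for training when a
  strict majority of raters labels every aspect good.

## Known limitations

* Likelihood magnitudes are implementation-specific (per-frame
  normalized log-likelihoods are reported precisely because raw
  "probability" scores are not comparable across implementations).
* The symmetry peak is ambiguous within a long hold plateau under
  realistic jitter: the ratio is a reported measurement with healthy
  scatter, not a sharp fault detector; duration-based flags carry the
  asymmetry detection.
* With eight training subjects, a held-out subject at the edge of the
  kinematic envelope can still produce occasional likelihood flags;
  the margin rule bounds, but cannot eliminate, this.
* Hidden semi-Markov duration modelling, mixture emissions and
  force/effort assessment are out of scope.
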