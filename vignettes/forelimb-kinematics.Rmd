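---
title: "Joint coordinate system kinematics of the rodent forelimb: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint coordinate system kinematics of the rodent forelimb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forelimbkin)
```

## The problem this package addresses

Biplanar videoradiography reconstructs the three-dimensional motion of
individual bones during locomotion, either by tracking implanted
radio-opaque beads (marker-based) or by manually registering bone models to
both X-ray views frame by frame (markerless rotoscoping).  For the walking
rat forelimb, the scientifically interesting quantities are the six
degrees of freedom of three virtual joints — shoulder (humerus relative to
the body midline), elbow (ulna relative to the humerus) and radioulnar
(radius relative to the ulna) — because long-axis rotation (LAR) of the
humerus and radius, invisible to conventional 2-D gait analysis, governs
how the manus stays pronated under load and supinates during swing.

`forelimbkin` implements the complete quantitative chain behind such a
study: camera calibration and triangulation, rigid-body pose estimation
from markers, a hierarchical joint-coordinate-system (JCS) rig with Euler
ZYX angles, step-cycle segmentation and ensemble averaging, excursion
statistics, and a gold-standard accuracy/precision framework.  Because raw
videoradiographic data cannot ship with a package, a forward-kinematic gait
simulator generates ground-truthed trials with the statistical and phase
structure the analysis assumes, so the whole pipeline is testable end to
end: the generator's configured quantities must be recovered by the
analysis through every intervening stage.

## The kinematic model

### Poses and Euler ZYX angles

A bone's pose is a proper rigid transform $(R, t)$ with $R \in SO(3)$ and
$t$ in mm.  Joint rotations are intrinsic Euler ZYX:
$R = R_z(\gamma)\,R_y(\beta)\,R_x(\alpha)$, right-hand rule, so rotating
the Z axis carries the Y and X axes with it.  The canonical decomposition
branch keeps $\beta \in [-90°, 90°]$ and the other two angles in
$(-180°, 180°]$.  At gimbal lock ($|\cos\beta| < 10^{-8}$) only
$\gamma \pm \alpha$ is observable; the package resolves the indeterminacy
deterministically by setting $\alpha := 0$, absorbing the coupled rotation
into $\gamma$, and flagging the frame.  Flags propagate through
`jcs_decompose()` as a warning plus a `gimbal_frames` attribute rather than
silently altering the series.  The default walking waveforms keep $\beta$
far from $\pm 90°$, so gimbal frames do not arise in simulated gait; the
convention exists to make behaviour at pathological inputs testable.

Per-frame decompositions are unwrapped over time (successive differences
≤ 180°) and each channel is re-centred so its median lies in
$(-180°, 180°]$.  The re-centring matters for the radioulnar joint, whose
pronation plateau sits at 180°: measurement noise makes raw frames
alternate between just under $+180°$ and just over $-180°$, and unwrap
plus median re-centring restores one continuous branch near $+180°$.

### The chain, its reference pose and the JCS frames

The default rig links body → humerus → ulna → radius.  The body frame
plays the role of the sternum/midline reference; a root JCS tracks it in
the world so that whole-body motion is absorbed by the root and never
contaminates the anatomical joints (this is tested as an exact
invariance).  The world frame is right-handed with +X the direction of
travel, +Y the animal's left, +Z up.

The reference ("zero") pose standardises measurement and is deliberately
not a feasible posture: the humerus lies horizontal beneath the body
frame; the ulna is folded so the anatomical elbow angle reads 0°; the
radius is rotated 180° from its most pronated orientation, i.e. fully
supinated.  Every JCS is constructed so that all six DOF read exactly
zero in this configuration.  Each JCS is a world frame at reference
(origin + axis triad); the fixed parent-side and child-side transforms are
derived from the bones' reference poses, and forward kinematics composes
`parent ∘ A ∘ T(dof) ∘ B⁻¹` down the chain.  `jcs_decompose()` inverts
this exactly (mutual-inverse round trips are tested to 1e-8).

Axis semantics follow veterinary convention and are stored on each JCS as
labels plus ±1 sign maps: shoulder Z protraction (−) / retraction (+),
Y abduction (−) / adduction (+), X medial (−) / lateral (+) LAR; elbow Z
on the anatomical scale (0° folded, < 90° flexed, ≥ 90° extended);
radioulnar X rising towards 180° with pronation.  In the default rig the
JCS axis directions were chosen so the raw senses already coincide with
the reporting conventions (all signs +1); `apply_sign_conventions()`
still validates, supports custom sign maps, and flags converted series so
the map can never be applied twice silently.

The default metric geometry (humerus 30 mm, ulna 35 mm, radius 33 mm,
joint offsets of a few mm) is package plumbing with no claim of anatomical
fidelity — only the topology and the axis conventions matter for the
joint-angle algebra, and everything is configurable through
`default_chain_config()`.

### Rigid-body fitting and cameras

Pose estimation from markers is the standard SVD (Kabsch) solution of the
orthogonal Procrustes problem with a reflection guard on the smallest
singular vector.  Markers must be non-collinear (smallest principal
spread > 1e-6 mm); fits report an RMS per-marker residual.

Cameras are ideal 11-parameter direct linear transformations (DLT);
image distortion is assumed removed upstream and is out of scope.
Calibration centres and scales world points before the linear solve;
triangulation stacks both cameras' linearised projection rows into a 4×3
least-squares system and refuses near-parallel geometry (condition number
> 1e8).  The packaged 48-sphere calibration object (three tiers of a 4×4
grid) mirrors standard biplanar calibration hardware.

## Step-cycle analysis

Stance detection tracks the distal-ulna landmark — a proxy for the wrist,
chosen because the ulna moves essentially in flexion/extension only.
Frames whose smoothed landmark speed falls below 10% of the trial's peak
smoothed speed are stance; the speed series uses forward differences with
a 5-frame centred moving average, and segments shorter than 10 frames (at
250 Hz) are merged into their neighbours.  These thresholds are exposed as
arguments; no principled universal value exists for "static", so the
defaults are package choices documented here.

Cycles run touchdown to touchdown.  A stance segment that opens a trial is
not a verified touchdown (recordings typically begin mid-cycle) and is
discarded, as are trailing partials.  Within a cycle, frame $f$ maps to
$100\,(f - f_{td})/L$ percent-of-cycle; 20 bins of 5% pool samples across
cycles and trials, reporting per-bin mean, SD (across pooled samples) and
count.  Excursion summaries (min/max/range/mean/median per joint/axis)
pool frames across all trials; in the end-to-end pipeline they pool only
frames belonging to complete cycles, which both matches how partial cycles
are treated in real recordings and keeps filter edge transients out of the
pooled extrema.

The elbow–supination coupling is summarised as the Pearson correlation of
the two 20-bin averaged curves.  With the reporting conventions here
(smaller elbow angle = more flexed; smaller radioulnar X = more
supinated), flexion–supination coupling appears as a positive coefficient.
Note the null distribution of $r$ at 20 bins is wide (SD ≈ 0.23), so only
the sign — not the magnitude — is a meaningful claim at this resolution.

## The synthetic gait generator

### What it emulates

`default_rat_profile()` encodes one walking step cycle at 250 frames/s,
0.5 s duration, 64% stance, with per-joint keypoint waveforms interpolated
by shape-preserving (Fritsch–Carlson) cubics.  Shape preservation is
essential: interpolants that overshoot their keypoints would break the
configured excursion envelope, which is exactly what the recovery tests
measure.  The envelope and phase structure encode the walking-rat
kinematics the package targets:

* shoulder Z from −97° (maximal protraction, near touchdown) to +31°
  (maximal retraction, just after toe-off);
* shoulder Y between −36° and +3°, abducting through swing;
* shoulder X between −14° and +40°, rotating medially through stance;
* elbow Z between 30° and 123°: ~70° at touchdown, a brief extension to
  ~90°, ~10° of yield under load, peak extension just before toe-off and
  maximal flexion mid-swing;
* radioulnar X: a fully pronated plateau at 180° through the first half
  of the cycle, lateral rotation from ~50% onward, most supinated
  (~160° on average) near 75% of the cycle — in phase with elbow flexion —
  then re-pronation before the next touchdown.

The exact curve shapes between keypoints follow the qualitative narrative
of walking-rat studies and are a package artifact, not measured data.

### Between-trial variability

Radius supination depth varies between trials of real animals by roughly
10–30°.  The profile encodes this as a deterministic cohort schedule:
trial $i$ of $n$ scales the supination dip (the deviation from the 180°
pronation anchor) by a factor evenly spaced in $[0.5, 1.5]$, so a 10-trial
cohort spans dips of 10–30° with mean 20°.  A deterministic schedule was
chosen over random draws because the pooled minimum is an order statistic:
random amplitudes would make the cohort's pooled envelope itself random,
which is not how a study's reported envelope behaves.  Other axes carry no
between-trial scaling; their pooled envelope equals the single-trial
envelope.  The generator does not attempt a fitted between-animal variance
model — that structure is not quantified in the literature this emulates.

### The body frame and the stance constraint

Rather than translating the body at constant velocity and hoping the limb
waveforms cancel it during stance, the generator solves the body
trajectory from the stance constraint: during stance the world position of
the distal-ulna landmark is pinned at the footfall point; over swing it
advances one stride (mean speed × cycle duration, default 300 mm/s × 0.5 s
= 150 mm) under a trapezoidal speed profile with 10% ramps.  The body
translation is whatever makes that true given the joint waveforms.  This
produces a foot that is exactly static in stance — the property the stance
detector assumes — at the cost of a body frame that wobbles slightly
instead of gliding; for testing the analysis chain this trade is the right
one.  The trapezoid ramps keep the speed's threshold crossing within about
one frame of the true phase boundary, so detected stance fractions land
within a point or two of the configured 64% (the residual ~1-point
negative bias comes from the 5-frame speed smoothing at the boundaries).

### Measurement noise and marker placement

`render_markers()` adds isotropic Gaussian noise (default σ = 0.1 mm) to
world marker positions, and/or projects noiseless markers through a
calibrated camera pair adding image noise (default 0.5 px).  Each bone
carries six markers distributed along its shaft with 4 mm transverse
offsets, emulating beads implanted along the bone including the wider
epiphyses.  The transverse spread matters: rotation about a bone's long
axis is constrained only by off-axis markers, so LAR is always the
noisiest channel (here ~0.5–0.8° per-frame at σ = 0.1 mm, against
~0.2–0.3° for flexion axes).  Tight marker triads would push per-frame LAR
noise past 1° and make pooled min/max excursions unrecoverable at the
stated tolerances — which is also why real studies quote their worst
accuracy on LAR axes.

### Filtering

Pooled minima and maxima are order statistics: over ~4000 pooled frames
even 0.5° of per-frame noise inflates a range by several degrees.  The
pipeline therefore low-pass filters marker trajectories (zero-phase
4th-order Butterworth) before rigid fitting, the standard treatment for
marker jitter in skeletal kinematics.  The default cutoff is 15 Hz —
roughly the 7th harmonic of the 2 Hz stride — chosen to pass the sharpest
real feature (the mid-swing elbow flexion peak, which a 10–12 Hz cutoff
visibly attenuates) while suppressing enough noise that pooled ranges stay
within ±2° of truth.  Series are reflection-padded before `filtfilt` to
limit edge transients.  Gait-event detection deliberately uses the
*unfiltered* fit: zero-phase smoothing spreads the foot's static-to-moving
transition over the filter's response width and biases stance duration by
several percentage points, while the threshold detector needs no noise
suppression (the speed threshold sits an order of magnitude above the
noise floor).

## Validation framework

`accuracy_residuals()` compares any two angle streams per joint and DOF by
mean absolute residual, SD and maximum — the gold-standard accuracy design
in which marker-driven poses provide ground truth for a candidate
reconstruction.  "Mean residual" is implemented as the mean of absolute
values (the alternative — absolute value of the mean — would reward
sign-cancelling errors).  Residuals are computed on unwrapped,
sign-converted series so a 360° wrap or a convention flip can never
masquerade as error, and the metric is symmetric.  On noiseless synthetic
data the full pipeline's residuals are below 1e-6°, orders of magnitude
inside the 1.4–3.6° envelope typical of manual rotoscoping — a sanity
ceiling, not a target.  `precision_repeated()` summarises repeated
registrations of a single frame by per-DOF SD and range; note that at
K = 10 repeats the SD estimate itself has ~24% sampling spread.

## Problem sizes and numerical choices

The packaged validation runs 10 trials × 3 cycles × 125 frames at 250 Hz
(~4400 frames, ~26000 pose fits including the event-detection track),
which exercises every stage in well under two minutes on one core; tests
use smaller cohorts where the full size adds nothing.  Tolerances follow
the error structure: exact-arithmetic paths (Euler round trips, noiseless
fits, FK/inverse) are tested at 1e-8 to 1e-10; stochastic recoveries at
the tolerances the study design supports (±2° on pooled excursion ranges,
±2 points on stance fraction, ±3° on binned supination depth).  Stochastic
tests fix their seeds; the generator itself contains no hidden global
RNG state (noise seeds are explicit, and the RNG state is saved and
restored around rendering).

## Known limitations

* The rig's metric geometry is schematic; absolute translations are
  reported but carry no anatomical meaning, and translation channels are
  excluded from the headline excursion table.
* The scapula is not modelled (as in the markerless studies this
  emulates); shoulder motion is humerus-relative-to-body-midline.
* Synthetic markers are rigidly bone-fixed: no soft-tissue artifact, no
  marker occlusion or tracking loss, and noise is white — real bead
  tracking errors are temporally correlated.  Passing recovery tests
  therefore demonstrates correctness of the analysis chain, not robustness
  to every failure mode of real videoradiography.
* The camera model is an ideal DLT: no lens or image-intensifier
  distortion, exactly two views.
* Waveform shapes between keypoints, and the deterministic between-trial
  amplitude schedule, are modelling conveniences; only the envelope, the
  phase landmarks and the stance fraction are treated as study conditions.
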