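---
title: "Detecting abnormal gait with a one-class codeword HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting abnormal gait with a one-class codeword HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitnorm)
```

## The problem and the model

Clinical gait screening asks a one-class question: given recordings of
*normal* walking only, flag walks that deviate from that learned range —
without any prior model of the particular pathology (shuffling, stiff leg,
asymmetric stride, unsteady timing). `gaitnorm` implements a detector for 3D
skeleton streams such as those produced by consumer depth cameras (Kinect v1:
20 named joints at 30 fps; the OpenNI 15-joint variant is accepted with
reduced features).

The detector has four stages.

**1. Posture features.** Each frame is summarised by seven joint angles of
the lower body — left/right hip, left/right knee, left/right ankle included
angles, plus the angle between the two leg planes (each plane spanned by a
leg's hip, knee and ankle; normals taken as
$(\mathrm{knee}-\mathrm{hip}) \times (\mathrm{ankle}-\mathrm{knee})$ with the
same operand order for both legs). Angles are invariant under rotation,
translation and uniform scaling, so subject height, position and heading do
not matter. Upper-body joints are ignored: lower-limb motion is the
established clinical signal and depth-camera arm tracking is unreliable
under self-occlusion.

**2. Vector quantization.** Posture vectors are clustered with $k$-means
(Lloyd's algorithm, Euclidean distance, seeded $k$-means++ initialisation,
10 restarts, convergence at $10^{-6}$ centroid motion; an emptied cluster is
reseeded at the point farthest from its centroid). Every frame becomes the
integer index of its nearest centroid — a *codeword*. No feature scaling is
applied; all features are angles in radians on comparable scales. The
codebook is fit on training (normal) cycles only, so no information leaks
from evaluation data.

**3. Gait cycles.** The Euclidean distance between the two feet is a
quasi-periodic signal peaking at every double support. It is smoothed with
first-order exponential smoothing, $s_t = \alpha x_t + (1-\alpha)s_{t-1}$
($s_0 = x_0$), and a frame is a cycle boundary when it is the *strict*
maximum of the sliding window centred on it. A cycle is the inclusive span
between consecutive boundaries; cycles shorter than `min_cycle_frames` are
discarded as noise artifacts. Note the unit: the foot-to-foot distance peaks
twice per stride, so these cycles are *steps* (maxima-to-maxima segments),
not full strides.

**4. Normality model and threshold.** The codeword sequences of normal
cycles train a left-right (Bakis) discrete-observation HMM: states are
ordered, transitions only persist or advance
($a_{ij} = 0$ for $j < i$ or $j > i+1$; no return from the last state to the
first), and the chain starts in state 1. Training is multi-sequence
Baum–Welch from a seeded random initialisation; the structural zeros are
preserved exactly by the EM updates. A cycle is scored by the scaled forward
algorithm (natural log, exact over all state paths). The anomaly threshold
is learned from the training scores $\zeta_i$ as

$$\mathrm{threshold} = \mu + \lambda\,\sigma,\qquad
  \sigma = \sqrt{\tfrac{1}{n}\sum_i(\zeta_i-\mu)^2},$$

with population (divide-by-$n$) standard deviation. A cycle is abnormal iff
its $\zeta$ is *strictly* below the threshold. For whole walking sequences,
`score_sequence()` takes the minimum over all windows of three consecutive
cycles of the window-mean $\zeta$ — a sustained-abnormality score robust to
a single noisy cycle (sequences with fewer than three cycles are scored by
their plain mean).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.2 | smoothing factor; removes foot-jitter while keeping the peak structure |
| `window` | 5 frames | sliding window for strict-maximum boundary detection |
| `min_cycle_frames` | 10 | discard implausibly short cycles (noise peaks) |
| `k` | 43 | codewords = HMM observation symbols |
| `n_states` | 24 | left-right HMM states |
| `lambda` | −1.28 | threshold constant; $\Phi^{-1}(0.10)$ to two decimals, i.e. the Gaussian 10th percentile of training scores |
| `train_fraction` | 0.75 | share of normal cycles used for training; the rest is held out |

`k = 43` and `n_states = 24` are the model size that maximised detection
accuracy in the reference experiments this package re-implements;
`grid_search()` reproduces that kind of model selection (accuracy over a
states × codewords grid, ties broken toward the cheaper model).
With `lambda = -1.28` about 10% of genuinely normal cycles are expected to
fall below the threshold, trading specificity for sensitivity.

## Numerical choices and degenerate inputs

* **Raw log-likelihoods.** Scores are *not* length-normalised: an unusually
  long (slow) cycle is itself evidence of abnormality, and normalisation
  would discard it. The converse is a known limitation — an abnormally
  *short* cycle scores less negative than typical normal cycles and cannot
  be caught by a lower-tail threshold.
* **Emission flooring.** After training, emission probabilities are floored
  at $10^{-8}$ and renormalised. A codeword never seen in training then
  yields a very low finite score instead of $-\infty$, which would break the
  threshold formula when it occurs in a training fold.
* **Strict maxima.** Plateau ties produce no boundary; this avoids duplicate
  boundaries on flat tops of smoothed signals. The centred window equals the
  online trailing-window rule with a fixed $(\mathrm{window}-1)/2$-frame
  reporting delay.
* **Degenerate geometry.** A momentarily straight leg (collinear
  hip–knee–ankle) has no defined plane; during extraction the previous
  frame's two-feet angle is carried forward (0 at the first frame) so the
  feature stream never contains `NA` or errors mid-walk. Zero-length limb
  vectors raise an error naming the frame.
* **Ties in encoding** go to the lowest centroid index; the encoder is
  deterministic and idempotent.
* **Seeding.** Every stochastic stage (simulator, $k$-means++, restarts,
  train/test split, HMM initialisation) derives from one user seed, making
  whole runs — including serialized model files — reproducible byte for byte.

## Design decisions where the design was open

* **Joint triples.** The hip angle uses HipCenter as its third joint
  (configurable in principle; Spine would be the alternative); knee and
  ankle angles use the anatomically standard included-angle triples. Any
  consistent choice yields an equivalent codebook.
* **Leg plane.** The two-feet angle uses the (hip, knee, ankle) plane, which
  is computable on reduced 15-joint skeletons; in that mode only the two
  ankle angles are masked, leaving five features. `sphere_compat = TRUE`
  additionally masks the plane angle for strict four-feature compatibility
  with OpenNI-style pipelines.
* **Topology.** The most constrained sequential reading — self and
  next-state transitions only — is the default; `allow_skip = TRUE` permits
  one-state skips. The initial distribution is fixed at state 1 rather than
  estimated, implementing the argument that a cycle-aligned model should not
  treat every state as a possible start.
* **Cycle unit.** Maxima-to-maxima segments (steps) are used exactly as the
  segmentation defines them; merging step pairs into strides was considered
  and deliberately not made the default.
* **Codewords are 1-based** (`1..k`), following R indexing conventions.

## The synthetic walker: what it emulates, and what it does not

`simulate_gait()` is a seeded planar (sagittal-plane) kinematic walker: the
pelvis translates at constant speed; per leg, hip flexion is
$A_h \sin(2\pi t/T + \phi)$ and knee flexion
$A_k \max(0, \sin(2\pi t/T + \phi + \pi/2))$ plus a constant 0.08 rad
stance-phase flexion, with the legs in anti-phase
($\phi_{left}=0, \phi_{right}=\pi$). Joints follow two-segment forward
kinematics; feet continue along the shin with a fixed dorsiflexion offset;
Gaussian noise (default 5 mm, typical depth-camera joint jitter) is added to
every coordinate last. The small constant stance flexion is deliberate:
with the knee locking fully straight, the leg plane would be undefined for
half of every stride and the two-feet angle would degenerate; a few degrees
of standing knee flexion is also the physiological norm. Ground truth
records the analytic joint angles and the noise-free foot-distance maxima.

Abnormal types map to clinically motivated perturbations: `asymmetric`
scales one leg's hip and knee amplitudes (unequal stride lengths),
`stiff_knee` scales one knee's amplitude only, `shuffling` scales both legs'
amplitudes (short flat steps), `irregular` jitters each stride's period.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: ground-contact physics, pelvic tilt and trunk
compensation, out-of-sagittal-plane motion (the true two-feet angle is
therefore constant and its measured value is noise-driven), skeleton-tracking
outliers and dropouts, and inter-subject variability. Real pathological gait
also alters the *unaffected* side through compensation; the simulator's
one-sided perturbations do not, with a measurable consequence discussed
below.

## Problem sizes and what the checks show

The test suite and `scripts/acceptance.R` work at desk scale: the reference
study trains on 150 simulated normal cycles and evaluates 50 held-out normal
plus 150 abnormal cycles (50 each of asymmetric, stiff-knee, shuffling),
once at a deliberately small online model (16 codewords, 12 states) and once
at the full selected size (43 codewords, 24 states). These sizes keep a full
run in tens of seconds while exercising every stage end to end.

A structural property of the simulator shows up clearly in those runs: with
strictly one-sided perturbations and the step-level cycle unit, the step led
by the *unaffected* leg is kinematically indistinguishable from a normal
step (the affected knee only flexes during its own swing), so roughly a
third of "abnormal" cycles are intrinsically near-normal and per-cycle
sensitivity plateaus around 0.7 at the small model size. The full-size model
recovers high accuracy by resolving the subtler boundary-phase shifts. Both
numbers are recomputed, not quoted, by `scripts/acceptance.R`; sequence-level
scoring (`score_sequence()`) is the practical answer when whole walks, not
single steps, are the unit of decision.

## Known limitations

* One-class only: the model reports *how unusual*, never *which pathology*.
* Abnormally fast/short cycles evade a lower-tail threshold on raw
  log-likelihood.
* Curved walking trajectories are not handled; recordings are assumed to be
  straight walkway passes.
* The simulator is a testing instrument, not a biomechanical model; results
  on it bound software correctness, not clinical performance.
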