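---
title: "Decoding the content and production of vocalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the content and production of vocalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vocalinfo)
```

## The scientific problem

Speech dissociates *what* is said from *how* it is produced: the same vowel
can be spoken aloud or merely imagined. The rule-based vocalization task
this package models instructs both dimensions sequentially — one of two
vowels (/u/, a strongly articulated vowel, or /ə/, a neutral one) and one
of two production forms (vocalized or imagined) — with 100-ms visual cues
separated by 2-s delays, in both cue orders and with counterbalanced
glyph-to-meaning assignments. The analysis question is whether, in the
delay periods *before* any overt behavior, multichannel MEG patterns carry
information about each variable, how stable each representation is over
time, and how much the two representations overlap.

## The estimator

All decoding rests on cross-validated MANOVA pattern distinctness. Per
cross-validation fold, condition-mean coefficients are fit by least squares
on the training and test splits separately (for an indicator design these
are per-condition channel means),

$$B = X^{+} Y ,$$

and the noise precision is estimated from training residuals of the data
averaged over the window from first-cue offset to go-cue onset:

$$\Sigma^{-1} = (f_E - p - 1)\,(\Xi'\Xi)^{-1}, \qquad
  \Xi = Y^{tw} - X B^{tw}, \quad f_E = n_{train} - \mathrm{rank}(X),$$

where $p$ is the channel count. The $(f_E - p - 1)$ factor makes the
inverse-Wishart estimate unbiased; it requires $f_E - p - 1 > 0$, which is
why sensor-level analyses run on a spatially subsampled channel set
(137 of 273 at full scale, by farthest-point selection).

Given zero-sum condition contrasts $C_{train}$ and $C_{test}$, the pattern
distinctness of one train/test instance is

$$D = \frac{1}{n}\,\mathrm{tr}\!\Big(B_{train}' C_{train}
      (C_{train}'C_{train})^{+}\,
      \big[C_{train}' X_{test}'X_{test} C_{train}\big]\,
      (C_{test}'C_{test})^{+} C_{test}' B_{test}\,\Sigma^{-1}\Big),$$

with $n$ the number of test trials in the fold. Three properties the test
suite verifies directly:

- **Unbiasedness.** $B_{test}$ is independent of everything train-derived
  and has mean zero after contrast projection, so $E[D] = 0$ under the
  null; sampling noise can make $D$ negative.
- **Affine invariance.** Any fixed invertible channel mixing applied to
  all data cancels between the coefficient patterns and the re-estimated
  precision, leaving $D$ unchanged.
- **Scale freedom.** Only the column spaces of the contrasts matter; when
  $C_{train} = C_{test}$ the expression reduces to the familiar
  contrast-subspace projector form
  $\mathrm{tr}(B' P\, X'X\, P\, B\, \Sigma^{-1})/n$ with
  $P = C (C'C)^{+} C'$.

A note on the middle factor: writing the test-design normalization with
the *training* contrast on both sides, rather than as a projector product
$P_{train} X'X P_{test}$, is essential for cross-decoding. With orthogonal
train and test contrasts under a balanced design the projector product is
identically zero, which would make cross-variable information vanish by
construction rather than by data; the form used here instead couples the
two contrast patterns through channel space and satisfies the
expected-cross-information identity below.

### Cross-decoding variants

Training and testing can differ in time point (temporal generalization),
variable (content → production), condition subset (split analyses: train
on all conditions, test on one level of the other variable), and session
(twofold cross-validation with the two recording sessions as alternating
train/test sets). The cross-session variant doubles as the cue-confound
control: glyph-locked additive patterns cancel in the balanced contrasts,
and block-specific pattern drifts are independent across sessions, so a
purely visual confound contributes no information in expectation — the
test suite plants exactly this failure mode and verifies both the
within-session inflation and the cross-session cancellation.

### Expected cross-information

The attainable cross-decoding between two contexts depends on how much
information each context carries. The benchmark for *identical*
representations up to magnitude is the signed geometric mean

$$E_{12} = \mathrm{sign}(D_1)\,\mathrm{sign}(D_2)\sqrt{|D_1 D_2|} ,$$

computed via the absolute product so that negative (noise-dominated)
inputs do not produce square roots of negative numbers, with the sign
convention preserving directionality. Observed cross-information
significantly below $E_{12}$ indicates non-identical representations.

### Cross-validation scheme

Five folds, stratified by the full 16-level condition code so every
condition is estimable in every split, repeated 20 times with independent
fold assignments (defaults of `foldScheme`); folds, then repetitions, are
averaged. The precision matrix is re-estimated within every fold of every
repetition. Sessions of a subject are averaged at the D level before group
statistics.

## Group statistics

Information is averaged in two delay windows — 250 ms after first-cue
offset to second-cue onset (350–2100 ms), and 250 ms after second-cue
offset to go-cue onset (2450–4200 ms) — the 250-ms exclusions discard the
cue-evoked transients that a glyph confound would affect. Temporal
generalization is averaged over train × test rectangles with the diagonal
± 100 ms removed. Information is tested against zero with one-tailed
one-sample t tests; cross-information is tested against its expected value
with one-tailed paired t tests; split comparisons use two-tailed paired
t tests. p-values are Benjamini–Hochberg corrected within the family of
tested intervals of one analysis. The 100-ms-FWHM Hann smoother exists for
visualization only and is never applied before statistics.

## The synthetic-data generator

The generator is first-class, tested code: it forward-simulates the full
experiment so that every downstream stage can be validated against known
ground truth without any recorded data.

**What it emulates.** The 4-rule block session design (16 conditions,
20 trials per condition per block, 320 trials per session, reversed block
order in session 2); condition-specific source patterns with the assumed
representational structure — a stable content axis $u_c$, an early
production axis $u_{pe}$, a late motor-program axis $u_{pl}$ whose ramp
starts only at the second cue (once both variables are known), and a
shared effort axis $u_{eff}$; spatially correlated (random SPD mixing,
condition number capped at 10) and temporally autocorrelated (AR(1),
$\varphi = 0.7$) sensor noise behind a distance-decaying synthetic
leadfield; left-biased pattern mass via the weight $\lambda$; a session-2
perturbation (per-channel gain scaling, a rigid rotation of the source
cloud, and per-channel sensitivity-direction tilt) emulating head
repositioning; an optional glyph-locked cue pattern with per-block drift
(the visual confound); and per-trial audio whose vocal onsets are drawn
from $N(0.58, 0.12^2)$ s after the go cue.

**The effort model.** Each factor's effort multiplier ramps from that
factor's own instruction cue:
$m_{eff}(t) = a_{eff}\, u_{eff}\, (e_v(t)\, e_p(t) - 1)$ with
$e_v(t) = 1 + (e(\text{vowel}) - 1)\, g(t;\ \text{content cue})$ and
analogously for production, where $e(u) > e(ə)$ and
$e(\text{vocalized}) > e(\text{imagined})$. This keeps the generator
causal — no variable contributes information before its cue — while
placing both variables on a shared axis, which is what produces positive
cross-variable information in delay 1 and the higher information in
conditions with stronger motor involvement.

**Ramp shape.** Activation builds up as a logistic saturation
$g(t) = \sigma\big((t - t_0 - \tau) / (\tau/4)\big)$ for $t \ge t_0$
(exactly zero before the cue), with time constant $\tau = 300$ ms: smooth,
monotone, two parameters.

**Calibrated working point.** No numeric effect sizes exist to copy, so
the defaults are fixed once as the package's own calibration: amplitudes
$a_c = 1$, $a_p = 1$, $a_{late} = 0.8$, $a_{eff} = 1$ on unit-norm axes,
effort scalars $1.3 / 0.7$, sensor noise SD 1, trial-amplitude jitter SD
0.15, laterality $\lambda = 0.7$. At these values a simulated cohort
reproduces the qualitative significance layout of the within-session
analyses (content decodable from its cue onward, production only after its
cue, both sustained) while null plants remain null. Two designed
experiments in the acceptance suite use deliberate plants: an effort-only
plant ($a_{eff} = 2$, other amplitudes zero) to isolate the shared axis,
and an effort-heavy plant ($a_{eff} = 1.6$, effort scalars $1.4/0.6$) for
the split-condition comparisons, whose signal-to-noise ratio is otherwise
dominated by per-subject pattern geometry.

**What it does not emulate.** Real head anatomy and tissue conductivity
(the leadfield is a smooth synthetic gain model), biological artifacts
(heartbeat, eye movements, muscle — the ICA stage is accordingly an
identity hook), slow nonstationary drifts, behavioral errors (correctness
flags default to all-correct), and aborted-fixation or training trials.
Passing tests therefore demonstrate the correctness and calibration of the
*analysis machinery*, not the realism of any particular neural claim.

## Source analysis

Unit-gain LCMV beamformer weights
$W = (L' C^{-1} L)^{-1} L' C^{-1}$ are computed per source from the sensor
covariance with 5% diagonal loading (the field does not agree on a single
value; 5% of the mean sensor variance is a conventional, conservative
choice). Searchlights comprise the three dipole directions of a source and
those of its immediate graph neighbors (distance-threshold graph at 1.5 ×
the median nearest-neighbor spacing, nearest neighbor always included);
locations whose searchlight dimension violates $f_E - p - 1 > 0$ are
marked not estimable rather than silently dropped. The lateralization
index is the mean left-hemisphere minus mean right-hemisphere searchlight
information. Hemisphere labels come from a median split of the lateral
coordinate, which equals the sign split for symmetric clouds and
guarantees balanced hemispheres for any source count.

## Preprocessing

The pipeline order is fixed: jump repair → 30-Hz zero-phase sixth-order
Butterworth low-pass → anti-aliased resampling to 300 Hz → 10-Hz low-pass
(same filter design; the second cutoff is assumed to share the design of
the first) → baseline correction on the 500 ms before the first cue.
Channel jumps are detected as first differences exceeding 20 robust SDs
(MAD) of the trace's differences and corrected by step subtraction — the
detection rule is this package's construction, as only the step itself is
conventionally specified. The vocal-onset detector rectifies the audio
before median smoothing (an envelope is needed for a one-sided threshold),
uses a 42.66-ms median window (100 samples at the 2343.75-Hz microphone
rate), and thresholds at the reference-segment RMS plus 8 SDs; the
manual per-participant threshold adjustments used with very soft voices
are replaced by a single configurable multiplier, because manual steps are
not reproducible.

## Numerical choices

- Pseudoinverses (SVD, tolerance $10^{-10}$ × largest singular value) for
  $C'C$ and $X^{+}$; Cholesky-based inversion for $\Xi'\Xi$ (errors on
  rank deficiency rather than silently regularizing).
- Zero-phase filtering pads each trace by odd reflection around its
  endpoints after removing the endpoint-to-endpoint linear trend, which
  suppresses filtfilt edge transients and preserves constant traces
  exactly.
- Resampling interpolates onto a grid anchored at $t = 0$, keeping
  cue-locked alignment within half a sample.
- The $1/n$ prefactor uses the number of test trials of the fold, making
  D scale-free in trial count and the temporal-generalization diagonal
  equal to per-timepoint decoding.
- Degenerate inputs error loudly: zero-variance t tests, empty delay
  windows, fully diagonal-excluded rectangles, conditions missing from a
  fold, upsampling requests, cutoffs at or above Nyquist.
- The identical-input paired t test returns $t = 0$ (two-tailed $p = 1$)
  instead of erroring, since "no difference" is the correct inference for
  literally identical samples.

## Problem sizes

Full-scale geometry (273 sensors with a 137-channel analysis subset, 457
sources, 300 Hz) is available through `experimentConfig`. The test and
acceptance suites run reduced profiles chosen for minutes-level runtimes:
16–40 channels, 12–30 sources, 8–40 Hz sampling, cohorts of 5–24 simulated
subjects, 300–500 simulations for null calibration and false-positive
rates. These sizes are the package's own validation choices; the
statistical properties they verify (unbiasedness, invariance, calibration,
qualitative structure recovery) are dimension-independent.

## Known limitations

- The effort axis is a single shared direction; graded or
  condition-specific effort geometries are not modeled.
- The synthetic leadfield is smooth and spherically symmetric; localization
  performance on it is optimistic relative to real anatomy.
- Cross-session decoding assumes channel-aligned sessions; co-registration
  of real sessions is out of scope.
- Single-trial classification outputs are not provided; the estimator
  quantifies information, not trialwise decisions.
- Serialization uses plain-text TSV tables; large binary containers are
  not written by the package.
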