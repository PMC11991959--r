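---
title: "Scoring sleep and arousals from respiratory effort: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sleep and arousals from respiratory effort: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ripsleep)
```

## The problem

Polysomnography scores sleep states (Wake, NREM, REM; 30-s epochs) and
arousals (≥ 3-s awakening-like events) from EEG, EOG and EMG. Home
sleep tests lack those channels, so they cannot measure total sleep
time (TST) or the arousal index (ArI) — quantities that matter both
diagnostically (sleep fragmentation) and for computing indices such as
the AHI, whose denominator is sleep time. `ripsleep` scores both from
the two respiratory inductance plethysmography (RIP) belts alone,
exploiting state-dependent breathing physiology: monotonous
metabolically-driven breathing in NREM; variable amplitude and timing
in REM together with paradoxical chest-wall motion (the thorax moves
inward during inspiration when intercostal tone is lost); volitional
irregularity, sighs and movements in wake; and the transient gasp-like
ventilatory response (VRA) with shortened inspiratory time that
follows an arousal.

## The synthetic study conditions

No public two-belt dataset with epoch-level staging and per-second
arousal annotations exists, so the package carries a first-class
generator whose defaults define the study conditions used by all tests
and by the acceptance script.

**Sleep macro-structure** is a semi-Markov process over
Wake/NREM/REM: bout dwell times are a per-state minimum plus an
exponential (WAKE 180/30 s mean/min, NREM 1140/300 s, REM 600/120 s),
with an embedded no-self-transition chain. This produces realistic
bouts rather than epoch-wise noise; stationary time fractions are
roughly 7% wake, 71% NREM, 22% REM within the night, and recordings
begin and end in WAKE. The Monte-Carlo test compares generated REM
fractions against an independently re-implemented simulator of the
same process.

**Breathing** is rendered breath-by-breath: each breath has a period
(~4 s with state-dependent jitter), an amplitude (coefficient of
variation 4% in NREM, 20% in REM, 35% in wake, with sighs and
breath-holds in wake), an inspiratory fraction (~0.42), and a
piecewise-cosine volume template plus a small random second harmonic.
The thorax channel is a gain-scaled copy of the abdomen drive; in REM
the gain is `1 − 2 · rem_paradox_factor` (default 0.7, i.e. gain −0.4),
so belt correlation flips negative — the paradox a classifier can
exploit. Wake adds sparse band-limited movement bursts. Each arousal
multiplies breath amplitude by `vra_gain` (default 1.8) for 10 s with a
10-s linear decay and shortens inspiration; apneas attenuate both belts
to 5% and hypopneas by 70% for their duration. Slow (< 0.02 Hz)
sinusoidal drift and white noise are added per channel, and the whole
recording is scaled into arbitrary inductance units.

**Events.** Respiratory events (10–25 s, 30% apneas) are placed only
inside sleep spans with ≥ 5-s gaps at a rate targeting the configured
AHI (default 15/h; clinical populations centre near 27 ± 25/h).
Arousals (3–12 s, default 20/h) are split between respiratory-linked
(onset 0.5–10 s after an event's end; default fraction 0.5, matching
the reported median near 49%) and spontaneous ones placed so that no
respiratory event intersects their 15-s look-back window. All
randomness flows through one seed; identical configs are bit-identical.

**What the generator does not emulate** — cardiogenic oscillations,
position changes, belt slippage, pediatric patterns, scorer
disagreement, and the full diversity of clinical pathology. Passing
the synthetic-recovery tests therefore demonstrates that the pipeline
is implemented correctly and that the learning task is solvable; it
does not certify clinical performance on real recordings.

## Preprocessing

Baseline removal must kill drift below ~0.1 Hz while preserving the
breathing band, and must recover quickly from large steps (movement).
The implementation subtracts a 20-s running-median baseline (smoothed
by a 10-s moving average so breathing-band ripple cannot leak through
the estimate), shrinking the median window to 2 s wherever the 1-s
residual RMS exceeds 3× its 30-s RMS (movement gating), then applies a
3rd-order Butterworth high-pass at 0.1 Hz forward-backward (zero
phase; 6th-order magnitude). The measured contract: DC rejected
essentially completely, 0.05 Hz attenuated to < 2%, 0.2 Hz preserved
at ~98%, re-convergence within seconds of a 5× step, and idempotence
to ~0.2% RMS in the settled interior. Channels are resampled to 25 Hz
(polyphase, anti-aliased) and scaled by the pooled median absolute
deviation, since inductance units are arbitrary.

Each scored epoch is presented to the model as a 9-epoch context
window (4 before, 4 after; 6,750 samples/channel). Edge epochs obtain
context by replicating the first/last epoch, so every epoch receives a
prediction. A second is arousal-positive if any part of it overlaps an
arousal event — the natural convention at ≥ 3-s event granularity.

## The model

A temporal convolutional network with two task heads sharing a trunk:

* encoder: two stride-5 convolutions (kernel 7) taking the 2 × 6,750
  input to a 16-channel 1 Hz sequence (270 steps);
* trunk: six residual blocks (two dilated kernel-7 convolutions each,
  dilations 1, 2, 4, 8, 16, 32; batch normalization; ReLU; spatial
  dropout 0.1), non-causal/centred since future context is an input by
  design. The receptive field is 18,937 input samples — comfortably
  covering the window;
* heads: state logits from mean-pooled center-epoch features (3-way
  softmax), and a 1×1 convolution over the 30 center steps (sigmoid)
  for per-second arousal probabilities.

At ~24k parameters the model is deliberately desk-scale: the synthetic
classes are separable by simple amplitude-variability and
belt-correlation features (a hand-coded discriminant reaches ~85%
3-state accuracy), so capacity is not the binding constraint. Depth,
width, kernel and dilations are all exposed in `model_config()`;
construction fails if the configured receptive field does not cover
the window. Forward/backward passes are hand-written (RcppArmadillo
kernels for convolution, batch norm, ReLU and channel dropout) and
validated against a pure-R reference and finite-difference gradients.

Training minimizes `state cross-entropy + λ · per-second arousal
cross-entropy` (λ = 1) with AdamW (lr 3e-3, decoupled weight decay
1e-4 on weights only). Batches of 32 windows are drawn
arousal-balanced (each draw positive with probability 0.5) with
augmentation: per-channel scaling (0.8–1.25) and whole-window shifts
up to ±4 s applied at extraction from the night, with targets shifted
consistently. The tuning split is evaluated every 100 steps; the
best-on-tune parameters are returned, and training stops early after
10 stale evaluations. A non-finite loss aborts with a diagnostic.
Everything is reproducible from one seed on one device.

**Prediction contract.** Only the center epoch's outputs are emitted
per window; a recording is scored by sliding the window one epoch at a
time and concatenating, giving exactly one hypnodensity triplet per
epoch and one arousal probability per second. Emitting all nine epochs
with overlap-averaging would also be defensible; the single-center
contract was chosen for its unambiguous output shape.

## Scoring rules

The hypnogram is the per-epoch argmax refined by a sliding mode filter
(window 5 epochs; ties keep the center's argmax; `smooth_window = 1`
disables it). The mode filter realizes the intended smoothing of
consecutive state outputs while being trivially testable; it can never
introduce a state absent from the local window.

Arousals are maximal runs of seconds whose probability strictly
exceeds the threshold, kept if ≥ 3 s. Boundary seconds exactly at the
threshold are excluded; runs separated by a single sub-threshold
second stay distinct (no gap merging, and no additional inter-arousal
sleep rule is imposed). The threshold defaults to 0.5 and
`calibrate_threshold()` selects it on the tuning split by event-level
F1 — never on test data. Arousals scored during predicted wake are
dropped from sleep summaries. TST is 0.5 min per sleep epoch (ARTIFACT
epochs count in neither direction); ArI is `60 · events / TST`.

## Agreement statistics

Epoch metrics use the standard formulas (sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)`, accuracy, `F1 = 2TP/(2TP+FP+FN)`), reported
in percent; zero denominators yield flagged `NA`s, never silent zeros.
Sleep states use one-vs-rest collapses of the 3×3 matrix; arousal
agreement is epoch presence/absence. Cohen's κ corrects agreement for
chance via the marginals. Artifact epochs are excluded everywhere.

Patient-level agreement uses Bland–Altman (differences are
**algorithm − reference**, so positive bias = overestimation; limits
are `bias ± 1.96 SD`; a proportionality slope is fit by least squares
of difference on pair mean) and ICC(2,1) — two-way random effects,
absolute agreement, single measure, the standard form for method
comparison, computed from the ANOVA sums of squares. Confidence
intervals are percentile bootstrap (10,000 iterations for reported
CIs; smaller defaults in interactive use), resampling subjects — or
whole recordings for pooled epoch metrics, respecting within-subject
correlation. AHI strata use left-closed boundaries at 5, 15 and 30;
PLMSI splits at 15. An arousal is respiratory-linked when an
apnea/hypopnea intersects `[onset − 15 s, onset)`; interpreting
"occurrence" as interval intersection (rather than keying on event
ends only) is the broadest reading and is fixed throughout.

## Numerical and design choices

* Strict `>` at the arousal threshold; per-second grid half-open
  `[t, t + 1)`; epochs 0-based.
* Mode-filter ties keep the center epoch's argmax (idempotent on
  alternating sequences).
* He initialization; batch norm uses batch statistics in training and
  running statistics (momentum 0.1) in evaluation, so evaluation is
  batch-independent and deterministic.
* Percentile (not BCa) bootstrap; the interval is undefined if the
  statistic fails in more than half the resamples.
* EDF is written with 1-s records, 16-bit samples, physical scaling
  per channel range; round trips are exact to quantization.
* Degenerate inputs fail loudly: empty signals, mismatched lengths,
  non-simplex probability rows, overlapping respiratory events,
  out-of-bounds events, zero TST, zero between-subject variance.

## Problem sizes

The recovery study trains on 6 synthetic nights of 6 h (4,320 windows,
above the 3,000-window floor), tunes on 1 night and holds out 2
nights, with 600 optimizer steps of batch 32 — about 4 minutes on one
CPU. Under these conditions the pipeline reaches held-out 3-state
κ ≈ 0.97, event-level arousal F1 ≈ 0.97, and recovers the planted ArI
with bias well under 20% of the rate (the test suite asserts the
conservative floors κ ≥ 0.6 and F1 ≥ 0.5). These sizes are the
package's chosen defaults for a desk-scale demonstration; scaling the
cohort up is a matter of configuration.

## Known limitations

* The synthetic physiology is stylized; real RIP data add sensor
  artifacts, belt drift and inter-scorer noise the generator does not
  model, so synthetic performance overstates clinical performance.
* N1/N2/N3 are not sub-staged; apnea/hypopnea detection is out of
  scope (reference respiratory events are inputs).
* The TCN is intentionally small; clinical-scale training would need
  larger capacity and a GPU framework.
* Bootstrap CIs for pooled epoch metrics resample recordings; with few
  recordings the intervals are coarse.
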