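# ripsleep

Sleep-state and arousal scoring from respiratory effort alone.

Home sleep tests record breathing but not the brain: without EEG they
cannot say when the patient was asleep, which state they were in, or how
often they aroused. Yet breathing itself carries that information —
NREM breathing is metabolically driven and monotonous, REM breathing is
variable with paradoxical (phase-opposed) chest motion as the
intercostal muscles lose tone, wakefulness shows volitional overwrite
(sighs, movements, breath-holds), and each arousal triggers a gasp-like
ventilatory response (VRA) with shortened inspiration. `ripsleep`
implements a complete pipeline that exploits this physiology to score
sleep from the two respiratory inductance plethysmography (RIP) belts
every home sleep test already records.

The pipeline, for sleep researchers and biomedical-signal engineers:

- **Synthetic data generator** — seeded overnight two-belt RIP
  recordings with known ground truth: a semi-Markov hypnogram,
  state-dependent breath synthesis, planted apneas/hypopneas at a
  configurable AHI, respiratory-linked and spontaneous arousals with
  VRA signatures, drift and sensor noise. Since clinical RIP datasets
  are proprietary, the generator defines the package's study
  conditions.
- **Preprocessing** — adaptive baseline removal (movement-gated median
  tracker + zero-phase high-pass: ≤ 0.05 Hz attenuated ≥ 90%, the
  breathing band ≥ 0.2 Hz preserved ≥ 90%), resampling to 25 Hz, robust
  amplitude normalization, and 9-epoch context windows (4 epochs each
  side of the scored epoch; 6,750 samples per channel).
- **Model** — a multi-task temporal convolutional network (TCN):
  strided encoder to a 1 Hz trunk, six residual blocks with dilations
  1–32 (receptive field 18,937 samples, covering the full window), a
  softmax head for the center epoch's state (Wake/NREM/REM) and a
  sigmoid head for 30 per-second arousal probabilities. Training uses
  AdamW on `state cross-entropy + λ · arousal cross-entropy`, batch
  normalization, spatial dropout, scale/shift augmentation, and
  balanced sampling (50% arousal-containing windows). Forward and
  backward passes are implemented in the package (RcppArmadillo
  kernels), verified against finite differences.
- **Scoring rules** — hypnogram = per-epoch argmax + sliding mode
  filter; an arousal is scored when the per-second probability exceeds
  a threshold for ≥ 3 consecutive seconds; TST (min) and ArI
  (arousals/hour of sleep) summaries.
- **Agreement statistics** — confusion matrices (with artifact
  exclusion), sensitivity/specificity/accuracy/F1 (`sens = TP/(TP+FN)`,
  `F1 = 2TP/(2TP+FP+FN)`), one-vs-rest class metrics, Cohen's κ,
  percentile bootstrap CIs (subject-level resampling), Bland–Altman
  bias and limits of agreement `bias ± 1.96 SD` with proportionality
  slope, ICC(2,1), AHI-severity stratification (<5 / 5–15 / 15–30 /
  ≥30), and the 15-s respiratory-arousal linkage rule.
- **IO / CLI** — EDF read/write (16-bit, "Thorax"/"Abdomen" channels),
  plain-text annotation sidecars, JSON summaries, and a
  `simulate | preprocess | train | score | evaluate` command line
  (`inst/cli/ripsleep`).

## Worked example

```r
library(ripsleep)

# a 2-hour synthetic night with known truth
night <- generate_night(synth_config(duration_hours = 2, seed = 3))
night$recording
#> <rip_recording: 2 x 180000 samples @ 25 Hz (2.00 h)>
round(c(ahi = night$truth$ahi, ari = night$truth$ari), 1)
#>  ahi  ari
#> 14.9 20.2

# preprocess and assemble model windows
rec <- preprocess_recording(night$recording)
ws  <- assemble_windows(rec, night$truth$hypnogram, night$truth$arousals)
ws
#> <rip_windows: 240 windows of 9 epochs x 750 samples>

# train a small model (about a minute here; the full-scale recovery
# study in scripts/acceptance.R takes ~4 minutes), then score the night
fit <- train_nbs(build_model(model_config(), seed = 42), ws, ws,
                 train_config(steps = 200, seed = 42))
sc  <- score_recording(fit$model, ws, threshold = 0.4)
sc
#> <nbs_scoring: TST 114.0 min, 38 arousals, ArI 20.0 /h>
# (ground truth: TST 113.0 min, planted ArI 20.2/h)

# agreement against ground truth
cm <- epoch_confusion(night$truth$hypnogram, sc$hypnogram)
cohen_kappa(cm)
#> [1] 0.9784599
glance(bland_altman(c(10, 20, 30), c(12, 19, 33)))
```

`autoplot()` renders hypnodensity and Bland–Altman plots;
`plot_hypnogram()` and `plot_arousal_track()` show scored nights.

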