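# vocalinfo

Decoding what a person is about to say, and how they are going to say it,
from noninvasive brain recordings.

`vocalinfo` implements a complete multivariate-pattern-analysis pipeline for
a rule-based vocalization experiment: participants are instructed, by two
sequential visual cues in randomized order, to overtly vocalize or covertly
imagine one of two vowels (/u/ or /ə/). The scientific question is whether
the *content* of the upcoming vocalization (which vowel) and its *production
form* (overt vs. covert) have dissociable neural representations in the
seconds before execution, how those representations evolve over time, and
how much they overlap.

The package provides, as tested R functions over S4 containers:

- **Task design** (`buildSessionDesign`): the 4-rule block structure
  (2 cue orders × 2 glyph assignments), 16 conditions, 20 trials per
  condition per block, 320 trials per session, reversed block order in the
  second session.
- **Forward simulation** (`simulateSession`, `effectSpec`, `noiseSpec`):
  multichannel epochs with planted representational structure — a stable
  content axis, an early production axis, a late motor-program component
  that appears once both variables are known, and a shared effort axis
  scaled by motor involvement — projected through a synthetic leadfield
  into spatially and temporally correlated sensor noise, plus per-trial
  audio with realistic vocal latencies.
- **Preprocessing** (`preprocess`, `detectVocalOnset`,
  `selectValidTrials`, `selectSensorSubset`): jump repair, zero-phase
  Butterworth filtering, anti-aliased resampling, baseline correction,
  envelope-threshold vocal-onset detection, and farthest-point sensor
  subsetting.
- **Cross-validated MANOVA** (`cvInformation` and friends): the core
  estimator of pattern distinctness

  D = (1/n) · tr( B'<sub>train</sub> C<sub>train</sub> (C'<sub>train</sub>C<sub>train</sub>)⁺ · [C'<sub>train</sub> X'<sub>test</sub>X<sub>test</sub> C<sub>train</sub>] · (C'<sub>test</sub>C<sub>test</sub>)⁺ C'<sub>test</sub> B<sub>test</sub> · Σ⁻¹ )

  where B are condition-mean coefficients from independent data splits,
  C are zero-sum condition contrasts, and Σ⁻¹ = (f<sub>E</sub> − p − 1)(Ξ'Ξ)⁻¹ is
  the bias-corrected noise precision from training residuals. Because
  training and test estimates are independent, E[D] = 0 when no effect
  exists. Variants decode across time (`crossTimeInformation`), across
  variables (`crossVariableInformation`), within condition splits
  (`splitConditionInformation`) and across sessions
  (`crossSessionInformation`, the cue-confound control). The
  expected-cross-information benchmark `expectedCrossInformation(D1, D2) =
  sign(D1)sign(D2)√|D1·D2|` is the value cross-decoding would reach for
  identical representations.
- **Source analysis** (`lcmvWeights`, `projectToSources`,
  `searchlightInformation`, `lateralizationIndex`): unit-gain LCMV
  beamforming, searchlights over each source's three dipole directions
  plus immediate neighbors, and the left-minus-right lateralization index.
- **Group statistics** (`averageDelay`, `averageCrossTimeWindow`,
  `oneSampleT`, `pairedT`, `fdrBH`, `hanningSmooth`): delay-window
  averaging with 250-ms post-cue exclusion, diagonal-band exclusion for
  temporal generalization, one-tailed and paired t tests,
  Benjamini–Hochberg FDR over tested intervals, and a 100-ms-FWHM Hann
  smoother for plots.
- **Orchestration** (`experimentConfig`, `runExperiment`,
  `cohortStructureMetrics`): seeded end-to-end simulated experiments with
  group tables.

## Worked example

Simulate one session at a small profile, decode both variables in the
content-first cue order, and average over the two statistical delay
windows (delay 1: after the first cue; delay 2: after the second):

```r
library(vocalinfo)

space     <- makeSourceSpace(60, seed = 1)
leadfield <- makeLeadfield(space, 32, seed = 1)
effect    <- effectSpec(space, seed = 2)       # calibrated default plant
noise     <- noiseSpec(seed = 3)
design    <- buildSessionDesign("P01", session = 1, seed = 42)
sim    <- simulateSession(design, effect, noise, leadfield, space,
                          seed = 7, fs = 40)
epochs <- baselineCorrect(sim@epochs)

folds <- foldScheme(nFolds = 5, nReps = 2, seed = 9)
content    <- cvInformation(epochs, makeContrast("content",
                            orders = "content_first"), folds)
production <- cvInformation(epochs, makeContrast("production",
                            orders = "content_first"), folds)
round(rbind(content    = averageDelay(content),
            production = averageDelay(production)), 4)
#>            delay1 delay2
#> content    2.3176 2.4832
#> production 0.0060 2.4564
```

The numbers are pattern distinctness D (arbitrary units; zero in
expectation without a true effect). The layout is the scientifically
meaningful part: with content instructed first, content information is
present in both delays, while production information appears only after
the production cue — the participant's brain cannot represent what it has
not yet been told. The benchmark for representational overlap:

```r
expectedCrossInformation(0.01, 0.04)
#> [1] 0.02
```

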