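---
title: "Semantic decoding of visual scenes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic decoding of visual scenes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdecode)
```

This vignette documents the models this package implements, the
assumptions they rest on, the parameters that matter, and the design
choices made where the procedure was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The semantic space

A scene's semantic vector is the two-level average of word-embedding
vectors over its annotations: tokens are averaged within each annotation,
and the per-annotator vectors are averaged across annotators
(`build_scene_vector()`). This relies on the approximate linearity of
word-embedding spaces — the mean of token vectors is a usable sentence
representation. The tokenizer is a pluggable interface; the default
lowercases and splits on whitespace/punctuation. Morphological analysis
(lemmatization) for specific languages is intentionally out of scope — a
caller can pass any tokenizer. Annotations whose tokens are all outside
the embedding vocabulary raise an error naming the scene; we do not impute.

Category vectors: `v_word` and `v_landscape` are the embedding vectors of
those tokens; `v_face` averages the vectors of "human" and "face".
`fit_pca()` wraps `prcomp()` and additionally fixes each direction's sign
(largest-magnitude loading positive) so projected correlations are
reproducible across runs — PCA directions are otherwise sign-ambiguous.

**Zero-variance rule.** Wherever correlations feed a ranking or a
classification (scene selection, scene identification, image selection,
category classification), the Pearson correlation of a zero-variance
vector is *defined* as 0 and a warning is emitted. This keeps degenerate
decoders comparable instead of undefined; it also means a constant decoder
scores 0 on scene identification, which is the strict reading of the
pairwise-comparison formula (ties count as failures).

## 2. High-γ features

Band powers use a single Hamming-window FFT periodogram per 1-s window
(no Welch segmenting), density-normalized, one-sided. Band means include
both band edges and always exclude the DC bin: re-referenced signals are
near zero-mean and no analysis band reaches 0 Hz. Whether the original
analysis used half-open bin conventions or zero-padding is not knowable
from the outside; the inclusive convention is documented rather than
inferred. The high-γ raw feature is the square root of the 80–150-Hz band
mean (µV/Hz^0.5).

Two compensation schemes correct for impedance/gain drift between
sessions: the resting scheme divides by the ratio of summed baseline
features to summed reference-baseline features; the image-matched scheme
divides by the mean of per-image feature ratios. Both are exactly
invariant to a multiplicative gain applied to a whole session (signal and
its baseline), which the test suite asserts to 1e-10. The
channel-stability filter discards a channel when the *sample* (n−1)
standard deviation of its baseline ratios exceeds 0.5 in at least one
video; the divisor convention is a choice (the conventional default) since
either reading is possible.

Fisher z-transforms clip |r| at 1−1e-7 so that identical repetitions in
the consistency map produce a large finite value, never an infinity.

The time–frequency map (`stft_spectrogram()`) is a plain short-time
Fourier transform reported in dB relative to a stated baseline interval.
It is a deliberate simplification of wavelet-style decompositions; the
imagery analysis only relies on dB differences between conditions, which
survive this simplification.

## 3. Low-level stimulus features

Motion energy uses quadrature spatiotemporal Gabor pairs over 8 motion
directions, spatial frequencies {0, 1.5, 3, 6, 12, 24} cycles/image and
temporal frequencies {0, 2, 4} Hz, on a square grid spaced at 4 spatial-
envelope SDs. The envelope SD per spatial frequency is *not* fully
determined by that description; we tie it to the carrier (1 cycle per SD,
configurable). Consequently the channel count is a pure function of the
configuration but will generally not equal any particular published count;
this is documented rather than forced. Zero-frequency filters get a single
direction and grid position (direction is undefined at DC), and all
band-pass spatial filters are made exactly zero-mean so uniform frames
yield zero energy. Energies are log-transformed with ε = 1e-8 inside the
log so uniform or silent input stays finite.

Auditory features follow the modulation-transfer scheme: a 128-band
spectrogram (25-ms windows, 10-ms steps, bands log-spaced 20 Hz–10 kHz),
100 modulation-selective filters (10 spectral scales × 10 temporal rates,
complex Gabors along the log-frequency and time axes — the filter shapes
are a documented choice, as is the scale range 0.25–8 cyc/oct and rate
range 1–32 Hz), log-transformed and pooled over time and over 20
log-spaced output bands: exactly 100 × 20 = 2000 features for any valid
input. Each spectrogram band is demeaned over time before modulation
filtering and the modulation kernels themselves are zero-mean: a
modulation filter measures fluctuation about the stationary band level,
and without both steps kernel truncation at the 1-s window edges would let
low-rate channels respond to the (much larger) mean band power. Synthetic drifting gratings and AM tones exercise both banks
without any video or audio codec.

## 4. Decoding

`semantic_decoder()` fits one ridge regression per output dimension with a
shared penalty, on z-scored features, via a single SVD of the
standardized design — all grid penalties then cost only a diagonal
reweighting. Standardization statistics come from the training data only
and are frozen into the model; zero-variance features are dropped and
recorded. Fold planning keeps all scenes of one video source in one fold
and minimizes the size imbalance by first-fit-decreasing assignment plus
move/swap local search; the original description of that partition step is
ambiguous ("generic algorithm"), so we implement greedy + local search and
verify against exhaustive optima on small cases rather than claim
equivalence to any particular heuristic.

Open design points and how they were fixed:

* **Inner CV**: the penalty for each outer fold is chosen by grouped CV
  over the outer-training groups (9 inner folds when the outer loop has
  10); the nesting depth is stated, the inner fold count was not.
* **Ties** in penalty selection go to the smaller λ — deterministic and
  stability-favoring.
* **Selection criterion**: mean dimension-wise Pearson correlation of
  out-of-fold predictions. Note a consequence: Pearson correlation is
  invariant to prediction shrinkage, so on pure-noise responses the score
  is essentially flat in λ and the selection is arbitrary (and, with the
  smaller-λ tie rule, tends toward small penalties). Shrinkage-based
  intuitions from MSE selection do not transfer; on structured responses
  the criterion behaves as expected (noiseless linear data selects the
  smallest grid penalty).

The encoding direction (`encode_features_with_ablation()`) predicts each
electrode's feature from concatenated semantic/visual/audio blocks and
re-scores out-of-fold predictions with the other blocks' weights zeroed
(intercept retained). The full-model correlation is *not* asserted to
dominate the ablated ones — with correlated blocks that inequality can
fail — only the contract that all-blocks-zeroed predictions reduce to the
intercept.

## 5. Closed loop

`v_online = α·v_inferred + (1−α)·v_online_prev`, with the first frame
taking the black-screen decode directly (no prior state); the feedback
image is the pool argmax of Pearson correlation with ties broken toward
the lowest scene id for deterministic replay. The ~200-ms hardware
presentation delay is not modeled: it shifts timing, not the mathematics
under test. The three evaluation methods — frame-averaged Fisher-z
three-choice, its pairwise restriction, and the projected correlation of
concatenated online vectors against per-trial target vectors — share their
correlation code paths with the off-line metrics.

## 6. The synthetic generator

The generator is the package's study stand-in, and its defaults are the
study conditions: 3600 scenes from six videos at 1 Hz (test scale 360
scenes from 10 sources; both are a config away), 5 annotators per scene,
1000-dim embeddings at paper scale (100 by default, 50 in the fast test
world), 50 imagery trials from 5+5 images, 32 feedback frames per trial.
Electrode features follow
`feature = session_gain × (w_e · x) + N(0, noise_sd)`, truncated at zero
because band powers are nonnegative; `x` concatenates the semantic vector
with optional low-level blocks. Imagery adds
`imagery_gain(imagined category, window) × (w_e · v_imagined)` on
higher-area electrodes by default (configurable), reflecting where
imagery-driven modulation is expected to be strongest; the closed-loop
subject mixes `imagery_gain × v_target + attention_gain × v_feedback`.
Session gains default to (1, 1.3, 0.8) — drift large enough that
uncompensated decoding would degrade, exercising the compensation path.
Noise SD defaults to 0.1 (encoding weights are ~unit-scale); the fast test
world uses 0.05 so that recovery thresholds are met with wide margin at
small n.

What the generator does *not* emulate: heavy-tailed or cross-electrode
correlated noise (independence and Gaussianity are modeling choices, not
inferences about real recordings), waveform-level dynamics (features are
synthesized at the feature level; raw waveforms appear only in the
band-power tests), eye movements, artifacts. Passing tests therefore
demonstrate that the *pipeline* is correct and parameter-recoverable under
its own assumptions — not that real cortical data satisfy those
assumptions.

## 7. Statistics

Permutation nulls recompute the observed statistic through the identical
code path: the clip-shuffle null permutes whole clips of the true-vector
sequence (preserving within-clip autocorrelation), the target-shuffle null
permutes trial targets. p-values use the +1 smoothing rule
`p = (1 + #{null ≥ observed}) / (1 + n_perm)` (two-sided analogue on the
distance from the null mean) so p = 0 is impossible; the default
`n_perm = 1000–10,000` is a desk-scale choice, configurable upward. BH
adjustment is `stats::p.adjust`; Welch's t is `stats::t.test` with
Welch–Satterthwaite df; one-way ANOVA maps use `stats::lm`/`anova` with
partial η² = SSB/(SSB+SSW) and an explicit infinite-F flag for zero
within-group variance.

## 8. Problem sizes

The test suite and acceptance script run at deliberately chosen scales:
the shared test world uses 120 scenes × 15 electrodes × 50 dimensions;
parameter recovery runs at 360 × 20 × 20 with noise at 10% of the signal
SD; chance-level calibrations use ≥ 10,000 simulated trials or draws;
permutation calibration uses 150 null datasets × 199 permutations; the
Welch calibration 2000 simulations. These sizes put Monte-Carlo error
comfortably inside the asserted tolerances while keeping a full run in the
minutes range on one CPU.

## 9. Known limitations

* Embeddings are synthetic cluster constructions; no trained word-embedding
  model or corpus handling is included (the embedding is an input).
* The motion-energy channel inventory is configuration-defined, not a
  reproduction of any specific published filter count.
* Electrode localization is metadata: area labels (`early`, `higher`,
  `other`) are inputs, never computed from imaging.
* The closed loop is simulated; no acquisition hardware, screen timing or
  real-time constraints are modeled.
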