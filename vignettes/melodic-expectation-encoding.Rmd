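---
title: "Modelling melodic-expectation encoding with temporal response functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling melodic-expectation encoding with temporal response functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(melodytrf)
```

## The scientific question

When people listen to melodies, each note is more or less expected given
what came before. Statistical-learning accounts hold that the brain
continuously predicts upcoming notes, and that the *violation* of those
predictions — quantified as the surprise (information content) of the note —
drives measurable cortical responses over and above the response to the
sound's acoustics. This package implements the full analysis chain needed
to test that idea on continuous neural recordings (EEG-like or
intracranial-like), together with a synthetic-data generator that provides
analytic ground truth for every stage.

Four per-note features quantify expectation, separately for the pitch and
the onset-time (inter-onset-interval, IOI) *viewpoints*:

* surprise of pitch $S_p(i) = -\log_2 p(\text{pitch}_i \mid \text{context})$,
* entropy of pitch $H_p(i) = -\sum_e p(e)\log_2 p(e)$ — the uncertainty
  *before* the note is heard,
* and their onset-time counterparts $S_o$, $H_o$.

Surprise is specific to the observed note; entropy characterizes the whole
predictive distribution. Both are in bits.

## The expectation model

Predictions come from a variable-order Markov model in the style of
information-dynamics models of melody. Counts of n-gram continuations are
turned into a full-support predictive distribution by prediction by partial
matching with escape method C (PPM-C): a context of length $k$ that has been
seen $n$ times with $t$ distinct continuations contributes its
maximum-likelihood estimate with weight $n/(n+t)$ and *escapes* with
probability $t/(n+t)$ to the next-shorter context, terminating in the
uniform distribution over the alphabet. This guarantees strictly positive
probabilities, so surprise is always finite.

Two models are combined per viewpoint:

* the **long-term model (LTM)**, pre-trained on a held-out corpus from the
  same source (never on the analysed pieces) — schematic knowledge;
* the **short-term model (STM)**, trained online, note by note, on the
  current piece only, strictly causally (a note is used for training only
  after it has been predicted).

The combination is a weight-normalized geometric mean with entropy-based
weights $w_m = 1/(1 + H_m/\log_2|E|)$: confident (low-entropy) models
dominate. We deliberately did *not* add a second entropy weighting across
context orders — the PPM escape mechanism already blends orders, and adding
a second weighting would double-smooth and break the exact correspondence
with the PPM-C recursion that our oracle tests verify. Unbounded contexts
are capped at 16 notes; beyond that length the escape mass of never-repeated
contexts makes longer matches numerically irrelevant, while training stays
O(notes × order).

Two design points the source literature leaves open, decided here:

* **Onset-time alphabet**: quantized IOI classes (each class has a duration
  in seconds). The first note of a piece has no preceding interval; it
  carries a designated initial class and its $S_o$, $H_o$ are set to 0 and
  excluded from evaluation statistics.
* **Memory-restriction control**: the STM can be rebuilt from scratch in
  chunks of 1–32 musical bars (`memory_restricted_series()`), leaving the
  LTM untouched; `Inf` reproduces the unrestricted analysis exactly. This
  yields expectation features of identical dimensionality but less local
  context — the control used to show that predictive enhancements are not a
  degrees-of-freedom artefact.

## The synthetic-data generator

Everything downstream is validated against simulations with known truth.

* **Melody source** (`markov_spec()`, `random_markov_spec()`): a known
  Markov chain over a pitch alphabet (default 8 chromatic pitches) and an
  IOI alphabet (default 0.3/0.6/1.2 s — eighth, quarter, half notes at
  100 bpm, 4/4, so a bar lasts 2.4 s and all durations are exact MIDI-tick
  multiples). Transition rows are Dirichlet draws whose concentration is
  sampled log-uniformly in [0.05, 5] per row, so some contexts are nearly
  deterministic and others nearly uniform; per-note entropies then span
  their full range, as they do in real music. With a single concentration
  the entropy features are almost constant (sd ≈ 0.15 bits) and their
  response kernels are unidentifiable in any regression.
  `true_expectations()` returns the exact per-note surprise and entropy of
  the generating chain — the oracle for the whole expectation stack.
* **Phrase structure**: with `phrase_repeat_prob > 0`, melodies are built in
  phrases spanning `bars_per_phrase` bars and a new phrase repeats an
  earlier one verbatim with that probability. Repetition is the essence of
  musical long-range structure, and it is exactly what a short-memory
  predictor cannot exploit: this is the constructed effect behind the
  memory-restriction analysis. For such sources no closed-form per-note
  truth exists, so simulated responses are driven by the unbounded-model
  estimates themselves; for plain Markov sources they are driven by the
  analytic truth.
* **Acoustics** (`synthesize_envelope()`): one linear-attack (10 ms),
  exponential-decay (100 ms) kernel per note, summed — piano-like. An
  optional per-note gain models loudness variation.
* **Forward model** (`simulate_neural()`, `default_trf_kernels()`): each
  channel is the sum over features of the feature signal convolved with a
  smooth gamma-shaped kernel, plus $1/f$ noise scaled so the realized
  signal-to-noise variance ratio equals the request exactly. Acoustic
  kernels peak at 50 ms, expectation kernels at 200 ms, mirroring the
  latency separation between envelope tracking and expectation responses.
  Expectation kernels are scaled 4× relative to acoustic ones: expectation
  regressors are sparse impulse trains, and without this scale their
  response contributes only ~3% of the signal variance; at 4× it contributes
  about a third, a regime in which both signal families matter.
* **Cohorts** (`make_cohort()`): subjects share the stimuli and differ by
  noise seed; the default snr of 0.2 puts acoustic-only prediction
  correlations around 0.4, the optimistic end of low-rate EEG envelope
  tracking. Group 2's expectation kernels can be scaled (a musician-like
  effect) or both groups silenced (`expectation_gain = c(0, 0)`) for null
  cohorts.

What the generator does **not** emulate: volume conduction and sensor
covariance, artefacts (blinks, line noise), non-linearities, adaptation,
and any relation between the simulated kernels and real anatomy. Passing
tests therefore show that the *analysis chain* is correct and calibrated,
not that real cortex behaves this way.

## The encoding model

`trf()` fits a linear *temporal response function*: the stimulus features
are expanded into time-lagged copies (`build_lagged_design()`; a stimulus
sample at time $t$ predicts response samples $t + \text{lag}$), and ridge
regression maps them to each channel,
$w = (X^\top X + \Lambda)^{-1} X^\top y$, with columns z-scored and the
intercept unpenalized. Edge samples are zero-padded so trials keep the same
length in every feature set. `trf_crossval()` evaluates by leave-one-trial-out
cross-validation, scoring each held-out trial by Pearson's correlation per
channel; internally both fitting and scoring run on per-trial sufficient
statistics (cross-products), so the cost of a fit does not depend on trial
length once the statistics are accumulated.

**Regularization** is *banded*: acoustic features (`Env`, `Env'`) and
expectation features form separate penalty bands, each with its own
$\lambda$ from a log grid $10^{-3}..10^6$, chosen jointly by an inner
cross-validation over the training trials of each outer fold (never the
held-out trial). Bands other than the first may also receive an infinite
penalty, which excludes the family outright. A single shared $\lambda$
fails in two ways on this design: it over-shrinks the sparse impulse
regressors (even oracle expectation features then add nothing to
prediction), and under the null it leaves a small systematic negative
$\Delta r$ (the overfitting cost of the extra regressors) that a paired test
across subjects mistakes for an effect. With the banded penalty the null
enhancement sits at zero and real expectation signal is retained.

Two lag windows are used, as is conventional: predictions are evaluated on
[0, 350] ms (longer latencies add little and increase dimensionality);
weight inspection and lag-relevance analyses use [−150, 750] ms.

**Feature sets.** `assemble_features()` builds the descriptors: `A` (envelope
and its half-wave-rectified derivative), `AM` (plus the four expectation
impulse trains), `AM_shu` (expectation values shuffled in time with onsets
intact — same dimensionality and value distribution, no information), and
the pitch-only / onset-only variants `AM_p`, `AM_o`. Columns are assembled
raw; all scaling happens inside the fit with training-fold statistics, so no
test-fold information leaks.

**The headline statistic** is the predictive enhancement
$\Delta r = r_{AM} - r_A$, channel-averaged per subject, tested by a paired
sign-flip permutation test. The test is one-tailed: the hypothesis is
directional (informative features can only help a correctly regularized
model), and because the cross-validated score of the larger nested model
carries a small negative bias under the null, the one-tailed test is
conservative there. The two-tailed variant remains available
(`compare_feature_sets(tails = "two")`).

**Identifiability caveat.** In the music design all four expectation trains
share one onset support, and the envelope is itself onset-locked; the
onset-mean component of the expectation response is therefore nearly
collinear with the acoustic regressors, and per-feature kernel recovery
from music-driven recordings is limited *by construction*. This is exactly
why the analysis rests on $\Delta r$ rather than on reading individual
kernels. The package's kernel-recovery validation accordingly uses six
mutually independent synthetic features (two smooth signals, four
amplitude-jittered impulse trains), where cross-validated ridge recovers
every kernel with correlation above 0.95 at snr 1.

## Lag relevance and component contrasts

`backward_eliminate_lags()` quantifies which 50 ms blocks of lags carry
non-redundant response energy: the model is refit with one block excluded
at a time (first elimination pass only) and the loss
$r_{\text{LOSS}} = r_{\text{full}} - r_{\text{without block}}$ is tested by
a sign-flip permutation over held-out trials, Bonferroni-corrected across
blocks and channels. The test is one-sided — relevance means *positive*
loss; under the null, excluding useless lags slightly *improves*
prediction, and a two-tailed test would flag that uninteresting direction.

Two calibration details matter. First, the full and reduced models are fit
once on a dedicated training subset (a third of the trials by default) and
the losses evaluated on the remaining trials: with one shared fit the
evaluation losses are independent and symmetric under the null and the
sign-flip test is exact. Evaluating by leave-one-out instead couples the
folds through their overlapping training sets and inflates the family-wise
false-positive rate several-fold (the classic anticonservativeness of
cross-validation tests; we measured ~0.13 at a nominal 0.05 with 10 trials).
Second, sign-flip tests have a hard p-value floor of
$2^{-n_\text{eval}}$, so Bonferroni significance across the 18 blocks of
the default window needs at least 10 evaluation trials; when the exhaustive
enumeration is no larger than about twice the requested permutation budget
it is used and the p-value is exact.

`trf_component_contrasts()` forms the surprise-vs-entropy and
pitch-vs-onset weight contrasts ($\frac{S_p+S_o}{2} - \frac{H_p+H_o}{2}$
and $\frac{S_p+H_p}{2} - \frac{S_o+H_o}{2}$), with sign-flip group tests
and FDR correction across lags and channels when per-subject models are
supplied.

## Note-locked ERP analysis

`epoch_notes()` cuts note-locked epochs; `select_envelope_matched()` keeps
only notes whose peak envelope (maximum within 150 ms of onset — the attack
of the piano-like kernel) lies within ±5% of the median. This is the key
acoustic confound control: any subsequent contrast between the top and
bottom 20% of pitch surprise (`split_by_feature()`) is computed on notes of
near-identical loudness. `erp_contrast()` then compares total ERP power in
0–200 ms by epoch-label permutation and tests every latency with FDR
correction. Pre-stimulus deflections from short inter-note intervals are
retained by default (epochs carry the preceding-IOI metadata for optional
filtering); no baseline correction is applied unless requested — both
choices mirror the standard treatment of naturalistic music, where note
responses overlap.

The ERP validation fixture simulates a single strongly music-responsive
channel (snr 3, high-gamma-like), 2500 notes with log-normal gain jitter
(sd 0.15), and all-positive response kernels with the surprise kernel
peaking at 150 ms. All-positive matters: with mixed-sign kernels a positive
surprise component can *destructively* interfere with an opposite-signed
acoustic response and lower total power — a real interpretive hazard of
ERP power contrasts that the temporal response function analysis does not
share. The fixture sizes come from a power analysis targeting ~95%
detection at the 0.05 level; the null (surprise kernel silenced) rejects at
the nominal rate.

## Statistics

`permutation_test()` (sign-flip when paired, exhaustive and exact when
$2^n$ fits in the budget, add-one convention otherwise so p is never 0),
`fdr_bh()` (Benjamini–Hochberg step-up), `cohens_d()` (pooled-SD unpaired,
difference-SD paired), `spearman_test()` (tie-corrected, permutation p),
and `rm_anova()` (one-way repeated measures through the multivariate
linear-model machinery, with Mauchly's sphericity test and
Greenhouse–Geisser correction of the degrees of freedom when sphericity is
rejected at 0.05; when there are too few subjects for Mauchly's test the
uncorrected F is reported).

`diss()` computes topographic dissimilarity exactly as
$\mathrm{DISS} = 2(1-r)$ between two channel maps (identical maps 0,
uncorrelated 2, anti-correlated 4); the conventional $\sqrt{2(1-r)}$ form
is available via `sqrt_form = TRUE`. The randomization exchanges the two
maps' values channel by channel (the null of no topographic difference),
with a one-sided p for larger dissimilarity. Note that this null preserves
any *globally* sign-symmetric structure — it asks whether the difference
between maps exceeds what per-channel exchangeability allows, which is the
interpretation we adopt since the original randomization is not described
in detail.

## End-to-end runs and problem sizes

`run_full()` orchestrates simulate → expectations → features → TRF →
comparison → ERP and writes tidy CSVs, a JSON summary and a provenance
manifest; identical configurations produce byte-identical outputs.
`run_memory_sweep()` and `run_piece_trend()` implement the two higher-level
analyses:

* the memory sweep refits the AM model with expectation features rebuilt at
  memory 1, 2, 4, 8, 16, 32 bars and unbounded, reusing each outer fold's
  banded penalties from the unbounded variant (all variants have identical
  dimensionality, so the regularization is comparable and the sweep costs
  one nested selection instead of seven); the trend is summarized by
  per-subject Spearman correlations with a sign-flip group test plus a
  repeated-measures ANOVA across levels. One caveat the simulations expose:
  a source *without* long-range structure does not give an exactly flat
  sweep. The short-term model keeps learning the current piece's realized
  statistics whatever the source, so restricting its memory always costs a
  little feature quality — a graded drift of ~0.001–0.002 in $\Delta r$,
  about a thirtieth of the phrase-structured effect, but reaching
  significance in roughly a third of stimulus draws because subjects share
  stimuli. A rising memory sweep is therefore strong evidence of long-range
  structure only when its magnitude clearly exceeds this warm-up floor;
* the piece trend grades *onset predictability* across pieces while holding
  the stationary IOI distribution fixed (transition rows are
  $(1-\varepsilon)\,\text{cyclic shift} + \varepsilon\,\text{uniform}$), so
  note density — and with it acoustic signal variance — is identical across
  pieces and only predictability varies. Under a common noise floor, pieces
  with higher mean onset surprise inject more response variance, and their
  single-trial prediction correlations rank accordingly.

Simulation sizes in the shipped validation suite are desk-scale choices:
cohorts of 20 subjects with 6 trials of ~60 s (roughly a tenth of a full
experimental session per subject), sweeps with 8 subjects, ERP fixtures
with 2500 notes. They were chosen once, with simple power analyses where a
detection probability mattered, and are stated here as the package's demo
conditions; nothing in the code depends on them.

## A short worked example

```{r example, eval = FALSE}
library(melodytrf)

spec <- random_markov_spec(seed = 1)
ltm <- train_ltm(spec, n_pieces = 8, notes_per_piece = 400, seed = 1)
cfg <- default_config(n_subjects = 6, n_pieces = 6, notes_per_piece = 120)
cohort <- make_cohort(spec, n_subjects = 6, n_pieces = 6,
                      notes_per_piece = 120, base_seed = 1)
res <- cohort_feature_comparison(cohort, ltm, cfg)
print(res$comparison)

mel <- cohort$stimuli[[1]]$melody
plot(trf(assemble_features("AM", cohort$stimuli[[1]]$envelope,
                           res$series[[1]], cohort$fs),
         cohort$subjects[[1]][[1]], lag_window_ms = c(-150, 750),
         lambda = 100))
```

## Known limitations

* The PPM escape scheme and the LTM/STM combination rule are documented
  stand-ins for the original model family's defaults; absolute surprise
  values will differ from other implementations even when orderings agree.
* Channel repair uses neighbour means, not spherical splines; downstream
  statistics do not depend on the interpolation method.
* The generator produces monophonic, metrically rigid melodies; no timbre,
  harmony, loudness or performance timing.
* Kernel-level interpretation of music-driven fits is limited by the
  onset-support collinearity discussed above.
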