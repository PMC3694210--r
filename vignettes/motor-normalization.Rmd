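---
title: "Motor-based speaker normalization: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-based speaker normalization: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`artimap` studies one question: when a listener classifies phones produced
by other speakers, does it help to first map their acoustics into the
listener's *motor* space rather than her acoustic space? The package
implements the full chain — corpus, features, deep networks, normalization
strategies, evaluation — so that the question can be answered by running
an experiment, not by argument.

The chain has five stages.

1. **Corpus.** Multi-speaker paired audio + articulograph recordings:
   each utterance is one word token with a waveform, 7-coil sagittal
   trajectories at 200 Hz (tongue tip/blade/dorsum, lips, teeth; x,y), and
   a phone segmentation. Since no such corpus can be shipped, a generator
   produces synthetic ones with the statistical structure the method
   assumes (below).
2. **Features.** Per phone, 10 analysis windows (25 ms Hamming) uniformly
   distributed over the phone — the *dynamic shift* — so short and long
   phones get the same balanced 10-frame description. Acoustics: 20
   triangular HTK-mel filterbank log energies per frame plus first and
   second time derivatives computed across the 10 frames with the actual
   inter-frame shift (10 × 60). Articulation: coil trajectories smoothed
   by a 15 ms moving average, differentiated at 200 Hz, each of the 42
   streams averaged in the same windows (10 × 42).
3. **Deep networks.** Every mapping and classifier is a 4-layer net: three
   logistic hidden layers pretrained as a stack of RBMs
   (Gaussian-visible/logistic at the bottom, logistic/logistic above,
   CD-1), then unrolled and fine-tuned by mini-batch back-propagation with
   momentum. Mappings end in linear regressors; the phone classifier in a
   softmax.
4. **Normalization strategies.** `NoNorm` (acoustics only);
   `MotorNorm` (acoustics + articulatory features reconstructed by the
   acoustic-to-articulatory mapping, trained on listener-audio →
   listener-AF pairs plus speaker-audio → listener-AF pairs aligned by the
   acoustic bootstrap: same phoneme, same word type, matched repetition,
   frame *i* ↔ frame *i*); and three acoustic counterparts
   (`AcouNorm_A/B/C`) that map into the listener's acoustic space — A
   reconstruction-only, B paired with the actual acoustics, C as B on a
   reduced acoustic set chosen to carry about as much discriminative
   information as the articulatory features.
5. **Evaluation.** Error rates per scenario (strategy × setting ×
   subject combination), exact two-sided McNemar tests on paired
   predictions (binomial, clamped at 1 — test sets are small at this
   scale), relative error reductions, and four Pearson diagnostics
   (intra-subject coherence; listener-speaker motor similarity;
   reconstruction correlation toward listener and toward speaker),
   averaged dimension → speaker.

## What the generator emulates — and what it does not

All subjects share one articulatory latent: a fixed target vector of 14
coil coordinates per phone, joined by 30 ms cosine ramps, with
per-repetition Gaussian target noise whose standard deviation is the
subject's *coherence* (default 0.02 target units — nearly coherent
subjects). Each subject renders the latent through her own vocal tract
model: three resonances whose frequencies are a sigmoidally warped affine
function of the coil state, scaled by a vocal-tract-length factor
(±8% across the default panel), excited by an impulse train at a
subject-specific f0 (180–240 Hz); the per-subject affine maps are a common
base perturbed by 20% relative noise, emulating a homogeneous same-sex,
same-dialect panel. The default conditions — 5 subjects, 12 word types of
3–5 phones over a 12-phone inventory, 3 repetitions, mean phone duration
0.12 s with 10% jitter, 16 kHz audio — keep a full experiment in minutes
on one CPU.

What this does **not** emulate: real coarticulation (targets only
interpolate at boundaries), consonant manner cues absent from EMA (the
generator's acoustics are fully determined by the coil state, unlike real
speech), noise and channel effects, prosody. Consequently the synthetic
phone-classification task is acoustically easier than a real 43-phone
task: baseline errors are a few percent within-speaker and ~15%
cross-speaker, versus ~21%/~27% on real corpora of this design. Passing
tests on this corpus demonstrates that the machinery behaves as specified
and that the method's qualitative orderings can be probed — not that its
quantitative gains transfer to real speech.

## Numerical choices

* **Initialization.** RBM weights are drawn at a Glorot-type scale for
  logistic units, `sd = 4 * sqrt(2 / (fan_in + fan_out))`; the small
  (`sd = 0.01`) init conventional in early deep-belief work collapses the
  signal through three logistic layers at these data sizes, stalling
  fine-tuning entirely.
* **Learning rates.** Pretraining 0.001 (Gaussian-visible) / 0.01
  (binary); fine-tuning 0.1 with per-epoch decay 0.98 and momentum 0.9.
  The decayed higher rate is what makes the nets converge at desk scale;
  a flat 0.01 plateaus far above the achievable loss.
* **Regularization.** A classical L2 weight cost (1e-4) during
  fine-tuning; no early stopping (epoch counts are fixed per experiment),
  no modern regularizers.
* **Standardization.** Inputs (and regression outputs) are z-scored;
  a zero-variance dimension is an error by design — it indicates a
  degenerate corpus, not something to mask. The one exception is the
  reduced-feature search, whose per-token articulatory vectors contain
  structurally constant columns (interior-frame velocities of flat
  trajectories); it screens training-constant columns before fitting.
* **Degenerate phones.** Phones shorter than one 25 ms window collapse all
  10 centers onto the midpoint with shift 0 (derivatives zero); windows
  extend into the utterance context by symmetric reflection (audio) or
  sample replication (trajectories), preserving the fixed 10 × 60 shape.
* **Ties.** The classifier's argmax breaks ties toward the lowest phone
  index.
* **Alignment.** Cross-speaker repetitions are paired by sorted repetition
  rank up to the smaller count; unmatched tokens are dropped and counted.
  Frame *i* of one subject's 10-frame block aligns with frame *i* of the
  other's — the natural consequence of the dynamic-shift design.
* **MotorNorm listener rows.** The classifier's listener rows use
  *reconstructed* articulatory features by default (matching the test-time
  distribution); the `listener_af = "actual"` switch provides the variant
  that uses the listener's measured features.

## Problem sizes used by tests and the acceptance script

Unit tests run on 2–3-subject corpora with 4 word types. The experiment
checks use the default 5-subject corpus, one listener, two S1 choices
(and matching S2 for cross-speaker cells), mapping nets with the standard
180-unit hidden layers (8 pretrain / 40 fine-tune epochs) and classifiers
with 120-unit hidden layers — a deliberate reduction of the full-scale
1500-unit configuration that keeps every run within minutes while
preserving the architecture. All seeds are explicit arguments.

## A known limitation: the cross-speaker setting at small scale

Within-speaker (T1), motor normalization consistently reduces the error on
the synthetic corpus. Cross-speaker (T2), it does not: the mapping trained
on the listener plus one speaker reconstructs the listener's articulation
at r ≈ 0.93 for the speaker it saw, but only r ≈ 0.7–0.8 for unseen
speakers, and a classifier trained on clean in-sample reconstructions
over-trusts the 420 articulatory dimensions, so the distribution shift at
test time costs more than the normalization saves. This is the same
mechanism by which a poorly reconstructed listener loses the motor
advantage (the degraded-listener experiment, `corrupt_coherence()`), and
it sharpens the method's stated precondition: motor normalization helps
exactly when the articulatory reconstruction is accurate enough. At this
corpus size (12 word types, ~700 tokens, 2 speakers feeding the mapping)
the unseen-speaker reconstruction does not reach that threshold; larger
corpora with more mapped speakers are the regime where the cross-speaker
benefit is claimed.

A converse limitation concerns the degraded-listener experiment
(`corrupt_coherence()`): because the generator's waveform is a
deterministic function of the articulatory latent, the
acoustic-to-articulatory regression *denoises* additive coil-measurement
noise in its training targets (its conditional mean is the clean latent),
so corrupting the listener's coils lowers her measured coherence
correlation as expected but leaves the reconstructed features — and hence
the motor advantage in her within-speaker cells — intact at any corruption
strength. Reproducing the harm that poor articulatory recordings cause in
real data would require a world where acoustics underdetermine
articulation, which is the opposite of the invertibility the
mapping-recovery experiment demands of the same generator. One generator
cannot satisfy both regimes; this one favours invertibility.

## Open choices made here

* Derivatives across the 10 dynamic frames use time-normalized finite
  differences (centered inside, two-point at the edges, divided by the
  actual shift) — the minimal faithful reading of "adjusted for the
  dynamic shift".
* Whether analysis windows may cross phone boundaries: they may (with the
  edge paddings above); truncating would break the fixed block shape.
* The 1/3–2/3 speaker splits are stratified by word type so that every
  word type appears on both sides; split seeds are independent of the
  corpus seed.
* Phone-duration statistics are not available for the emulated corpus
  design; 0.12 s ± 10% was fixed once as a typical spoken-Italian phone
  duration scale.
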