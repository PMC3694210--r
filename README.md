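# artimap

Motor-based speaker normalization for phone classification.

## The problem

A phone classifier trained on several speakers' acoustics learns fragmented
models, because the same phoneme sounds different from different vocal
tracts. One family of remedies maps every speaker's acoustics into the
space of a single *reference listener*. `artimap` implements and compares
two variants of that idea:

* **Motor normalization** — learn an acoustic-to-articulatory mapping (AAM)
  from any speaker's acoustics to the *listener's own articulatory
  features* (electromagnetic-articulography coil positions, velocities and
  accelerations), and give the classifier the reconstructed articulation
  alongside the acoustics. Only the listener's articulatory data is ever
  used; other speakers contribute acoustics alone, paired with the
  listener's realization of the same phoneme in the same word type (the
  "acoustic bootstrap").
* **Acoustic normalization** — the exact acoustic counterpart: map the
  speaker's acoustics into the *listener's acoustic* space (full or reduced
  feature set) with the same network machinery.

Both are evaluated against a no-normalization baseline in a phone
classification task, within-speaker (T1: train on the listener plus 1/3 or
2/3 of a speaker S1, test on the rest of S1) and cross-speaker (T2: same
training, test on an unseen speaker S2).

## The machinery

* Phone-synchronous features: each segmented phone yields 10 analysis
  frames uniformly spread over its duration ("dynamic shift"), each frame
  giving 20 log mel-filterbank energies (MFSCs) + Δ + ΔΔ (10 × 60), and,
  where coil data exist, 14 smoothed coil coordinates + velocities +
  accelerations (10 × 42) on the same windows.
* All mappings and classifiers are 4-layer deep networks: a 3-layer
  restricted-Boltzmann-machine stack pretrained by contrastive divergence,
  unrolled and fine-tuned by back-propagation (linear output for mappings,
  softmax over the phone inventory for classifiers). The AAM takes 3
  consecutive acoustic frames (180 inputs) and predicts the center frame's
  42 articulatory features.
* Evaluation: per-scenario error rates, exact two-sided McNemar tests on
  paired predictions, relative error reductions, and four Pearson
  correlation diagnostics of the articulatory reconstruction
  (subject coherence; listener-speaker motor similarity; reconstruction
  accuracy toward the listener and toward the speaker).

Because paired audio + articulography corpora cannot be redistributed, the
package ships a synthetic corpus generator: all subjects share one
articulatory latent (per-phone coil targets, cosine-ramp transitions), and
each subject renders it through her own source-filter map (sigmoidal
articulation-to-resonance map, vocal-tract-length scaling, subject f0).
A coherence knob degrades one subject's articulatory recordings to study
the effect of poor reconstruction.

## A worked example

```r
library(artimap)

inventory  <- default_inventory(12)            # 12 phones, fixed targets
subjects   <- default_subjects(5)              # 5-speaker panel
word_types <- default_word_types(inventory, 12)
corpus  <- generate_corpus(inventory, subjects, word_types,
                           repetitions = 3, seed = 101)
tokens  <- tokenize(corpus)                    # 705 phone tokens

res <- run_scenario(tokens, "MotorNorm", "T1_2Tr",
                    listener = "s01", s1 = "s02", split_seed = 3,
                    mapping_config    = train_config(pretrain_epochs = 8,
                                                     finetune_epochs = 40,
                                                     seed = 103),
                    classifier_config = train_config(pretrain_epochs = 8,
                                                     finetune_epochs = 40,
                                                     seed = 203))
res
#> <scenario> MotorNorm T1_2Tr L=s01 S1=s02: error 0.000 (235 train / 47 test)
```

The scenario trains the AAM on listener + S1 pairs, reconstructs
articulatory features for every token from acoustics alone, trains the
phone classifier on 600 acoustic + 420 reconstructed features, and scores
the held-out S1 tokens: zero errors on the 47 test tokens here, versus
6.4% (3 of 47) for the same cell under `"NoNorm"` — within-speaker, the
reconstructed motor information removes the residual confusions. Comparisons are made significant (or not) with
`mcnemar_exact()` on the paired predictions, and
`four_correlations()` reports how faithfully the reconstruction tracks the
listener's versus the speaker's actual articulation.

## Command line

A thin front end wraps the exported functions:

```sh
Rscript inst/cli/artimap.R generate       --config cfg.yaml --out corpus/
Rscript inst/cli/artimap.R extract        --corpus corpus/ --out features/
Rscript inst/cli/artimap.R run-experiment --config cfg.yaml --out results/
```

See `vignettes/motor-normalization.Rmd` for the model, its assumptions,
and the numerical choices.
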