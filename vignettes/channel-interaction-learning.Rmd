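---
title: "Channel interaction and learning in simulated cochlear-implant hearing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel interaction and learning in simulated cochlear-implant hearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Cochlear implants (CIs) replace the transduction performed by the inner ear
with 12–22 electrodes, each responsible for one frequency band. Two
properties limit the spectral resolution of the delivered signal: the small
number of channels, and *channel interaction* — the electrical fields of
neighboring electrodes overlap, so populations of neurons receive summed
input from adjacent frequency bands. `cisim` is a desk-scale simulation of
how this degradation interacts with *learning history*: a postlingually deaf
(PD) CI user adapted to high-resolution hearing before implantation, whereas
a congenitally deaf (CD) user learns from degraded input from the start. The
package's central reproducible result is that, in neural-network analogs of
these two regimes, channel interaction slows *early* learning only in the
pre-trained (PD) networks.

## The model pipeline

**Featurization.** Utterances are mel-scaled amplitude spectrograms:
50 ms Hann windows strided by 10 ms, triangular filters with centers equally
spaced on the (HTK-variant) mel scale between 200 and 7,000 Hz — roughly the
range delivered by most implants. Three resolutions are produced from each
waveform:

* **high**: 32 channels (an intact-cochlea stand-in),
* **med**: 16 channels (an idealized implant with no channel interaction),
* **low**: 16 channels followed by the channel-interaction operator.

Channel interaction is a simultaneous neighbor summation on the 16-row
matrix `x`: row 1 becomes `x[1,] + x[2,]`, row N becomes `x[N,] + x[N-1,]`,
and every inner row n becomes `x[n-1,] + x[n,] + x[n+1,]` — equivalently,
left-multiplication by the tridiagonal ones matrix. No renormalization is
applied after the summation, and the operator is applied *before* row
duplication. Rows of the med- and low-res spectrograms are then duplicated
pairwise so that every condition presents a 32 × T matrix and one network
can ingest all three. Values are raw linear amplitudes; log compression is
available (`feat_config(log_amplitude = TRUE)`) but off by default.

**Models.** Two classifiers, implemented from first principles in matrix
code. The perceptron is a single softmax layer over the flattened
spectrogram (`p(Y=i|x) = exp(W_i·x + b_i) / Σ_j exp(W_j·x + b_j)`,
max-stabilized). The CNN has three identical convolutional layers (5 filters
of 5 × 5, stride 2 × 2, valid padding), batch normalization before each
activation, ReLU, dropout 0.1 after each convolutional layer and 0.5 after
the 100-unit dense layer, and a softmax readout. Both are trained by
mini-batch (32) gradient descent on the categorical cross-entropy with
Adadelta step-size adaptation (learning-rate multipliers 0.01 for the
perceptron and 0.1 for the CNN; ρ = 0.95, ε = 1e−6, the original
publication's settings), and early stopping with patience 10. The CNN's
backward pass is verified against numerical gradients in the test suite.

**Initialization and the meaning of "chance before training".** Hidden
layers (convolutional and dense) are Glorot-uniform; every softmax readout
— the whole perceptron, and the CNN's output layer — starts at zero, the
standard starting point for (convex) softmax regression. An untrained model
therefore outputs *exactly* uniform class probabilities, and its argmax
ties are broken by a uniform draw seeded deterministically from the model
seed and the input data. This makes "accuracy is at chance level before
training" true by construction and reproducible: repeated evaluations of
the same model on the same data return identical label vectors, while
different seeds (or different featurizations) draw independent guesses. A
randomly initialized nonzero readout would instead produce item-correlated
guesses whose accuracy on an imbalanced task can sit far from 1/K — on
strongly separable synthetic data a random hyperplane picks up real class
structure — which is a property of random projections, not of learning.

**Regimes.** CD: train from the initialization above on one
featurization. PD: train on high-res first, then continue on med- or
low-res. Test accuracy and per-item predictions are recorded *before* any
update on the target featurization (epoch 0), after the first epoch, and at
the best validation epoch — the three timepoints of the transfer analysis.

**Statistics.** Paired accuracy differences are tested with an approximate
randomization test: each item's prediction pair is swapped with probability
½, the difference recomputed R times (default 1e5), and
`p = (r + 1) / (R + 1)` where `r` counts replicates meeting or exceeding the
observed difference. A full-enumeration version (`exact_art`, feasible to
n = 20) serves as the oracle in tests. The Bonferroni family is
pre-registered at 18 comparisons per corpus: 4 from Analysis I (high-vs-low
for each architecture, architecture-vs-architecture at both resolutions), 2
from Analysis II (med-vs-low per architecture), and 12 from Analysis III
(med-vs-low × three timepoints × two architectures × two initializations).

## The synthetic corpora

Real speech corpora for these tasks are licensed or large external
downloads, so the package generates its own audio with exactly the cue
structure the hypothesis concerns. Each utterance is a harmonic series at a
speaker's fundamental frequency (f0), shaped by Gaussian resonance gains
following 3 formant tracks scaled by a vocal-tract-length factor, multiplied
by a piecewise-linear amplitude envelope, at 16 kHz.

* **Gender task** (binary, 70/30 imbalance, 1–3 s utterances): classes
  differ in f0 — truncated Normal(120, 15) Hz vs. Normal(210, 20) Hz,
  typical adult ranges — and in formant scaling (1.00 vs. 1.18), while
  envelope levels overlap heavily. The class signal therefore lives in
  fine-grained spectral detail, which is what channel interaction destroys;
  a fixed nearest-centroid oracle in the test suite verifies that collapsing
  32 channels to the interaction featurization reduces accuracy on most
  seeds.
* **Word task** (30 classes by default, fixed 1 s): each class has a
  distinct procedurally generated formant-trajectory and envelope prototype;
  speakers come from a mixed low/high-f0 pool so speaker identity is
  uninformative.

Splits are 60/20/20 train/validation/test, drawn per utterance uniformly at
random (speaker-disjoint splitting is *not* modeled). What the generator
does **not** emulate: phonetic structure, prosody, noise, reverberation,
coarticulation, or realistic within-speaker variability. Passing tests
therefore show that the pipeline's machinery produces the expected learning
dynamics when the fine/coarse cue structure is as assumed — not that the
same effect sizes would be observed on real speech.

## Numerical and design choices

* **Fixed-length inputs.** Models need a fixed T. One-second word
  utterances give T = 96 exactly; variable-duration gender utterances are
  zero-padded/truncated to the 95th percentile of observed frame counts.
* **Input normalization.** Model inputs are z-scored per feature cell using
  train-split statistics (`featurize_corpus(normalize = TRUE)`). The
  spectrograms themselves remain raw non-negative amplitudes; this is purely
  input conditioning. It matters for two reasons: raw amplitude features are
  all-positive and strongly correlated, so an untrained linear model's
  decisions collapse toward a single class (epoch-0 accuracy then reflects
  the class imbalance rather than chance), and unconditioned inputs slow
  Adadelta convergence markedly.
* **Early stopping monitors validation cross-entropy** (not error rate);
  `monitor = "accuracy"` is available. The epoch ceiling is 200 by default;
  the packaged experiments use 150, which the observed runs never hit
  (typical convergence is 20–80 epochs).
* **FFT details.** FFT length is the next power of two at or above the
  window (1024 for 800 samples); periodic Hann window; magnitude (not
  power) spectra.
* **Batch-norm statistics are frozen for every evaluation**, including the
  epoch-0 one (running mean 0, variance 1 at initialization).
* **Transfer runs re-initialize the Adadelta accumulators** at the start of
  the transfer phase; only the weights carry over.
* **Randomization-test sidedness.** The observed difference is reported
  signed, but the default test is two-sided via absolute differences, since
  the analyses test differences in both directions; one-sided is an option.
* **Ties in `d' >= d`** are counted as exceedances (with a 1e−12 float
  guard), which is the conservative direction.

## Desk-scale problem sizes

The packaged defaults are sized for a single CPU: 2,000 gender utterances,
1,500 word utterances, perceptron-only experiment sweeps over five seeds
(`default_run_config()`). The CNN is fully implemented and tested (gradient
check, toy-problem learning) and can be enabled via
`experiment$arches = c("per", "cnn")`, but a full CNN sweep is much slower
than the perceptron one. The headline property — the PD epoch-0 med-vs-low
gap, its shrinkage over transfer training, and the absence of a consistent
CD-regime gap — is asserted over five seeds on the 2,000-utterance gender
corpus in `tests/testthat/test-acceptance.R` and recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* The acoustic generator is a cue-bearing caricature of speech; effect
  *sizes* on real corpora will differ, and the word task here is easier
  than real command-word recognition.
* Channel interaction is modeled as a fixed 0/1 tridiagonal summation;
  real current spread decays continuously with distance and varies per
  patient. Pulse-train/electrical stimulation modeling is out of scope.
* The med-res condition duplicates rows for shape compatibility; this is an
  analog of broad electrode coverage, not a claim about neural maps.
* With five seeds, the paired sign test used for the CD null has low power;
  the CD result is "no consistent direction", not a demonstrated zero.
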