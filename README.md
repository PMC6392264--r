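# cisim

Simulating speech processing with cochlear implants: how does channel
interaction affect learning in neural networks?

Cochlear implants (CIs) deliver sound through 12–22 electrodes, and the
electrical fields of neighboring electrodes overlap — *channel
interaction* — blurring adjacent frequency channels and reducing the
spectral resolution of the delivered signal. `cisim` is a desk-scale,
fully self-contained simulation pipeline for studying how that degradation
interacts with *learning history*: a postlingually deaf (PD) CI user
adapted to high-resolution hearing before implantation, while a
congenitally deaf (CD) user learns from degraded input from the start.

The pipeline:

1. **Synthetic speech** with controllable fine-grained cues (f0 harmonics,
   formants, vocal-tract scaling) and coarse-grained cues (amplitude
   envelope): a binary speaker-attribute task (70/30 imbalance, 1–3 s
   utterances) and a 30-class word task (1 s utterances).
2. **Featurization** as mel amplitude spectrograms (50 ms / 10 ms,
   200–7,000 Hz) at three resolutions: **high** (32 channels, intact
   cochlea), **med** (16 channels, idealized CI), and **low** (16 channels
   with channel interaction). Interaction is the neighbor summation

   `x'[n,] = x[n-1,] + x[n,] + x[n+1,]`   (edge rows sum two rows),

   i.e. left-multiplication by the tridiagonal ones matrix; med/low rows
   are duplicated pairwise so every condition is a 32 × T matrix.
3. **Models**: a softmax perceptron
   `p(Y=i|x) = exp(W_i·x + b_i) / Σ_j exp(W_j·x + b_j)` and a small CNN
   (3 conv layers, 5 filters 5×5, stride 2×2, batch norm, ReLU, dropout
   0.1/0.5, 100-unit dense layer), trained from scratch with Adadelta,
   mini-batches of 32, categorical cross-entropy, and early stopping
   (patience 10). Both epoch-0 (pre-update) and epoch-1 test predictions
   are recorded for the transfer analyses.
4. **Regimes**: CD = train from scratch on one featurization;
   PD = pre-train on high-res, then transfer to med- or low-res.
5. **Statistics**: approximate randomization test for paired classifier
   predictions (`p = (r+1)/(R+1)`, R = 1e5), an exact-enumeration oracle
   for small n, and Bonferroni correction over the pre-registered family of
   18 comparisons per corpus.

The reproducible headline result: channel interaction slows *early*
learning only in pre-trained networks — the PD epoch-0 accuracy on med-res
input exceeds low-res in every seed, the gap shrinks as transfer training
proceeds, and models trained from scratch (CD) show no consistent epoch-0
difference.

## Worked example

```r
library(cisim)

# a small corpus: 300 utterances, 70% class 0 (low f0), 30% class 1 (high f0)
corpus <- make_gender_corpus(300, seed = 1)
corpus
#> <ci_corpus> 300 utterances, 2 classes, 16000 Hz
#>   splits: test=60 train=180 val=60

# an experiment context over one or more corpora
lab <- ci_lab(list(gender = corpus), experiment_config(max_epochs = 60))

# congenitally-deaf analog: train from scratch on low-res (CI-like) input
cd <- run_regime(lab, "gender", "per", "low", "CD", seed = 0)
cd
#> <ci_run> gender/per low-res CD seed 0: acc 0.450 -> 0.900 -> 0.917 (60 epochs)

# postlingually-deaf analog: pre-trained on high-res, transferred to low-res
pd <- run_regime(lab, "gender", "per", "low", "PD", seed = 0)
pd
#> <ci_run> gender/per low-res PD seed 0: acc 0.917 -> 0.917 -> 0.900 (43 epochs)
```

The three accuracies are test accuracy before any update on the target
featurization (epoch 0), after one epoch, and at the best validation epoch.
The untrained CD model guesses at chance (0.450); the PD run starts at
0.917 with *zero* updates on low-res data: parameters learned on
high-resolution input generalize to the degraded featurization. The paired
randomization test confirms the epoch-0 difference between the two regimes:

```r
art <- art_test(pd$gold, pd$predictions_epoch0, cd$predictions_epoch0,
                R = 1e5, seed = 0)
art
#> ART: d = +0.4667, p = 1e-05 (r = 0 of R = 100000, two-sided)
star_code(art$p, family_size = 18)
#> "***"
```

At this 300-utterance scale the med-vs-low epoch-0 contrast is inside the
noise of a 60-item test split; the packaged experiment (2,000 utterances,
five seeds — see below) resolves it: pre-trained accuracy is higher on
med-res than low-res input in every seed (gap ≈ 5 points, ART p ≈ 1e-4),
and the gap shrinks to under one point by the final epoch.

The full three-analysis sweep (both tasks, five seeds, tidy CSVs, Markdown
tables, figures):

```r
run_all(load_config("my_config.yaml"))   # or run_all(default_run_config())
```

A thin command-line wrapper with `synth`, `featurize`, `art`, and `run`
subcommands is installed at `inst/cli/cisim.R`.

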