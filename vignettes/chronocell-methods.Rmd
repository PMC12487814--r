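---
title: "chronocell: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronocell: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chronocell models single-cell time-series profiles collected across
conditions and data modalities. Because sequencing destroys the cell,
no cell is ever observed twice: the package's job is to impute what a
cell's profile *would* look like at another time point, under another
condition (for example the opposite sex), or in another modality
(chromatin accessibility from gene expression). This vignette explains
the model, the choices behind its defaults, what the synthetic-data
generator does and does not emulate, and the package's known limits.

## The conditional VAE

Each modality gets a conditional variational autoencoder that
decomposes an observed profile into four factors:

* a **cell-identity embedding** `z` (default dimension L = 50), the
  only cell-specific latent variable, encouraged to be invariant of
  the other three;
* a **time factor**: a continuous sinusoidal encoding of the
  collection day;
* a **condition factor** (e.g. sex): one-hot;
* a **batch factor**: one-hot.

The encoder maps the depth-normalized `log1p` profile, concatenated
with the time encoding and the condition and batch indicators, through
two ReLU hidden layers to the posterior mean and log-variance of `z`.
A *temporal interaction layer* combines `[z, time encoding,
condition]` into an L-dimensional time-aware embedding, and the
decoder maps `[time-aware embedding, batch]` back to data space.
Hidden widths are the rounded geometric mean of the data dimension and
L; the interaction layer uses a single hidden layer (the two-hidden-
layer depth is spent in the encoder and decoder, which face the
high-dimensional data; the interaction layer only mixes two
L-to-50-dimensional factors, and giving it more depth made no
difference on the simulation fixtures while slowing training).

scRNA-seq counts are scored with a zero-inflated negative binomial:
the decoder emits per-gene softmax mean fractions (multiplied by the
observed library size), per-gene-per-cell dropout logits, and a free
per-gene dispersion shared across cells. Binarized scATAC-seq peaks
are scored with a Bernoulli likelihood on decoder logits, plus a
learned per-cell coverage offset proportional to the centered log
total-peak count, so that differences in per-cell coverage are not
absorbed into `z`. Predictions are returned at typical coverage /
unit depth, i.e. depth-corrected.

Training minimizes reconstruction negative log-likelihood plus the
closed-form KL to the standard-normal prior, with Adam
(learning rate 1e-3), minibatches of 128, a 10-epoch linear KL
warm-up, and early stopping on validation loss (patience 10). The
prior on `z` is independent of time: that independence is what makes
"swap the time factor" a meaningful imputation.

### Sinusoidal time encoding

Time `t` (days) is encoded as
`[sin(w_0 t'), cos(w_0 t'), ..., sin(w_{d/2-1} t'), cos(w_{d/2-1} t')]`
with `w_i = 2*pi / 10000^(2i/d)`, `t' = t / minWavelength`, and
default `d = 50`. The fastest component has period exactly
`minWavelength` (1 day by default, so circadian-scale structure
remains representable); the slowest has period
`minWavelength * 10000^((d-2)/d)`. The frequency ladder gives the
interaction layer a rich smooth basis in `t`, which is what lets the
model interpolate profiles at never-observed times.

### Adversarial time invariance

A discriminator (two ReLU hidden layers) predicts the discrete
training time point from the cell embedding, and the encoder is
trained against it. Two implementation points matter and are easy to
get wrong:

* The generator's adversarial term is the **confusion objective** —
  the cross-entropy between the discriminator's output and the
  *uniform* distribution over time classes — not the negated
  true-class cross-entropy. Ascending the true-class cross-entropy
  against a frozen discriminator only pushes embeddings across the
  current decision boundaries; in our experiments it *increased* the
  time information recoverable by a freshly trained probe as the
  weight grew. Descending the confusion objective drives the
  discriminator toward uninformative output and empirically removes
  the leakage.
* The discriminator reads the **posterior mean**, not a sample.
  With posterior scales near 1, samples are so noisy that the
  discriminator sees almost nothing, while any downstream consumer of
  the embeddings (all of which use means) sees clean time structure.

Defaults: `advWeight = 100` (the weight is relative to a
reconstruction loss summed over genes, so its useful scale grows with
the panel size) and `discSteps = 5` discriminator updates per
generator step (the discriminator must track the moving encoder to
produce a useful gradient). On the pseudotime simulation fixture these
defaults bring a multinomial-logistic probe on frozen embeddings to
within a few points of chance while the time-aware embedding remains
fully time-predictive, and they cost held-out-time prediction nothing
measurable.

## Multimodal coupling

With RNA as the reference (denser time series) and ATAC as the
undercharacterized modality, training is stepwise: step 1 fits the RNA
model alone; step 2 fits the ATAC encoder/decoder while

* the temporal interaction layer is *copied from the RNA model and
  frozen* (shared interaction effects across modalities),
* coassay partners' embeddings are pulled together by an MSE term
  with weight lambda (`mseWeight`, grid 1 / 100 / 10000),
* translation losses run in both directions: an RNA-encoded cell
  decoded as its partner's ATAC profile (Bernoulli), and an
  ATAC-encoded cell decoded through the frozen RNA decoder against
  its partner's counts (ZINB).

Embedding pulling uses posterior means. The ATAC side has no
adversarial discriminator of its own: its embeddings inherit time
invariance by being pulled onto the adversarially trained RNA
embeddings. Cross-modality prediction encodes an RNA cell, moves it
through the shared interaction layer at the target time, and decodes
peak probabilities.

## Hyperparameters and model selection

The tuned grid is latent dimension in {25, 50, 100} (times lambda in
{1, 100, 10000} for multimodal models); hidden layers are fixed at
two and the time encoding at 50. Candidates are compared on the
validation set by summed ranks over: cross-time pseudobulk Pearson
(each validation time predicted from its nearest neighbor time), mean
LISI between neighboring time points on the embeddings, LISI between
the hold-out's flanking time points, and batch LISI when several
batches exist; summed ranks are rescaled so the best model scores
exactly 1. Ties break toward the smaller latent dimension, then the
smaller lambda. When a metric is unavailable (single batch, no
hold-out) it simply drops out of the sum. LISI uses a
perplexity-calibrated Gaussian neighborhood (perplexity 30 by
default).

Robustness ensembles train 10 models (seeds incremented; optionally a
random time point held out from each) and downstream statistics take
the member-wise median.

## Downstream statistics

**Sex-bias score.** For every cell of a cell type (pooled with the
flanking time points by default, so single-sex collections still
yield a contrast), the profile is predicted under both sex factors
from the same identity embedding, and each gene's score is the
Wilcoxon signed-rank statistic W+ of (female - male) across cells
divided by `n(n+1)/2`: 1 = extremely female-biased, 0.5 = no shift.
Scores are only computed for groups of more than 50 cells, and
ensemble members are aggregated by median. Consistently biased genes
must stay on one side of 0.5 at every retained time point (>25 cells)
while remaining in the top half of predicted expression at every one
of them. The PPI odds-ratio test compares the interaction odds
between female-biased autosomal genes and female-biased X-linked
genes against 100 same-size random autosomal sets (refused below 50
relevant interactions).

**Time-lagged cross-correlation (TLCC).** For a query cell (plus its
four best ensemble-ranked neighbors: top-25 lists per model, summed
ranks, absentees penalized at rank 26), expression and accessibility
trajectories are predicted on a dense 0.01-day grid over [7.5, 9]
days, and every proximal (peak, gene) pair — peaks overlapping the
200-kb strand-aware upstream flank of the TSS — gets a 101-entry
vector `TLCC(s) = cor(expr(t), acc(t + s))` over the core [8, 8.5]
window, `s` in [-0.5, 0.5]. Shifting is index arithmetic on the grid
(no interpolation). Pairs with maximum correlation below 0.5 or
surviving in fewer than two cells are dropped; the sign of the argmax
classifies a pair as accessibility changing "before" (negative) or
"after" (positive) expression, with ties at zero or discordant cells
left uncategorized.

Two numerical caveats are documented deliberately. First, the Pearson
argmax identifies the true lag exactly only when the two trajectories
are *linearly* related at the optimal alignment; a strongly nonlinear
link (e.g. a saturating sigmoid from signal to accessibility
probability) can bias the argmax for asymmetric temporal patterns.
Second, end-to-end lag estimates are resolution-limited by the
training design: when accessibility is observed at a handful of
nominal time points a quarter- to half-day apart, the fitted
trajectory's *phase* is only constrained at that spacing, so
recovered lags carry errors of a few hundredths to a few tenths of a
day even when their sign is reliably correct. The package's tests
therefore check grid-precision (within 0.02 day) recovery on
trajectories that contain the lag exactly, and sign/class agreement
(at least 80% of retained pairs) for the full train-predict-correlate
pipeline.

## The synthetic-data generator

The generator exists so every claim above can be tested without
external data. Per (gene, cell type) it draws a smooth log-scale
temporal pattern (flat, linear, sigmoid, pulse or sinusoid, random
amplitude and sign), adds per-gene/per-cell Gaussian noise, softmaxes
into proportions and samples Poisson counts at log-normal library
sizes. Within a block of 100 cells sharing a nominal collection time,
pseudotimes step by 0.002 day between neighboring cells — a 0.198-day
spread (the per-neighbor step is implemented literally; 99 steps of
0.002 round to the nominal "0.2-day" spread). The two named
single-modality regimes are noise SD 3 with no pseudotime spread, and
noise SD 1 with the 0.002-day steps; held-out evaluation times are
6.75, 7.25, 7.75 and 8.25 days.

The sex generator samples alternating single sexes across time points
with a configurable shared-time exception, and multiplies effect
genes by a fold change in one sex. Note one closed-composition
subtlety: with a small gene panel, boosting a few genes measurably
deflates *every* other gene's fraction, and the signed-rank score —
which detects any consistent shift, however small — then pushes null
genes away from 0.5. This is a property of compositional data, not of
the method; at genome scale the footprint is negligible. Test
fixtures therefore use a 120-gene panel with the effect placed on
low-expressed genes (`effectGeneBias = "low"`), where null scores
center on 0.5 as they would in real data.

The multimodal generator draws coassay cells whose linked peaks read
the gene's latent signal at `tau - lag` through a sigmoid, so the
TLCC argmax of the true trajectories sits at the programmed lag
(negative = chromatin leads). Two additions proved necessary to make
cross-modality alignment *testable* at desk scale: a low-rank
per-cell identity (an `identityDim`-dimensional latent vector mapped
onto gene logits and shared with the cell's peaks) — without it,
cells within a (type, time) block are statistically exchangeable and
no method could match coassay partners — and `peaksPerGene`, since a
single Bernoulli draw per gene carries too little identity
information to generalize across cells. Real data are *not* like the
remaining simplifications: there are no doublets, no ambient
contamination, no branching lineages, and identity is exactly
low-rank and time-constant. Passing tests therefore demonstrate that
the machinery recovers what it models, not that real tissues behave
this simply.

## Problem sizes and reproducibility

The shipped tests train on fixtures of roughly 2,000-2,700 cells with
60-120 genes (single-modality), 2,000 RNA + 800 ATAC cells with 40
genes and about 125 peaks (multimodal), and a 48-pair
high-information coassay fixture for the alignment check; ensembles
use 3-5 members. These sizes keep the full suite in the tens of
minutes on one CPU while leaving every qualitative conclusion stable
across the seeds we examined; the alignment (mutual-nearest-neighbor)
rate is the most seed-sensitive quantity, varying roughly 0.69-0.88
across data seeds at the fixture's settings. Every entry point that
consumes randomness takes an integer seed, and identical seeds give
bit-identical simulations and training trajectories.

## Known limitations

* The somite-to-day conversion's anchor (which day corresponds to
  somite 0) is an assumption exposed as `baseDay`; only the 2/34-day
  increment is established.
* "Upstream" peak assignment uses the single strand-aware 200-kb
  window upstream of the TSS, not a symmetric flank.
* Absolute lag magnitudes from the TLCC pipeline are
  sampling-interval-limited (see above); interpret the before/after
  classes and the ordering of lags, not their third decimal.
* Cross-modality alignment requires coassay anchors; nothing in the
  package aligns modalities without them.
* Proliferation, cell death and lineage branching are not modeled;
  the time factor moves a cell along its own trajectory only.
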