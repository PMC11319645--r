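---
title: "Transfer learning for CRISPR/Cas9 on-target efficiency: models, protocols, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for CRISPR/Cas9 on-target efficiency: models, protocols, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

CRISPR/Cas9 editing efficiency varies strongly between guide RNAs, and the
datasets available to model it come in two very different shapes. Lentiviral
high-throughput screens measure tens of thousands of guides in a synthetic
genomic context; functional and endogenous datasets measure hundreds to a few
thousand guides in a biologically meaningful cellular context, but correlate
only partially with the screens. A model trained on a screen alone transfers
poorly to a specific cellular context; a model trained on a small functional
dataset alone overfits. `crisprtl` implements the transfer-learning answer:
pre-train a sequence model on a large source screen, then fine-tune it on the
small target dataset, with explicit control over which layers move during
fine-tuning and strict Hamming-distance leakage control at every split.

## Data model and conventions

A dataset is a table of guides: a 21-nt sequence (20-nt protospacer + the
first PAM base; the final PAM `GG` is constant in these libraries and is
never modeled), an optional 30-nt extended context laid out as 4 nt upstream,
20 nt protospacer, 3 nt PAM, 3 nt downstream (0-based offsets `[0,4)`,
`[4,24)`, `[24,27)`, `[27,30)`), and one efficiency in `[0,1]` per condition
(an enzyme variant such as WT/eSpCas9/SpCas9-HF1, or a dataset's single
readout). Efficiencies are min-max normalized **per dataset, once, before any
filtering or splitting**; the raw min/max are recorded so predictions can be
mapped back. Missing per-enzyme measurements stay absent — they are masked
out of the loss, never imputed. Letter order `A,C,G,T`, enzyme order
`WT,Esp,HF`, and `U -> T` input mapping are frozen so encodings are
reproducible across machines and runs.

## Leakage control

All sequence similarity is Hamming distance over the 23-nt guide+PAM string.
Three thresholds are used, all with strict inequality (`distance < T` links
two guides): source-vs-target removal uses `T = 4` (a source guide within
distance 3 of any target guide is dropped), pre-training splits use `T = 5`,
and fine-tuning splits link guides at distance at most 4 (the same `T = 5`
graph). Clusters are connected components of the link graph, found by
union-find over candidate pairs from pigeonhole segmentation: a 23-mer is cut
into `max_dist + 1` segments (5,5,5,4,4 at distance 4), and any pair within
`max_dist` mismatches must agree exactly on one segment, which turns the
otherwise quadratic all-pairs scan into hash lookups. Whole clusters are
assigned greedily to whichever side of a split is furthest below its quota,
so the achieved test fraction is within `max cluster size / N` of the
request and no near-duplicate pair ever spans the split. A cluster larger
than both quotas goes to train with a warning — quota preservation is
impossible in that degenerate case and the training side is the conservative
destination. Ties in the size ordering break by smallest member id for
reproducibility.

## The two architectures

Both models are regression networks from sequence to efficiency, built on a
small reverse-mode automatic-differentiation tape implemented in base R
matrix operations (verified against central finite differences in the test
suite; the same tape supplies the input gradients that saliency needs).

**Recurrent guide model.** Input is the start symbol plus the 21 guide
tokens over a 5-letter integer alphabet. A learned embedding feeds a
bidirectional LSTM; the full output sequence of both directions is
flattened and concatenated with 11 sequence-derived bio-features (and, for
the multi-task variant, a 3-long one-hot enzyme indicator), then passed
through a cascade of fully connected layers to a sigmoid output. We keep the
full output sequence rather than only the final hidden states: guide
efficiency is dominated by position-specific nucleotide preferences, and
flattening preserves position information that a final-state summary would
have to squeeze through the recurrence. The multi-task
variant is a single shared output head conditioned on the enzyme indicator;
each training sample contributes a loss term only for its observed enzyme.

**Convolutional context model.** Input is the 30-nt context one-hot encoded
as 30 x 4. Three parallel 1-D convolution branches with distinct widths
(default 3/5/7, ~100 filters each) are each followed by windowed pooling
(non-overlapping windows of size 2; max by default, average available) and
flattening; the concatenated branches pass through a dense layer, the
scalar binding-energy score is appended, and a dense cascade produces a
linear output. Pooling is windowed, not global: global pooling discards
position, and position-specific effects are exactly what the model must
represent.

Every trainable tensor carries one of five group tags —
`input_embedding_or_conv`, `sequence_encoder`, `dense_hidden`,
`last_hidden`, `output` — and the transfer-learning schemes are defined as
masks over these tags. "Last hidden layer" means the final dense layer
before the output unit.

## Bio-features and the energy score

The recurrent model consumes 11 deterministic per-guide features: mean
predicted unpaired probability over protospacer windows 1–7, 8–14, 15–20; a
stem-loop score (fraction of seed positions, 13–20, predicted paired);
nearest-neighbor melting temperatures of the full 20-mer and segments 1–5,
6–13, 14–20 (SantaLucia 2004 unified parameters, 25/25 nM strands, 50 mM
monovalent salt); and GC count, GC fraction, and seed GC fraction. The
window boundaries are configuration, not canon — the training contract is
only "11 finite reals per guide" — and the default secondary-structure
backend is a deliberately simple deterministic hairpin heuristic so the
pipeline needs no external folding tool; any callable returning per-position
unpaired probabilities (e.g. an adapter over an RNA-folding CLI's
dot-bracket output, for which a parser is provided) can be injected.
Features are z-scored per dataset when attached: melting temperatures and
counts otherwise sit orders of magnitude above the one-hot inputs and slow
optimization. The convolutional model's binding-energy score is injected,
not computed: a precomputed column or a callable. A documented GC-based
proxy stands in for synthetic runs; it makes no claim of thermodynamic
fidelity.

## Training and fine-tuning protocols

Optimization is Adam (plain gradient descent available) on mean squared
error, with per-epoch reshuffling; all randomness fans out deterministically
from one seed via a single derivation function, so ensembles are
reproducible yet diverse. Pre-training trains N identically specified models
from different initializations (random-ensemble initialization; the
prediction is the member mean), each early-stopped on a random 10%
validation carve-out: training halts once `patience` epochs pass without a
new best validation loss, and the best-epoch weights are restored (patience
0 therefore trains exactly one epoch). A random hyper-parameter search
(validation Spearman as the criterion, failed trials recorded at `-Inf`) is
provided for the recurrent model; the convolutional model defaults to its
source study's published recipe (Adam, learning rate 1e-4, batch 500,
ensemble of 6).

Fine-tuning schemes, as freeze masks: **full** (all tags), **last_layer**
(`last_hidden` + `output`), **no_input_layer** (all but
`input_embedding_or_conv`), and **gradual** (phase 1 = last_layer at the
configured rate, then phase 2 = all weights at the rate scaled by
`gradual_lr_factor`, default 0.1 — the published description says only "a
smaller learning rate"). Phase 1 uses the same fixed epoch budget as the
rest of the recurrent path; whether the original protocol early-stopped
phase 1 is unstated, and using one rule keeps the phases comparable. The
recurrent path first fixes its epoch budget by cluster-aware k-fold
cross-validation over the target training set (each fold fine-tunes with
early stopping, and the budget is the mean best epoch rounded half away
from zero — the published "rounded average" does not state a tie rule — with
a floor of 1), then fine-tunes every member for exactly that many epochs on
the full training split. The convolutional path instead early-stops each
member on a cluster-aware 10% carve-out with patience 100 up to 5000
epochs. Two baselines complete the comparison: **no_tl** (the pre-trained
ensemble untouched) and **no_pretrain** (fresh ensembles trained on the
target alone).

## Evaluation

Small-dataset performance is evaluated by five independent repeats: each
draws a fresh cluster-aware 80/20 split (random cluster order, derived
seed), trains the method on the 80%, and scores Spearman correlation
(average ranks on ties) on the 20%. Degenerate repeats (constant
predictions) yield `NaN` and are excluded from the mean with a recorded
count rather than crashing a comparison. Methods are compared by two-sided
Wilcoxon rank-sum tests — exact for tie-free samples up to 10 per group,
normal approximation otherwise. Cross-context generalization is summarized
as a matrix of Spearman scores of every model on every complete dataset;
because Spearman only uses ranks, no cross-dataset rescaling is needed.

## Interpretation

Attribution of nucleotide feature `j` is the mean over samples of the
gradient of the output with respect to that feature,
`I_j = (1/n) sum_i dY_i / dX_{i,j}`, computed per member and averaged over
the ensemble, using the samples the model was trained or fine-tuned on. For
the recurrent model the gradient is taken at the one-hot layer feeding the
embedding (token indices are not differentiable; the embedding lookup is
exactly `one-hot x embedding-matrix`), dropping the start symbol; for the
convolutional model the two fixed PAM `GG` positions are dropped. Signed
attributions are the default export (a position-by-letter TSV consumable by
logo renderers, plus an absolute-value variant — whether published logos use
signed or absolute heights is not stated); bio-feature, enzyme-indicator and
energy attributions go to a sidecar table, since logos visualize nucleotides
only. Attribution is identifiable only up to a per-position constant (adding
a constant to all four letters at a position changes no prediction on
one-hot inputs), so recovery analyses row-center both the attribution and
the planted truth.

## The simulator

The synthetic module generates source/target pairs with planted effects so
every stage is testable offline. Contexts are uniform random 30-mers with
`GG` fixed at the PAM; the true score is
`logistic(sum_j w[j, letter_j] + gc_effect * (GC fraction - 0.5))`, the
observation adds Gaussian noise and is min-max normalized per dataset.
Effects are drawn iid normal, row-centered (per-position offsets are
unidentifiable, see above; centering keeps recovery well-posed), zeroed at
the fixed GG positions, and the target effect matrix is
`rho * w_source + sqrt(1 - rho^2) * independent draw`, so `rho` dials
exactly the property transfer learning depends on. Defaults (source 5000,
target 300, effect scale 0.3, GC effect 0.5, noise 0.1, rho 0.6) are the
desk-scale study conditions used by the protocol tests. What the simulator
deliberately does not emulate: read-count sampling noise, library
composition biases, chromatin or any cellular covariate, and realistic
bio-feature/efficiency dependence (bio-features are computed from the
simulated sequences but carry no planted signal beyond GC). Passing tests
on simulated pairs therefore demonstrates that the machinery — leakage
control, training, freezing, attribution — behaves as specified, not that
any particular real-data Spearman will be attained.

## Desk-scale experiment protocols and problem sizes

Two protocol functions drive the package's own end-to-end checks and the
acceptance script. `tl_benefit_experiment()` pre-trains a small recurrent
spec (embedding 8, 16 recurrent units, one dense layer of 16; learning rate
5e-3, batch 500, up to 25 epochs with patience 4, ensemble of 3) on the
simulated source and compares full fine-tuning against both baselines over
five independent target splits (fine-tuning at learning rate 2e-3, batch
128, epoch budget from 5-fold cluster-aware CV determined on the first
split and shared across splits). With `rho = 0.6` full transfer should beat
both baselines; with `rho = 0` (same source, same pre-trained ensemble) the
advantage over target-only training should vanish.
`saliency_recovery_experiment()` trains a 2-member convolutional ensemble
(16 filters per branch, average pooling, up to 100 epochs) on five
independent 2000-guide simulations at noise 0.05 and asks whether saliency
ranks the largest planted (effective, row-centered) position-letter effect
in its top 3 attributions. These sizes are the package's chosen desk-scale
study conditions: large enough that the recurrent source model reaches
held-out Spearman around 0.8 and the attribution signal is clean, small
enough to run routinely on one CPU.

## Numerical choices and degenerate inputs

Min-max normalization refuses constant columns by name. Spearman refuses
vectors shorter than 3 and returns `NaN` with a warning on constant input.
Training aborts a member on non-finite loss (all members failing is a hard
error); the linear-output convolutional model can genuinely overflow under
aggressive plain-gradient steps, while the sigmoid-output recurrent model
saturates instead. Max pooling routes gradients to the first argmax on
exact ties. Forget-gate biases initialize to 1 (standard LSTM practice);
weight matrices default to Glorot-uniform initialization. Checkpoints store
one JSON weight file per parameter group per member, which makes a
fine-tuning scheme's footprint visible as which files changed; JSON weight
round-trips are exact to ~1e-15 relative, so reloaded ensembles predict
identically to well below evaluation noise.

## Known limitations

The neural stack is compact by design: no GPU path, no attention variants,
no uncertainty beyond ensemble spread; wall-clock scale is thousands to low
tens of thousands of guides. The built-in folding heuristic and the GC-proxy
energy score are stand-ins with documented shapes, not validated
thermodynamics — real analyses should inject real scores. Reproducing the
published real-data curation counts and Spearman values requires
downloading the original supplementary datasets, which the package treats
as optional external inputs rather than test fixtures.
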