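---
title: "Detecting phage depolymerases from per-residue fold labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phage depolymerases from per-residue fold labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Phage depolymerases degrade the polysaccharide layers of bacterial
hosts. Their sequences diverge quickly, but the catalytic region keeps
one of a small number of folds: the right-handed β-helix (by far the
most common), the n-bladed β-propeller, or a triple helix. A useful
detector therefore needs to reason at the level of residues — *where*
in the protein a fold-typical region sits — and only then at the level
of the whole sequence.

`depolyscan` makes this two-step structure explicit as a stacked
model:

* the **token classifier** assigns each residue one of four labels
  (`NONE`, `BETA_HELIX`, `BETA_PROPELLER`, `TRIPLE_HELIX`) from
  per-residue backbone features. It is a multinomial softmax layer
  trained with minibatch Adam under cross-entropy. Its output for a
  protein of length $L$ is a row-stochastic matrix
  $P \in \mathbb{R}^{L \times 4}$.
* the **binary head** consumes $P$ (the class *probabilities*, not
  the hard labels — soft inputs strictly generalise one-hot labels,
  and a `one_hot_labels` input mode is retained for comparison) and
  emits one depolymerase probability. Architecture: two 1-D
  convolutional layers (default kernels 7 and 5, 16 channels each,
  ReLU), global max-pooling and global average-pooling concatenated,
  then two dense layers (default 16 → 1) ending in a sigmoid. The
  decision threshold is fixed at 0.5 with ties called positive.

Training is *sequential*: the token stage is fitted first, then
frozen — its parameters are fingerprinted before and after the head
stage and asserted unchanged — while the head is fitted on its
outputs. We read "trained sequentially" as stage-wise rather than
joint fine-tuning; joint tuning would let the head reshape the token
representation and lose the interpretable per-residue labelling.
Where descriptions of such stacked designs disagree on the head depth
(one dense layer versus two), we follow the two-convolution +
two-dense reading.

Global pooling is what lets a fixed-size head read variable-length
proteins; max-pooling responds to the strongest local fold signal,
average-pooling to its extent, and both signals matter (a short
spurious patch should not dominate a long protein).

## Backbones

The token stage runs over a pluggable embedding backbone:

* **mock** (default): a deterministic encoding of each residue and
  its k-mer context. Feature $(i, d)$ is the sum over window offsets
  $o \in [-h, h]$ (default $h = 6$, i.e. 13-mers) of a fixed
  pseudo-random projection value indexed by (residue at $i+o$, $o$,
  $d$). The embedding is thus a linear image of the windowed one-hot
  encoding; with the default dimension of 280 (≥ 21 letters × 13
  offsets) the projection is essentially information-preserving, so
  the softmax stage can realise any window-linear discriminant. The
  projection values come from a private Lehmer generator so embedding
  never perturbs the user's RNG state. The mock backbone is exactly
  reproducible everywhere and is what all tests run on.
* **pretrained_plm**: one of the three published protein
  language-model configurations (6-, 12- and 30-layer; the 12-layer
  is the default name, the usual balance of memory and accuracy).
  Weights are deliberately not bundled: selecting this backbone
  without usable weights fails loudly at load time. The mock backbone
  is never substituted silently.

The choice $h = 6$ and $d = 280$ is a model capacity choice: with the
default grammars the per-window fold evidence is a sum of per-residue
log-likelihood contributions, and a 13-residue window makes the
within-domain misclassification probability of the optimal
window-linear rule small (a 9-residue window leaves a few percent of
intrinsically ambiguous interior windows, which caps per-residue
accuracy noticeably lower).

## Curation rules

The curation module encodes every decision rule of the training-set
assembly funnel as a pure function, with the external search tools
represented only by parsers for their output files:

| rule | default | reading |
|---|---|---|
| length filter | keep length ≥ 200 aa | "under 200 discarded" is strict; 200 itself is kept |
| profile-search hit | bit score > 20 **and** aligned positions ≥ 30 | "higher than" strict, "at least" inclusive |
| structural hit | probability > 0.5; β-helix > 0.2 | "exceeded"/"greater than" strict |
| cluster representative | longest member, ties by smallest id | |
| diversity cap | ≤ 5 per (embedding-cluster, annotation) | longest preferred, id tie-break |

The two clusterings play different roles: the fine sequence-identity
clusters (95 % identity / 80 % coverage) feed representative
selection, while the coarse embedding clusters (affinity propagation,
damping 0.90, no preference) carry the per-annotation diversity cap.
Both clusterings, like the profile and structure searches, arrive as
files; their generating commands are recorded as configuration
constants for provenance only. Hit calling is monotone in its scores
by construction, and all parsers reject malformed lines rather than
skipping them — silent skipping is how curation bugs hide.

The alternative reading "> 200 aa" appears in benchmark-style
descriptions of the same filter; we adopt the inclusive-200 convention
everywhere and note it here because the boundary case (exactly 200)
is decided by convention, not by data.

## Splitting

`group_shuffle_split()` partitions records 70/20/10 (token training /
binary-head training / evaluation) without ever letting a sequence
cluster straddle two sets. Quotas are the largest-remainder
apportionment of the fractions over record counts; whole clusters are
then assigned in seeded shuffled order, each to the split with the
largest remaining quota (earlier split on ties). This greedy rule is
simple, deterministic for a fixed seed, and exactly cluster-atomic;
realised fractions are the closest achievable given whole clusters. A
dataset that is one single cluster lands entirely in one split with a
warning — that is the honest answer, not an error.

## The synthetic generator

The generator exists so the full pipeline is exercisable with no
downloads. Each positive protein is a background sequence (uniform
residue composition, length 200–500 aa, the minimum mirroring the
curation filter) with **one** contiguous fold domain injected — one
domain per positive, because delineation of real depolymerases
typically yields a single catalytic region. Domains are tiled repeats
sampled from a per-fold grammar:

* β-helix: period 22, polar/small bias (S, T, N, D, G, V);
* β-propeller: period 45 (blade-scale), aromatic bias (W, Y, F, R, L, A);
* triple helix: period 3, Gly–X–Y with X, Y drawn from P, A, Q, K.

Each grammar puts 0.9 of its per-position mass on its biased set
(0.95 on glycine at the Gly anchor), the remainder spread uniformly —
enough overlap with the background that classification is a real
statistical task, enough signal that the task is provably solvable.
Domain lengths are 60–150 aa. Negatives are all-`NONE`; 30 % of them
are *hard negatives* carrying an unlabelled decoy repeat (period-7
heptad, L/E/K/I/M bias — a coiled-coil-like structural-protein
signal), so the sequence-level stage cannot succeed by merely
detecting "some repeat".

Defaults are 100 positives per fold plus 500 negatives (800 proteins,
positive fraction 0.375, echoing the roughly 1:2 positive:negative
balance of curated training sets). A separability oracle in the test
suite verifies that a *trivial* windowed naive-Bayes classifier using
only the known grammar frequencies exceeds 0.95 token accuracy on
generated data — establishing that the dataset is learnable, so the
training acceptance checks measure the model rather than the data.

What the generator does **not** emulate: real evolutionary signal,
secondary-structure context, 3-D structure, compositional bias of real
phage proteomes, or multi-domain architectures. Passing the recovery
checks therefore shows the pipeline is correct and the architecture
can learn fold-grammar signal; it says nothing about accuracy on real
proteins, which requires the pretrained backbone and real curated
data.

## Delineation

Two directions are provided. For training-label construction,
`project_match_to_units()` maps a best structural match onto
structure-derived protein units: a unit is labelled iff ≥ 50 % of its
residues lie inside the match interval, and adjacent contiguous
labelled units merge into one segment. The 50 % rule is our
operationalisation of "inferred from the best match"; it is monotone
(enlarging a match never unlabels a unit). When several hits tie, the
best match is the highest probability, then the longest interval.

At inference, `labels_to_segments()` smooths the predicted labels by
a majority vote over an odd window (default 9; ties keep the centre's
original label) and reports maximal single-fold runs of at least 30
residues (mirroring the 30-aligned-position homology floor). Both
parameters are configurable; window 1 disables smoothing, and the
segment/label representations round-trip exactly at
`min_segment_length = 1`.

All coordinates are 0-based half-open internally — unambiguous
interval arithmetic — and 1-based inclusive only in human-readable
reports.

## Metrics

`binary_metrics()` computes precision, recall, specificity, accuracy,
F1 and MCC from a confusion table. Numerical conventions:

* F1 is the harmonic mean $2PR/(P+R)$. (A published formula for this
  quantity circulates in reciprocal form; the harmonic mean is what
  the accompanying reported values are consistent with.)
* Any metric with a zero denominator is reported as 0 and listed in
  `zero_denominator_flags` — benchmark tables stay total and
  machine-readable, and the flag keeps the 0 honest.
* Multi-class (token) MCC is the generalised $R_k$ statistic on the
  4×4 confusion matrix; micro-averaged precision, recall, F1 and
  accuracy all equal trace/total, which is the signature of
  micro-averaging and is property-tested.
* PR-AUC is step-wise average precision: distinct score values form
  the threshold sweep (tied scores are one step), and the area is
  $\sum_i (R_i - R_{i-1}) P_i$. No trapezoidal interpolation — the
  interpolated variant is optimistic between sparse recall points.

`adjust_false_positives()` implements benchmark re-assessment: when
flagged false positives are re-examined and found to be genuine
positives missed by the reference truth, the confirmed-innocent FPs
move to TN (TP and FN untouched) and metrics are recomputed. Ids must
currently be FPs; anything else is an error.

## Determinism and serialisation

Every stochastic step takes an explicit seed; the same seeds give
bit-identical datasets, models and predictions. Model archives are
plain text: weights are written with 17 significant digits, which
round-trips IEEE doubles exactly, so save → load → predict equals
predict. Every pipeline command writes a manifest (inputs, outputs,
MD5 hashes, config, seed, versions) sufficient to reproduce the run.

## Problem sizes and known limitations

The bundled experiments use the generator defaults: 800 proteins, 600
for sequential training and 200 held out, identity clusters. At these
sizes the held-out token $R_k$ is ≈ 0.94, the binary MCC 1.0, and the
mean Jaccard between delineated and injected domains ≈ 0.90. These
numbers are recomputed, not stored, by `scripts/acceptance.R` and the
acceptance tests.

Limitations worth stating plainly: the mock backbone is a windowed
linear encoder, so the token stage can only learn window-linear
discriminants (sufficient for the repeat grammars, insufficient for
real remote homology); hyperparameter search is a seeded random
search over the documented space (learning rate log-uniform
10⁻⁵–10⁻³, batch size {4, 8, 16}, dropout 0–0.3) that always includes
the default configuration as trial 1 — an argmax over a trial log,
not a surrogate-model optimiser; and the curation funnel, while
rule-complete, is only as good as the external search files fed to
it.
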