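---
title: "Predicting 4mC sites from sequence windows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 4mC sites from sequence windows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourmc)
```

## The problem

N4-methylcytosine (4mC) is a DNA modification in which a methyl group is
added to the amino nitrogen of a cytosine. Experimentally mapping 4mC sites
genome-wide is expensive, so sequence-based predictors are used to triage
candidate sites. The standard benchmark format is a fixed-length window —
41 nucleotides over the alphabet {A, C, G, T, N} with the candidate cytosine
at the centre (0-based position 20) — and a binary label: 4mC or not.
`fourmc` implements the full pipeline for this problem: six feature
encodings, a small 1-D convolutional classifier, a 10-fold cross-validation
protocol with the field's usual metrics, a hyperparameter grid search, and
two model-interpretation procedures. A synthetic generator produces
benchmarks of exactly this shape so every stage runs without external data.

## Sequence encodings

All encoders are pure functions from a window string to a positions ×
channels matrix; `encode_dataset()` stacks them into an
`n × positions × channels` array.

* **BE** (binary / one-hot): each base becomes a 5-bit indicator in channel
  order A, C, G, T, N, with N as the all-zero vector — so an N row sums to
  0, not 1. Shape 41 × 5.
* **DNC / TNC** (di-/tri-nucleotide composition): the L − k + 1 overlapping
  k-mers are one-hot encoded over the 5^k k-mer alphabet, giving 40 × 25
  (k = 2) and 39 × 125 (k = 3). Two points are deliberate here. First, the
  encoding is *positional* (one token per k-mer position) rather than a
  global composition vector: a 1-D convolution needs a sequence axis, and
  the dinucleotide saliency analysis asks *where* each 2-mer matters, which
  is only answerable positionally. Second, the window count is L − k + 1
  for both k; that is the count that yields 40 and 39 positions for a 41-nt
  window. The k-mer channel order is lexicographic over the fixed symbol
  order A < C < G < N < T; the order is arbitrary but frozen, because a
  trained model's input channels depend on it.
* **NCP** (nucleotide chemical property): three 0/1 coordinates per base —
  ring structure (purines A/G = 1), hydrogen-bond strength (weak-pairing
  A/T = 1), functional group (amino A/C = 1); N is (0,0,0). Shape 41 × 3.
* **NCPNF**: NCP plus the cumulative nucleotide density
  d_i = #\{j ≤ i : s_j = s_i\} / i, i.e. how often the base at position i
  has occurred in the prefix ending there; d_1 = 1 always and d_i ∈ (0, 1].
  We emit 4 informative channels; a `pad5` flag appends an all-zero fifth
  channel for callers that want strict 5-row shape parity with the
  5-symbol description of this encoding, but we do not invent a fifth
  feature.
* **MMI** (multivariate mutual information): a 55-vector — 5 mononucleotide
  frequencies, 15 pairwise terms I2(a,b) = f2·ln(f2/(f(a)f(b))) over the
  unordered pairs, and 35 triple terms
  I3(a,b,c) = I2(a,b) − f3·ln(f3·f(c)/(f2(a,c)f2(b,c))) over the unordered
  triples, where f2/f3 count unordered adjacent pairs/triples over the
  L − 1 and L − 2 windows. The complete unordered triple multiset over five
  symbols has 35 members (all non-decreasing triples in the order
  A, C, G, T, N), and 5 + 15 + 35 is the only decomposition that reaches
  the published 55-feature total, so we use the complete set. Any
  logarithmic term touching a zero frequency is defined as 0. The
  implementation is cross-checked against an independent brute-force loop
  in the test suite.

## The classifier

The network is a stack of identical blocks

> Conv1D(f = 32, k = 5, s = 1, ELU, L2 on weights and biases)
> → GroupNorm(g = 4) → MaxPool1D(l = 4, r = 2) → Dropout(0.25)

with two blocks by default, followed by flatten → Dense(32, ELU, L2) →
Dense(1, sigmoid). The L2 weight is 1e-4 and is applied to the weights
*and* biases of every convolution and of the first dense layer (not to the
normalization parameters or the output layer). Training uses SGD with
momentum 0.95, learning rate 0.005, binary cross-entropy, 100 epochs of
batch size 32, early stopping on validation loss with patience 30, and
best-epoch checkpointing. No deep-learning framework is used: forward and
backward passes (im2col convolution, group-norm and max-pool backprop) are
implemented directly, and the analytic gradients are verified against
central finite differences in the tests (agreement ~1e-9 relative).

Choices the architecture description leaves open, frozen here:

* **Padding.** Convolutions and pooling both use "same"-style padding
  (output length = ceiling(input/stride); pooling pads with −Inf, extra on
  the right). This keeps the two-block chain valid for every in-scope
  input, including the 39-position TNC and 55-position MMI tensors, and
  makes the position chain 41 → 21 → 11.
* **Layer order.** ELU is the convolution's own activation, so it is
  applied before group normalization — the order a
  `Conv1D(activation = "elu")` layer followed by a normalization layer
  produces.
* **Initialization and epsilon.** Glorot-uniform weights, zero biases, unit
  normalization gains; group-norm epsilon 1e-5. These are the common
  defaults; nothing in the pipeline is sensitive to them at the reported
  tolerances.
* **Loss numerics.** The cross-entropy is evaluated in logit space
  (softplus form), so saturated sigmoids cannot produce NaN; a non-finite
  loss aborts training with a diagnostic instead of propagating.
* **Epoch metrics.** The per-epoch training loss/accuracy recorded in the
  history are the sample-weighted means over the minibatch passes (the
  running-metric convention of the usual frameworks); validation metrics
  come from a clean full pass. Early stopping compares validation loss
  strictly (`<`), so a plateau counts as non-improvement.
* **Seeds.** One integer seed drives weight initialization, epoch
  shuffling and dropout; the caller's RNG state is restored afterwards.
  Bit-level reproducibility across BLAS builds is not promised, which is
  why the end-to-end assertions are statistical bounds, not exact values.

The parameter count is a pure function of the architecture and input
shape; for the default two-block network on a 41 × 5 input it is 17,441,
asserted against a hand computation in the tests.

## Evaluation protocol

`make_folds()` shuffles stratified by label and divides the data into k
near-equal folds; rotation j uses fold j for testing, fold (j mod k) + 1
for validation (early stopping and checkpoint selection), and the rest for
training — the 8/1/1 role split at k = 10. The validation-fold assignment
(test fold + 1, cyclic) is our construction; only the 8/1/1 role split is
prescribed. Per-fold MCC, ACC, Sn, Sp (threshold 0.5, matching the sigmoid
decision framing) and AUC are reported along with their means over folds —
the mean-over-folds aggregation, not pooled predictions. MCC is defined as
0 whenever a marginal of its denominator is zero. The ROC is traced by a
threshold sweep over the unique scores and integrated by the trapezoidal
rule, which equals the normalized Mann–Whitney statistic with ties counted
half; the tests check this against an O(n²) concordant-pair oracle and
against pROC.

## Grid search

`grid_search()` enumerates the Cartesian product of the published tuning
ranges (1–5 conv blocks; filters 8–128; kernel 2–14; pool size/stride 2 or
4; dropout 0.2–0.4; 8000 combinations in full) and scores each by k-fold
cross-validation. The selection criterion is the mean *validation*-fold
MCC — MCC because it is the headline metric of this literature, validation
folds because test folds must stay untouched by model selection; ties go
to the first combination in iteration order. Two kinds of combination
cannot be built and are skipped with a logged reason rather than failing
the search: kernels wider than the positions surviving the pooling chain,
and filter counts not divisible by the 4 normalization groups (the
published filter range includes 22 and 42, which violate the group-norm
constraint that range is used with).

## Interpretation

**Saturation mutagenesis.** For every record, position and substitution
symbol (all five, N included, since the five-symbol alphabet is explicit
throughout), the window is mutated, re-encoded and re-scored; the map is
the mean of |p_mutated − p_original| over records. Substituting a base by
itself contributes exactly 0, so positions where all records already carry
the substituted symbol are zero by construction.

**Saliency.** The gradient of the *pre-sigmoid logit* with respect to the
encoded input (differentiating the logit rather than the probability avoids
vanishing gradients at saturated outputs) is multiplied pointwise with the
input and summed over channels, giving a per-position importance. The 2-mer
score at position i is importance(i) + importance(i+1), accumulated into
the observed dinucleotide's cell and averaged over records — our concrete
reading of "pointwise product with the binary-encoded sequence, divided
into 2-mer components". For the DNC encoding the input rows *are*
dinucleotide positions, so their channel-summed gradient × input is binned
directly; TNC and MMI have no dinucleotide-aligned gradient path and are
rejected with an error naming the scheme. Both maps average over the whole
supplied dataset by default, with a `positives_only` flag, since it is not
specified which set published attribution figures were averaged over.

## The synthetic generator

`simulate_windows()` emulates the *shape* of the real benchmarks: balanced
classes of 41-nt windows, central C forced in every record. The class
signal is a short motif (default "CC", the methylation context itself)
planted at a fixed offset from the centre with probability p in positives
(default 0.9) and q in negatives (default 0.1); background bases are i.i.d.
uniform over A/C/G/T with a 1% N rate so the five-symbol code paths stay
exercised. The generation order is background → motif → centre forced to C.
The defaults place the motif on the centre so the interpretation maps have
a known ground-truth hotspot at the window centre, mirroring the centre
peak reported for real 4mC models.

What the generator does *not* emulate: genomic sequence context, CpG
structure, species-specific composition, homology between records, or
label noise from the underlying sequencing chemistry. Passing the
end-to-end tests therefore demonstrates that the pipeline can extract a
localized sequence signal under controlled conditions — not that it
reproduces published performance on real genomes, which requires the
external benchmark files.

## Problem sizes and test design

The end-to-end checks run at sizes chosen to exercise the full protocol on
a single CPU: 300 windows per class for the 10-fold discrimination checks
(separable benchmark: motif "CCCC", p = 1, q = 0; null benchmark: p = q =
0.5), and 200 per class for the interpretation model trained on the
generator defaults. On the separable benchmark the tests require the
default classifier to reach mean AUC ≥ 0.95 and accuracy ≥ 0.90; on the
null benchmark the mean AUC must stay within 0.5 ± 0.1. `scripts/acceptance.R` recomputes all of these quantities from
scratch under a caller-supplied seed.

## Known limitations

* Pure-R training is CPU-bound: a 10-fold run at the sizes above takes a
  few minutes. The implementation is vectorized (im2col + BLAS matrix
  products) but does not use compiled code or threading.
* Only convolution stride 1 is implemented — the architecture under study
  fixes s = 1 and the tuning grid does not vary it.
* The greedy identity filter (`filter_redundant()`) is a naive stand-in
  for CD-HIT-EST-style redundancy removal: it uses ungapped full-length
  identity in input order and will not reproduce CD-HIT-EST clusters.
* Published headline numbers on the public plant-genome 4mC benchmarks
  are not reproducible here without their FASTA files; given such a pair,
  `cmd_cv()` emits the same metric set (MCC/ACC/Sn/Sp/AUC) for side-by-side
  comparison.
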