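---
title: "Predicting drug–disease associations with kerndr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug–disease associations with kerndr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kerndr)
```

## The problem

Drug repositioning asks which approved drugs might treat diseases they were
never developed for. The starting point is a binary association matrix
$A$ (diseases on the rows, drugs on the columns; $A_{ij} = 1$ when drug $j$
is a known treatment for disease $i$), plus two *side* similarity sources:
chemical-structure similarity between drugs (Tanimoto coefficients of
molecular fingerprints) and semantic similarity between diseases (a
MimMiner-style matrix computed from MeSH term profiles, consumed here as a
precomputed input). `kerndr` turns these into per-pair descriptors, learns a
feature representation with a small convolutional network, and scores pairs
with a random forest.

## The similarity model

**Interaction-profile kernels.** Each drug's interaction profile is its
column of $A$, each disease's its row. The sigmoid kernel between two
profiles $u, v$ is

$$K(u, v) = \tanh\!\left(a \,\langle u, v\rangle + r\right),
\qquad a = 1/N,\; r = 0,$$

with $N$ the profile length. Profiles that share many partners score close
to $\tanh(1)$; disjoint profiles score 0. Both parameters are exposed
(`similarity_control()`), with the $1/N$ scale as the default.

**Logistic rescaling.** Raw side similarities are pushed through
$L(x) = 1/(1 + e^{cx + f})$ with defaults $c = -15$, $f = \ln 9999$, so
$L(0) = 10^{-4}$ and $L(1) \approx 0.997$: weakly informative similarities
are silenced, strong ones are amplified. These defaults follow the
convention of the comprehensive-similarity literature this model builds on;
both are tunable, and the same defaults serve drugs and diseases.

**Cohesive-module enhancement.** Drugs that co-treat diseases form a
weighted graph (edge weight = number of shared diseases; the disease graph
is built the same way from shared drugs). Cohesive modules are detected by
a greedy, fully deterministic procedure: seeds in descending
weighted-degree order, each seed grown by the single add-or-remove move
that most increases the cohesiveness

$$f(C) = \frac{W_{in}(C)}{W_{in}(C) + W_{bound}(C) + P(C)},
\qquad P(C) = 2\,|C|,$$

until no move improves it; grown groups merge when their overlap score
$|C_1 \cap C_2|^2 / (|C_1| |C_2|)$ exceeds 0.8. Pairs sharing a module get
their similarity multiplied by $1 + f(C)$ (the maximum $f$ over shared
modules when the clustering overlaps — the most generous deterministic
extension); any product at or above 1 becomes 0.99, so enhanced
similarities remain valid and the cap is idempotent. The per-vertex penalty
(2), the merge threshold (0.8) and the density filter (0 = keep all) mirror
the published defaults of the cohesive-module literature; determinism makes
every clustering exactly reproducible.

**Fusion.** For each pair the kernel value is used when *both* entities
have a non-empty interaction profile in the training data; otherwise the
kernel row is uninformative ($\tanh 0 = 0$ against everything) and the
enhanced side similarity substitutes. This is the standard new-entity
fallback in kernel-fusion repositioning. Diagonals are fixed at 0.99 so
self-similarity survives the cap uniformly.

## Descriptors and the encoder

A pair's descriptor is the concatenation of its fused drug-similarity row
and fused disease-similarity row, zero-padded to the next perfect square
and reshaped row-major into an $s \times s$ grid (906 entries give
$31 \times 31$ with 55 pads). The encoder is

conv($n_f$ filters, $k \times k$, sigmoid) → max-pool($2 \times 2$) →
dense($d$, sigmoid) → dense(1, sigmoid),

trained end-to-end on binary cross-entropy plus an L2 weight penalty
$\tfrac{\lambda}{2}\lVert W \rVert^2$ (biases unpenalised) with Adam
(plain SGD available via config). The *features* handed to the classifier
are the penultimate dense activations — the only layer that is both learned
and separable from the output unit.

Numerical choices that matter:

- **Input standardisation.** Fused similarity values are small (kernel
  entries rarely exceed 0.2), which parks every sigmoid unit on a flat
  stretch of its curve; gradients vanish and training stalls with the loss
  pinned at $\ln 2$. The encoder therefore standardises each grid cell by
  its training-set mean and SD (SD floored at 0.05 so near-constant cells
  such as padding are not amplified). The statistics are estimated from the
  training descriptors only and stored with the encoder.
- **Kernel size.** The canonical kernel is $16 \times 16$; grids smaller
  than that use half the grid side, keeping a genuine sliding window.
- **Pooling edges.** Odd trailing rows/columns are dropped by the
  $2\times2$ pool; maps smaller than the window pass through unchanged.
- **Defaults.** 32 filters, 128 dense units, 80 epochs, batch 32,
  $\eta = 0.01$, $\lambda = 2\times10^{-4}$. The literature this
  implementation follows states only the kernel and pool sizes, the
  activation, the loss and the optimizer; the remaining values were chosen
  once on the synthetic benchmark for stable training and are all exposed
  in `encoder_config()`. One conv/pool block is used; training is
  deterministic given a seed (seeded initialisation and shuffling).
- **Committees.** `n_encoders > 1` trains several encoders from different
  seeded initialisations and concatenates their feature layers — a
  variance-reduction option for small data; the default is a single
  encoder.

## Evaluation protocol

Balanced negatives are drawn uniformly from the zero cells once per
experiment (never colliding with positives), all pairs are dealt into ten
stratified folds, and each fold is scored by a model whose *entire*
upstream — kernels, clustering, enhancement, fusion, encoder, random
forest — is recomputed from a training view of $A$ with the fold's positive
cells zeroed. This strict protocol is the default. `paper_mode = TRUE`
instead computes the similarities once from the full matrix, the optimistic
protocol common in this literature; it leaks test associations into the
similarity stage and is provided to quantify exactly that effect. Metrics
are accuracy, precision, recall and F1 at a 0.5 threshold (percent,
mean ± SD across folds) plus AUC by the midrank Mann–Whitney estimator,
which is deterministic and tie-robust.

The case-study protocol (`rank_candidates_for_disease()`) removes every
association of one target disease, retrains on the rest (balanced negatives
that avoid the target), scores all drugs against the target and returns the
ranking with the withheld truth attached.

## The synthetic benchmark

`generate_synthetic()` plants matched drug/disease blocks: associations are
Bernoulli(0.4) inside a matched block and Bernoulli(0.02) elsewhere
(defaults: 60 drugs, 40 diseases, 4 blocks, round-robin assignment); side
similarities are 0.6 × same-block indicator plus Gaussian noise (SD 0.1),
clipped, symmetrised, unit diagonal. These defaults make an instance that
is clearly learnable, leaves some entities with empty profiles (exercising
the fusion fallback), and runs in minutes on one CPU.

What the generator does *not* emulate: real chemistry (fingerprint
similarities have heavy-tailed, non-block structure), real disease
ontologies, hubness of drug usage, and — critically — any association
signal beyond block membership. That last point bounds what is achievable:
because cells are conditionally independent given blocks, the same-block
indicator is the Bayes-optimal score under the strict protocol, and its
ten-fold mean AUC on the default instance (seed 0) is 0.846. Passing tests
on this benchmark therefore demonstrate correct mechanics and genuine
signal recovery, not the headline accuracy reachable on the real
benchmarks, whose training sets are about seven times larger. On the
default instance the full pipeline reaches a mean AUC of roughly 0.84
under the optimistic protocol (a random forest on raw descriptors, which
skips the encoder bottleneck, reaches about 0.92 there; at this sample
size the convolutional compression costs accuracy rather than adding it).
The no-signal control (equal within/background rates) stays at chance, and
a marker test verifies that a test-fold association never influences any
training-view similarity.

## Known limitations

- Disease semantic similarity is consumed, never computed; drugs without
  parseable SMILES get zero structure similarity (the kernel can still
  cover them after fusion).
- The encoder is a faithful small CNN, not a modern architecture; sigmoid
  activations were kept for fidelity and need the standardisation layer to
  train.
- Strict per-fold recomputation makes cross-validation roughly ten times
  more expensive than the optimistic protocol; both are exposed.
- Problem sizes in the test-suite are desk-scale (tens of entities,
  hundreds of pairs) so the whole suite runs in minutes; the package
  itself handles the reference-scale matrices (593 × 313) without special
  handling.
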