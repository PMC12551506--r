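---
title: "Simulated INT8 quantization for embedding-based ontology alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated INT8 quantization for embedding-based ontology alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalign)
```

## The problem

Aligning a layman biomedical vocabulary with a large ontology string
table means finding, for every lexicon entry (a term plus its public
explanation), the ontology concept whose surface string is semantically
closest. The embedding approach encodes both text collections with the
same sentence encoder, computes the dense cosine-similarity matrix
between the two sides, and maps each lexicon entry to the ontology row
maximizing its similarity:

$$ S_{ij} = \frac{\langle e^{L}_i, e^{M}_j\rangle}{\lVert e^{L}_i\rVert\,\lVert e^{M}_j\rVert},
\qquad j^{*}_i = \arg\max_j S_{ij}. $$

Because the ontology side can hold millions of strings, the encoder's
cost dominates, which motivates post-training INT8 quantization of the
encoder (8-bit weights and activations, "W8A8"). This package provides
the complete desk-scale apparatus to study that trade-off: the
quantization arithmetic itself, a deterministic encoder that runs in
FP32 or in simulated INT8, the alignment and evaluation pipeline, and a
seeded synthetic-corpus generator with known ground truth so every
property is verifiable without licensed resources.

## The quantization model

A real tensor $x$ is mapped to a symmetric signed-int8 grid
$q = \mathrm{clamp}(\mathrm{round}(x/s), -127, 127)$ with zero-point 0.
We use the range $[-127, 127]$ rather than $[-128, 127]$ so negation
stays symmetric and a single positive scale parameterizes each tensor
or channel. Rounding is round-half-to-even: it is unbiased and
bit-reproducible across platforms (no rounding mode is standard in this
setting, so we fix one and document it).

Two granularities are supported:

* **per-tensor** — one scale $s = \max|x| / 127$ for the whole tensor
  (activations always use this, computed dynamically);
* **per-channel** — one scale per row or column, used for weights
  (per output column), which always weakly reduces the Frobenius
  quantization error relative to a per-tensor scale.

The quantized linear operator accumulates the integer grids exactly and
applies the scales afterwards:
$y_{ij} = \bigl(\sum_k q^x_{ik} q^W_{kj}\bigr)\, s_x\, s_j .$
Exactness holds because int32-style sums of int8 products are
representable exactly (in R, in doubles well below $2^{53}$). The
combination *per-channel activations with per-channel weights* is
rejected with a "non-dequantizable scheme combination" error: the scale
of an activation channel then depends on the contraction index and
cannot be factored out of the sum, so no single dequantization scale
exists. Elementwise operators (bias add, ReLU) use
dequantize-then-apply semantics.

Degenerate inputs: an all-zero tensor or channel receives a tiny
positive floor scale ($10^{-12}$) so every `QuantizedTensor` carries
strictly positive scales and dequantizes to exact zeros.

## Smoothing: migrating activation outliers into the weights

Transformer activations often have a few channels with far larger
magnitudes than the rest; a single per-tensor activation scale then
wastes most of the int8 grid. The smoothing step rescales channel $j$
of the activations by $1/s_j$ and row $j$ of the weights by $s_j$,
leaving the product unchanged, with

$$ s_j = \frac{\max(\max_i |X_{ij}|,\ \varepsilon)^{\alpha}}
             {\max(\max_k |W_{jk}|,\ \varepsilon)^{1-\alpha}} . $$

`alpha` (default 0.5) balances how much of the range difficulty moves
to the weight side; 0.5 splits it evenly and is the package default for
both execution paths. The closed form follows the established
activation-smoothing approach for W8A8 quantization; the
$\varepsilon$-floor (default $10^{-8}$) guards channels that are
identically zero in the calibration set. Activation maxima come from
running the FP32 forward pass over a calibration corpus
(`collectActivationStats()`); those statistics are used *only* for the
smoothing scales — activation quantization itself stays dynamic.

## The encoder

The encoder is a deliberately small, fully deterministic stand-in for a
pretrained transformer; pretrained weights are out of scope. Its
forward pass is: token-embedding lookup plus a fixed sinusoidal
positional signal, then $n$ positionwise linear blocks
(matmul, bias add, ReLU; the final block omits the ReLU), then mean
pooling over the sequence. There is no cross-token attention: the
quantized operator set of interest is exactly matmul/add/relu, and
pooling makes alignment depend on token content, which is sufficient to
exercise every quantization and alignment contract at desk scale.

Tokenization is hash-based: text is normalized (lowercase,
non-alphanumerics to spaces, whitespace collapsed, stopwords dropped),
split on spaces, and each token id is `3 + (stable FNV-1a hash mod
(V - 3))`, with PAD = 0, CLS = 1, SEP = 2. The hash is seed- and
process-independent, so identical text always maps to identical ids.
Pair encoding uses the layout `[CLS] A [SEP] B [SEP]` and is provided
for scored sentence pairs; the alignment pipeline encodes single
concatenated texts.

Design choices that matter:

* **Pooling.** The default pools over *all* `maxLen` positions,
  padding included, matching the plain sequence-length average of the
  batch-encoding formulation; a mask-aware mean is available via
  `pooling = "masked"`. To keep the literal full-length mean
  meaningful, the PAD embedding row is fixed at zero (the familiar
  `padding_idx` convention), so padded positions contribute only the
  small positional signal rather than a large shared component.
* **Dynamic activation scales per sequence, not per batch.** Each
  sequence's activation matrix is quantized on its own, so embeddings
  are bit-identical for any batch size. Reproducibility trumps the
  micro-efficiency of batch-level scales.
* **Dimensions.** Defaults are $d = 192$, $H = 384$, 2 layers. A
  random positionwise network preserves the token-overlap geometry of
  two texts only up to a distortion that shrinks like $1/\sqrt{H}$;
  with much smaller widths that distortion is comparable to the cosine
  margins between matched and unmatched concepts and alignment
  accuracy suffers. The defaults keep the distortion safely below the
  margins while remaining fast on one CPU.
* **Positional amplitude.** The sinusoidal signal is scaled to 0.1 of
  the unit-variance token embeddings: position is secondary
  information for bag-of-content matching, and a full-amplitude signal
  inflates the shared component across texts, compressing cosine
  margins.
* **Initialization.** Linear weights are seeded standard normals
  scaled by $1/\sqrt{\text{fan-in}}$, keeping activations $O(1)$ so
  the int8 range is exercised meaningfully.
* **Sequence length.** The class default is `maxLen = 512`; the study
  configuration used throughout the tests and the acceptance script is
  `maxLen = 16`, ample for the synthetic texts (at most ten tokens
  with specials) and proportionally cheaper.

Quantizing an encoder (`quantizeEncoder()`) folds the smoothing scales
into each layer's weights, quantizes the smoothed weights per output
channel (or per tensor on request), and leaves biases in FP32. The
serialized payload of the quantizable weights is 1 byte per int8 value
plus 4 bytes per scale, versus 4 bytes per FP32 value — about 26% of
the FP32 payload at the default shapes. Payload size is the package's
deterministic proxy for the deployment-side memory/latency benefit;
wall-clock latency is hardware-dependent and deliberately not measured.

## Alignment, merging, and the configuration search

`alignCorpora()` computes the dense similarity matrix in one pass (the
naive $O(n^2)$ formulation — exact and oracle-testable; approximate
nearest-neighbour search is out of scope) and maps every source row to
its argmax, ties broken toward the smallest target index so results
are deterministic and order-stable. Alignment is many-to-one; no
global one-to-one assignment is attempted.

Raw cosine scores are calibrated onto the six-point 0–5 rating scale by
min–max rescaling, fit on the score vector being rescaled. A constant
score vector maps to the bottom of the scale — no similarity evidence,
conservative by design (configurable).

`complementarityMerge()` combines two models' manually rated
alignments: iterate the rating from 5 down to 0, at each level first
admitting the primary model's uncovered alignments, then the secondary
model's. The merged set covers exactly the union of sources, keeps one
alignment per source, and never downgrades: each source enters at the
highest rating either model offers it. Sub-3 alignments are kept by
default; a `minRating` filter is available.

`searchQuantConfigs()` evaluates a finite candidate space (scheme
granularity × smoothing factor) exhaustively. Quality is argmax
agreement with the FP32 alignment; cost is the serialized weight
payload. Candidates are feasible when degradation stays within
`maxDegradation` (default 0.01%) and the payload shrinks by at least
`minCostReduction` (default 20%) — the latter replaces a
latency-improvement constraint with its deterministic size proxy. The
report includes the Pareto frontier (points not strictly dominated in
quality/cost) and the best feasible frontier point. An adaptive
sampler would add nothing here: the space is tiny and exhaustive
search subsumes its result.

## Evaluation metrics

* **EDRM** — for predictions $h_i$ and references $r_i$ on a scale
  $[lo, hi]$: $\mathrm{EDRM} = \frac1n \sum_i
  \bigl(1 - |h_i - r_i| / d_{\max}(r_i)\bigr)$ with
  $d_{\max}(r_i) = \max(r_i - lo,\ hi - r_i)$, the largest distance any
  prediction on the legal scale can achieve from $r_i$. Predictions
  are clamped into the scale first, keeping the metric within
  $[0, 1]$ for arbitrary raw scores. Note $d_{\max} \ge (hi - lo)/2 >
  0$ whenever the scale is non-degenerate; the defensive branch for
  $d_{\max} = 0$ contributes 1 exactly when $h_i = r_i$.
* **Triplet MAP** — each group has one source, three candidates and
  one correct target; candidates are ranked by cosine to the source
  (ties toward the smaller index), average precision is the
  reciprocal rank of the correct target, and MAP is the mean over
  groups. The general multiple-correct-answers form is reachable via
  precomputed ranks.
* **Spearman** — rank correlation with average ranks on ties, via
  `stats::cor`; a constant vector raises an error rather than
  returning `NA`.

## The synthetic-data generator

`genAlignedCorpora()` emulates the paired lexicon/ontology setting:
each of `nConcepts` concepts owns four unique base tokens; the lexicon
row carries them as term (2) plus explanation (2), the ontology string
carries all four plus a variant affix, in the same order (the
positionwise encoder sees aligned positions). One synthetic CUI per
concept keeps top-1 accuracy well-defined. Every token is replaced by
a token from a disjoint noise pool with probability `noiseRate`, so
difficulty rises monotonically with noise. Defaults — 50 concepts, one
entry per side, noise 0.1 — are the study conditions used by the test
suite and the acceptance script. `genSimilarityPairs()` builds scored
sentence pairs whose 0–5 mark is `round(5 rho)` for a uniformly drawn
token-overlap fraction `rho`; `genTriplets()` builds groups whose
correct target is a token-dropout copy of the source and whose
distractors are other groups' sources. All generators draw from a
single seeded generator scoped to the call and write byte-identical
files per seed.

What the generator does **not** emulate: real lexical variation
(synonyms that share no surface tokens), subword morphology, polysemy,
bilingual translation noise, and the skewed length and frequency
distributions of real terminologies. Passing tests therefore
demonstrate that the quantization and alignment machinery is correct
and that quantization preserves alignment behaviour *on corpora whose
signal is token overlap* — they do not certify accuracy numbers on real
lexicon/ontology pairs, which also depend on a pretrained encoder.

## Problem sizes and runtime

The test suite and acceptance script run, per replicate, 50 lexicon
entries against 50 ontology strings at `maxLen = 16` with the default
encoder, over ten fixture seeds; the similarity task uses 200 pairs and
the triplet task 100 groups. These sizes give stable statistics (500
alignment decisions per condition) while the whole pipeline — fixture
generation, FP32 and INT8 encoding, alignment, and all metrics —
completes in well under a minute on one CPU.

## Known limitations

* The encoder is positionwise; phenomena that need cross-token
  interaction (contextual disambiguation, word order beyond the
  positional signal) are outside its reach.
* Lemmatization is not implemented; the normalizer (lowercasing,
  punctuation splitting, stopword removal) is the in-package
  substitute.
* Quantization is simulated in ordinary arithmetic with genuine
  integer accumulation; there are no hardware kernels, and no
  latency, energy or emission measurements — serialized payload size
  is the only cost measure.
* The min–max calibration is fit per score vector; no learned
  correction beyond rescaling is modelled.
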