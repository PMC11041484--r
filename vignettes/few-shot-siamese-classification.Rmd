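---
title: "Few-shot sentence classification with Siamese networks: methods and design"
author: "fewshotSNN maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot sentence classification with Siamese networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fewshotSNN)
```

# The problem

Clinical text classification rarely comes with abundant labels: annotating
sentences from critical-care notes requires clinical expertise and access to
protected data. In the N-way-K-shot regime only K labeled examples per class
(here K ∈ {4, 8, 16}, N = 4) are available for training, while hundreds of
samples must be classified. Fine-tuning a large model on 16–64 samples is
unstable; this package instead treats a pretrained sentence encoder as a
frozen feature extractor and performs classification in its embedding space
with two Siamese-network-style methods.

Both methods operate on an `EmbeddingSet`: an n × d matrix of sentence
embeddings with aligned class labels, stored as a `SummarizedExperiment`.
Embeddings can come from any pluggable backend; the bundled offline backend
(`hashingBackend()`) maps character n-grams through seeded Gaussian random
projections, which is deterministic and requires no model download. It
preserves lexical overlap structure — texts sharing character n-grams are
close in cosine space — but none of the *semantics* a pretrained transformer
captures, which is exactly enough to exercise the algorithms and not enough
to make claims about clinical accuracy.

# PT-SNN: mean class cosine similarity

For sentences $a, b$ with embeddings $A, B$, similarity is the cosine

$$\mathrm{cos}(A, B) = \frac{A \cdot B}{\lVert A\rVert_2 \lVert B\rVert_2}.$$

A test sample receives, for every class $c$, the arithmetic mean of its
cosine similarities to all support samples of $c$, and is assigned the
arg-max class. With one support sample per class this is nearest-neighbor
classification; with K samples it is a class-mean rule on the unit sphere.
The implementation is fully vectorized: both sides are row-L2-normalized,
the similarity table is a single matrix product, and the per-class means are
a second product with the row-L1-normalized one-hot label table.
`classScores()` exposes the score table, `classifyPT()` the decision.

Numerical choices:

* **Ties** in the arg-max are broken toward the earliest class in
  `classOrder()` (sorted label order). Exact ties occur with measure zero on
  continuous data but must be deterministic for reproducible evaluation.
* **Zero vectors** are rejected (with the offending row index) rather than
  silently mapped anywhere: cosine similarity is undefined at the origin.
* No sigmoid is applied at classification time: a monotone transform applied
  after averaging cannot change the arg-max, so the scores reported are
  plain mean cosines in [−1, 1]. (The sigmoid matters only inside the
  SOE training loss, where the pair score must live in (0, 1).)
* The vectorized path is held to agree with a scalar double-loop oracle to
  1e−8; in practice agreement is at machine precision.

# Pair augmentation

Siamese training does not consume samples, it consumes *pairs*. From NK
support samples, all unique unordered pairs

$$\{(x_i, x_j)\,:\, i < j\}, \qquad \#\text{pairs} = \frac{(NK)^2 - NK}{2}$$

are enumerated with a binary target: 1 if the two samples share a class,
0 otherwise. Eight samples yield 28 pairs (a 3.5-fold augmentation), sixteen
yield 120 (7.5-fold). `makePairs()` enumerates exhaustively in lexicographic
(i, j) order — the ordering is deliberately deterministic so that any
shuffling happens downstream under the training seed. Self-pairs are
excluded. No balancing or hard-negative mining is done: at few-shot scale
the exhaustive set is small and the class imbalance of the pair targets is
part of the signal.

# SOE-SNN: a trainable second-order encoder

The second method learns a task-adapted metric. A *second-order* encoder —
two weight-sharing copies of a bidirectional LSTM followed by a linear
projection — maps each frozen first-order embedding to a new vector. A pair
of samples is scored

$$\mathrm{out} = \sigma(\mathrm{distance}(e_1, e_2)),$$

where the distance is cosine similarity by default (configurable to negative
Euclidean), and trained with binary cross-entropy against the same-class
flag, penalizing high similarity for cross-class pairs and low similarity
for within-class pairs. Classification then applies the PT-SNN rule to the
second-order embeddings.

Design decisions that were genuinely open:

* **Sequence view.** A recurrent encoder needs a sequence, but a sentence
  embedding is a single vector. We view the d-vector as `chunkLength`
  consecutive segments of size d/`chunkLength` (default 16, shrunk to the
  largest divisor of d). This preserves all information and gives the
  bidirectional LSTM a genuine sequence; it is the least-assumptive reading
  of "stack a recurrent layer on the embeddings".
* **Data split.** Of the NK support samples, half train the encoder and half
  serve as the labeled support set for classification. The split is
  *stratified per class* (every class must stay represented on both sides,
  otherwise the classification step is undefined), with the larger part of
  an odd class going to the encoder side. `splitForSOE()` is deterministic
  given its seed.
* **Optimizer and training loop.** Binary cross-entropy with AdamW
  (decoupled weight decay 0.01), learning rate 1e−3, 50 epochs, full-batch
  over all pairs — at few-shot scale a full batch is at most a few hundred
  pairs, so minibatching buys nothing and costs determinism. All of these
  are exposed in `encoderConfig()`. The recurrent architecture sizes
  (hidden 32 per direction by default) are implementation defaults, not
  empirically reported values.
* **Implementation.** The encoder, backpropagation through time and AdamW
  are written in plain R. Gradients are verified against central finite
  differences in the test suite (agreement below 1e−7 on sampled
  coordinates). Training is exactly reproducible given the config seed.
* An `architecture = "identity"` pass-through encoder is provided; with it,
  `classifySOE()` provably reduces to `classifyPT()`, which the tests
  exploit as a reduction check.

Note the cosine-distance variant bounds the pair score to
(σ(−1), σ(1)) ≈ (0.27, 0.73), so the BCE loss cannot reach zero even on
perfectly separated data; what matters for classification is the induced
geometry, not the absolute loss value.

# Episodic evaluation with M-iteration averaging

Small-support classifiers are unstable under resampling of the support set,
so every reported metric is an average over M independent episodes
(M = 3 by default):

$$\mathrm{Metric} = \frac{1}{M}\sum_{i=1}^{M} \mathrm{Metric}_i.$$

Episode Idx (0-based) draws exactly K samples per class without replacement
using seed `baseSeed + Idx` — the seeds are the iteration indices, making
the entire protocol reproducible end to end. Two test-set conventions are
supported because both are defensible: `"complement"` (default) classifies
every sample not drawn into the support set, which on a 444-sample 4-class
corpus yields the train/test sizes 16/428, 32/412 and 64/380 for K = 4, 8,
16; `"fixed_test"` evaluates every episode against one held-out set.

`computeMetrics()` provides macro, weighted and micro precision/recall/F.
The default is **macro**: under heavy class imbalance (majority share 55.2%
in the emulated corpus) micro-averaging is dominated by the majority class,
and macro is the conservative choice. Published tables in this area often
leave the averaging scheme unstated, which is precisely why all three are
implemented and the choice is explicit in every result row. A class never
predicted contributes precision 0 rather than NaN (the usual sklearn-style
convention); micro precision = recall = F = accuracy, which the tests use
as a closed-form cross-check.

# Synthetic data: what it emulates and what it does not

`generateEmbeddings()` draws N class centroids on the unit hypersphere with
a minimum pairwise angle (default 60°, rejection sampling) and adds
isotropic Gaussian within-class noise. Centroids are placed on the sphere
because cosine classification is scale-invariant: only angles carry class
signal. Per-class counts are apportioned by largest-remainder rounding,
which reproduces the emulated corpus exactly: proportions
55.2/26.4/10.8/7.7% at 444 samples give counts 245/117/48/34. The default
within-class noise (0.25 relative to unit centroids) makes 4-shot
classification good but imperfect — informative for testing.

`generateToyCorpus()` produces texts from disjoint class-specific token
pools so the hashing backend yields separable embeddings, enabling
end-to-end corpus → embeddings → classifier tests.

What passing tests on this data **do** show: the algorithms are implemented
correctly (oracle equivalence, parameter recovery at zero noise, chance
behavior at extreme noise, monotone degradation with noise). What they do
**not** show: anything about accuracy on real clinical text, where class
structure is not isotropic-Gaussian, classes overlap, and embedding quality
depends on the pretrained backend. Published precision/recall/F values on
the restricted 444-sentence clinical corpus require both that data (under a
data-use agreement) and specific pretrained language models, and are
deliberately not used as numeric targets anywhere in this package.

# Prompt baseline construction

For comparison against a generative baseline, `buildPrompt()` constructs the
prefix prompt

```
{text}. options are advanced cancer, advanced heart disease,
advanced lung disease, chronic pain fibromyalgia. type of disease
```

with generation beginning where the prompt ends. If the tokenized prompt
exceeds the context budget (default 1024 tokens), the *input text* is
trimmed from its end, token by token, until it fits — the options list and
the trailing scaffold are never touched. Token counting is pluggable; the
default whitespace tokenizer avoids a tokenizer-model download, and an
adapter for a real subword tokenizer can be passed to `promptTemplate()`.
Querying a generative model and mapping its free-text output to classes are
out of scope (the latter is a human-annotation step by nature).

# Problem sizes and limitations

The test suite and the acceptance script run synthetic problems of modest
size — corpora of 120–516 samples in 16–64 dimensions, encoders with hidden
size 8–16 trained for up to 60 epochs on ≤ 120 pairs — chosen so the full
pipeline (including five-seed trend assertions) completes in well under a
minute while still exercising every code path at the same N, K and M as the
emulated study design.

Known limitations:

* The pure-R LSTM is adequate for few-shot scale only; hundreds of support
  samples or large hidden sizes would call for a compiled backend.
* The hashing backend is lexical; backends wrapping real sentence encoders
  must be supplied by the user as `embeddingBackend()` adapters.
* Exhaustive pairing grows quadratically in NK; no pair subsampling is
  implemented because the few-shot setting never needs it.
* `evaluateAveraged()` reports no between-method significance tests; with
  M = 3 iterations a formal test would be underpowered anyway.
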