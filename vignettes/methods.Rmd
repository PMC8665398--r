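---
title: "Knowledge-graph-augmented clinical sentence similarity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph-augmented clinical sentence similarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphsts)
```

## The problem

Clinical notes accumulate near-duplicate sentences through templating and
copy-forward documentation. Detecting such redundancy is cast as semantic
textual similarity (STS): given two sentences, predict a similarity score on
a 0–5 rubric (0 = unrelated, 5 = equivalent), evaluated by the Pearson
correlation between predicted and gold scores, overall and within manually
assigned topical categories (status, education, meds, miscellaneous).

Plain text encoders miss domain knowledge that clinicians take for granted:
that "pacu" is the post-anesthesia care unit, that two drug names are close
relatives in a terminology, that two differently-worded findings denote
neighboring concepts. `graphsts` injects that knowledge from a SNOMED
CT-style terminology graph along two routes:

1. **Textual augmentation** — concept mentions found in a sentence
   contribute their preferred names and semantic types, appended to the
   sentence before text encoding.
2. **Graph encoding** — each sentence's concepts are looked up in the
   terminology graph; the union of pairwise shortest paths between them
   forms a per-sentence concept subgraph, encoded by a graph convolutional
   network (GCN) whose node features come from pretrained concept
   embeddings.

## Pipeline and model

### Terminology graph and subgraph induction

Concept and relation tables are read from pipe-delimited RRF-dialect files
(standard MRCONSO/MRREL column positions by default; the column map is
configurable because miniature fixtures and other dialects move columns).
The graph is undirected, unweighted and untyped: only connectivity among
concepts is retained, relation labels are carried along but never affect
topology.

For a sentence with tagged concepts $C = \{c_1, \dots, c_k\}$, one shortest
path is computed for every unordered pair within the same connected
component (breadth-first search, since edges are unweighted) and the
induced graph is the union of the nodes and consecutive edges of those
paths. Choices worth making explicit:

* *All seed pairs* are connected, which is order-independent and maximal.
* *Exactly one* shortest path per pair is used, with ties broken by
  expanding neighbors in lexicographic CUI order. Any fixed tie-break
  works; a deterministic one makes runs and tests reproducible.
* Seeds missing from the graph are dropped with a warning — taggers
  routinely emit out-of-vocabulary concepts — and seeds in different
  components simply remain isolated nodes.
* Duplicate concepts within a sentence collapse to one seed (set
  semantics).

### Concept tagging

A dictionary tagger stands in for a full concept-mapping system:
case-insensitive longest-match-first left-to-right matching of lexicon
surfaces on token boundaries (tokens are alphanumeric runs), yielding
non-overlapping mentions with 0-based half-open character offsets. Output
from an external tagger can be supplied instead, as a TSV of
`sentence_id, start, end, matched_text, cui, preferred_name, semtypes`;
only the content of such exports (CUI, preferred name, semantic types) is
consumed, not any tool-specific serialization. The tagger makes no attempt
at word-sense disambiguation or negation handling.

### Augmentation

`augment_with_concepts()` appends, after the original sentence: the
mentions' preferred names (in mention order), then their semantic types,
space-separated, duplicates dropped keeping first occurrence. The rubric
example: "the patient was taken to the pacu in stable condition" becomes
"... stable condition postoperative anesthesia care unit (PACU) Health Care
Related Organization". The append order, single-space separator, and
deduplication are canonical choices fixed for reproducibility; augmentation
is applied exactly once per record by the pipeline (it is deliberately not
idempotent).

`reverse_pair_double()` appends a swapped copy of every record — scores and
categories preserved — an explicit hint that the task is symmetric in the
two sentences, which a joint pair encoder does not otherwise know.

### Graph encoder

A stacked GCN with the symmetric-normalized propagation rule with
self-loops,
$$H^{(l+1)} = \sigma\!\left(\tilde D^{-1/2}(A + I)\tilde D^{-1/2} H^{(l)} W^{(l)}\right),$$
with $\tilde D$ the degree matrix of $A + I$ and $\sigma$ the rectified
linear unit; defaults are 2 layers and 64-dimensional hidden and output
representations. The readout is mean pooling over nodes (size- and
permutation-invariant); the empty graph encodes to the zero vector. Node
features are initialized either

* **pretrained** — looked up in a knowledge-graph-embedding table
  (word2vec-style text file), with seeded random fallback vectors for
  out-of-table concepts (no table fully covers an ontology), or
* **random** — per-CUI seeded draws from $N(0, 1/\sqrt d)$, so a concept
  receives the same vector in every graph: node identity is preserved even
  without pretrained embeddings.

### Text encoder

The builtin desk-scale encoder is a small trainable transformer-style
model: token plus position embeddings (64-dim), two single-head
self-attention blocks with residual connections, mean pooling. The pair is
encoded jointly as one sequence `text1 <sep> text2`, so attention can
relate tokens across the sentences. With zero blocks it degrades to a bag
of embeddings. Large pretrained sentence-pair encoders plug in through an
adapter contract (`encoder_kind = "external_adapter"`, a user-supplied
callable); no checkpoints are bundled, keeping the package self-contained.
The builtin scale (64-dim, 2 blocks, max length 64) targets CPU-minute
training.

### Fusion and scoring

One graph encoder with shared weights encodes both sentences' graphs; its
two readouts $g_1, g_2$ are concatenated with the pair-level text vector
$t$ into the fused vector $[t; g_1; g_2]$. The scoring head is a
one-hidden-layer feed-forward network (relu, 64 hidden units) applied to
the fused vector augmented with the elementwise interaction features
$g_1 \odot g_2$ and $|g_1 - g_2|$.

Two design points deserve their rationale:

* **Why a feed-forward head rather than a single linear map.** The two
  graphs are encoded independently, so any pairwise-similarity signal must
  be a function of $(g_1, g_2)$ jointly; a linear map of a concatenation is
  additive in its blocks and can express no such function.
* **Why explicit interaction features.** Even a shallow nonlinear head
  learns pairwise similarity slowly from raw concatenations in a
  small-data, few-epoch regime. The product and absolute difference make
  dot-product-like and distance-like quantities linearly accessible —
  standard practice in sentence-pair models. On the synthetic benchmark, a
  linear probe over these interactions recovers the planted graph signal
  while a probe over the bare concatenation does not.

Regression happens on the raw 0–5 scale; predictions are clamped to
$[0, 5]$ only at reporting and ensembling time.

### Training

Adam with two parameter groups: the text encoder at learning rate $10^{-4}$
and the graph encoder plus head at $10^{-3}$, 4 epochs, minibatches of 16,
mean-squared-error loss. The split learning rates follow the convention of
updating a text encoder gently while letting the randomly initialized graph
side catch up. The rates and epoch count are standard tuned values for
this task family; the optimizer behind them (Adam, β = 0.9/0.999) is a
package choice. All shuffling is seeded; two runs with identical
configurations produce identical loss traces and predictions.

### Ensembling and distillation

Ensembles average member scores with equal weights *before* clamping:
averaging happens in the models' native output space, the rubric projection
is applied last (so members {1, 2, 6} average to 3.0). Member diversity
comes from varied seeds and encoder configurations — checkpoint variety in
the style of multi-source ensembles requires external weights this package
does not ship.

Knowledge distillation trains a student against the ensemble's soft labels
with the teacher-bounded regression loss
$$\ell = (s - y)^2 + \nu B, \qquad
B = \begin{cases}(s - \tau)^2 & \text{if } (s-y)^2 + m > (\tau - y)^2\\
0 & \text{otherwise,}\end{cases}$$
where $s$, $\tau$, $y$ are student, teacher and gold scores: the student is
pulled toward the teacher only while doing worse than the teacher (up to
margin $m$). Defaults $m = 0$, $\nu = 0.5$ are explicit package choices —
the loss family is inherited, its constants are not published for this
task.

### Evaluation

`pearson()` refuses to compute undefined correlations (constant vectors,
$n < 2$) rather than coercing them to 0 — silent zeros corrupt model
comparisons; per-category entries for such subsets are reported as missing.
Splits are seeded shuffles followed by prefix splits, mirroring the
1313/329 train/validation protocol of the benchmark this package targets.

## The synthetic benchmark

Real clinical STS data and terminologies are license-restricted, so the
package ships a generator whose outputs exercise every pipeline stage:

* **Ontology** — a uniformly random spanning tree (random Prüfer sequence)
  over `n_concepts = 200` concepts plus `0.3 * n` extra random edges,
  connected by construction, serialized in the RRF dialect. The extra-edge
  fraction gives a sparse cyclic graph qualitatively similar to a
  terminology's relation structure.
* **Lexicon** — 2 distinct single-token surface forms per concept plus a
  preferred name and a semantic type from a fixed small set. Synonymy is
  the crux: the two surfaces of a concept share a CUI, so the graph sees
  one node where a purely lexical model sees two unrelated tokens.
* **Embeddings** — a spectral layout of the ontology (Laplacian
  eigenvectors of the smallest nontrivial eigenvalues, diffusion-scaled),
  so graph-nearby concepts get similar vectors: a self-contained stand-in
  for pretrained knowledge-graph embeddings.
* **Pairs** — 2000 sentence pairs; each sentence renders 2–4 concepts
  (one random surface form each) interleaved with filler tokens. The
  latent similarity is $w_{lex} J + w_{graph} G$ with $J$ the Jaccard
  overlap of rendered surface tokens and $G$ the mean over cross-set
  concept pairs of $1/(1 + d)$, $d$ the shortest-path distance ($1/(1+d)$
  is bounded, monotone, and hand-computable). Gold scores are
  $\mathrm{clamp}(5 \cdot \mathrm{latent} + N(0, 0.3),\, 0,\, 5)$ with
  weights $w_{lex} = 0.3$, $w_{graph} = 0.7$: most of the signal is
  reachable only through graph proximity. Categories rotate round-robin —
  they exist to exercise the per-category evaluator, not to carry meaning.

What the generator does *not* emulate: clinical language, annotator
disagreement and bias, protected-health-information patterns, realistic
term-frequency distributions. Passing the benchmark therefore demonstrates
that the pipeline's machinery works and that the graph route recovers
signal invisible to the text route under these controlled conditions — not
that any particular score would transfer to real clinical data.

## Benchmark protocol and problem sizes

The standard benchmark run (`run_benchmark()`) splits the 2000 pairs into
1400 training / 300 validation / 300 test records, doubles the training
set by pair reversal, trains for 4 epochs, and evaluates held-out Pearson
correlations for: the full fusion model with pretrained embeddings, the
same with random initialization, the text-only ablation (graph blocks
zeroed, same architecture otherwise), and a 5-member seed-varied ensemble
of full models; three benchmark seeds are averaged. These sizes keep a full
run in CPU minutes while leaving the planted-signal ordering (pretrained >
random > text-only) clearly resolvable.

The builtin text encoder trains from scratch at learning rate $10^{-4}$
over 4 epochs, so the text route underfits by construction; the comparison
of interest is the *gap* the graph route adds under a protocol shared by
all variants, mirroring the qualitative ordering reported for the
full-scale system without claiming its magnitudes.

## Numerical choices and degenerate inputs

* Empty induced graphs encode to zero vectors; records without any tagged
  concept flow through the model on the text route alone.
* Undefined correlations error (overall) or are reported missing
  (per-category); they are never 0.
* Gradients of all trainable components are analytic and are verified
  against central finite differences in the test suite (tolerance 1e-5 at
  step 1e-5).
* `|g1 - g2|` has a subgradient of 0 at ties, the usual convention.
* Tie-breaks in shortest paths are lexicographic by CUI; node orderings in
  induced graphs are sorted, making adjacency matrices unique.
* Scores parsed from datasets must lie in $[0, 5]$; out-of-range values
  are format errors, not clamped.

## Known limitations

* The dictionary tagger has no disambiguation; ambiguous surfaces resolve
  to their first lexicon entry.
* The builtin text encoder is deliberately small and will not approach the
  quality of pretrained clinical language models; use the adapter for real
  deployments.
* Only connectivity of the terminology is used; typed or weighted
  relations, hierarchy-only views, and attention-based graph encoders are
  out of scope.
* Multi-task training and category-auxiliary objectives are not
  implemented (reported elsewhere as unhelpful for this task).
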