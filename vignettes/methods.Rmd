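---
title: "Methods: concept tokenization, shuffle-ensemble embeddings and cluster validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept tokenization, shuffle-ensemble embeddings and cluster validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A structured electronic medical record (sEMR) is a wide, heterogeneous row:
demographics, admission details, resource utilization, diagnosis and
procedure codes, medication names, and dozens to hundreds of laboratory
items — categorical and continuous values side by side, with most lab
columns missing for most patients because items are ordered per clinical
need. A one-hot/multi-hot encoding of such data is very high-dimensional,
sparse, and blind to the relations between features. `emr2vec` builds a
dense, low-dimensional patient representation instead, by borrowing the
word-embedding machinery of natural language processing.

## From record to sentence

Every feature value is discretized into a *medical concept*, written
canonically as `feature_id=value`:

* **Age** uses fixed bands `<18, 18-34, 35-44, 45-59, >=60` years; a
  boundary age belongs to the upper band, matching the band labels.
* **Laboratory items** are classified against their clinical reference
  range `(lo, hi)`: 3-class `low`/`medium`/`high` with a closed reference
  interval (`lo <= x <= hi` is `medium`), or 2-class `normal`/`abnormal`.
  The boundary convention is ours; reference intervals are conventionally
  reported inclusive.
* **Other continuous features** are cut at the cohort's 25/50/75th
  percentiles into quartile concepts `Q1..Q4`. Edges are right-closed
  (a value exactly at an edge falls low) and frozen after fitting; unseen
  out-of-range values clamp to the outer bins so the same edges can be
  re-applied to new data.
* **Categorical features** (sex, departments, diagnosis/procedure/medication
  codes) pass through verbatim.

A record becomes the *sentence* of its present concepts, one token per
present non-outcome feature, in schema order. Missing features simply emit
no token — no imputation happens on the corpus path, which is exactly how
the embedding approach absorbs missing labs. Outcome features (length of
stay, cost, death, discharge route) are never tokenized; they are held out
to evaluate the learned representations.

## Skip-gram with negative sampling

Concepts are embedded with a skip-gram model: each token predicts its
neighbors within a symmetric window of `c` positions (default `c = 5`;
`window = "max"` resolves to the longest record, so every concept sees
every other). We fit by stochastic gradient descent with negative sampling
(5 noise tokens per observed pair, unigram^0.75 noise distribution),
`d = 200` dimensions, 5 epochs, a linear learning-rate decay from 0.025 to
1e-4, and `min_count = 1` (medical vocabularies are small; nothing is
discarded by default). The estimator choice is ours: negative sampling is
the tractable standard for this model family. The window is fixed (no
random shrinking), so the `"max"` setting covers exactly all ordered
within-sentence pairs — a property the tests assert by counting pairs.

The trainer is single-threaded and bit-deterministic given its seed: a
self-contained linear-congruential RNG drives the noise sampling, so
results do not depend on the compiler's `std::` distribution
implementations.

## The shuffle ensemble

Unlike words in prose, concepts in a record are ordered by documentation
convention, not by meaning — two strongly associated concepts may sit at
opposite ends of a record and never co-occur inside a window of 5. We
therefore re-shuffle every sentence uniformly at random, train, and repeat
20 times, averaging each concept's 20 vectors elementwise.

One design point deserves emphasis, because the averaging step is otherwise
ill-posed: embeddings from independently initialized runs agree only up to
an arbitrary rotation, and averaging rotated solutions cancels toward zero.
**All 20 runs share one weight initialization** (and one noise-stream
seed); only the token order differs. The runs then stay in a common
coordinate system and their mean is meaningful. Whether the original
formulation shared initialization is unstated; this is our resolution,
recorded prominently.

The planted-block fixture (`make_planted_block_corpus()`) makes the
motivation testable: correlated tokens are laid out with 5 noise tokens
between them, so an unshuffled window-5 run cannot pair them while the
shuffle ensemble can. On 4 blocks x 10 tokens and 2,000 sentences the
ensemble recovers same-block neighbors with top-10 precision >= 0.8,
clearly above the single unshuffled run — the package's quantitative
analogue of the qualitative ordering reported for shuffled versus
unshuffled training.

A patient is the arithmetic mean of their record's concept vectors
(order-invariant by construction). Tokens missing from the vocabulary are
skipped with a warning; only a record with no known token at all is an
error.

## Reference representations

Two baselines mirror common practice: the **multi-hot** vector (bitwise OR
of the one-hot codes of a record's concepts) and the **mixture** vector (a
multi-hot block for discrete features concatenated with raw continuous
values for age and the retained lab panel). The panel keeps labs observed
in at least 90% of cohort records; sparser labs are dropped because raw
columns cannot carry that much missingness, and remaining gaps are filled
with the per-lab cohort median. The continuous block is z-scored by default
before cosine distance — with raw scales a single high-magnitude lab would
dominate — and the flag is recorded in the object so the raw variant
remains available.

## Clustering and validity

Distances follow representation type: cosine for embedding vectors, Jaccard
for multi-hot, and their sum (Jaccard on the discrete block plus cosine
distance on the continuous block, weights 1 and 1, configurable) for the
mixture. "k-means" is realized per geometry: spherical k-means for cosine
(unit-normalized points, renormalized mean centroids, best of 10 seeded
restarts, 300-iteration cap, relative tolerance 1e-4, empty clusters
reseeded from the farthest point) and PAM k-medoids for Jaccard/mixed,
where Lloyd means are undefined; PAM's build+swap is deterministic, so
restarts are unnecessary there.

Validity indices:

* **Hopkins statistic** `H = sum(u) / (sum(u) + sum(w))`, with `m =
  min(0.1 n, 100)` pseudo-points sampled uniformly in the per-dimension
  bounding box. `H ~ 0.5` signals spatial uniformity (the uniform-random
  null), values near 1 a clusterable structure. Note a regular lattice
  scores *below* 0.5 — real-point spacing is maximal there — so the null
  calibration test uses uniformly random points.
* **Silhouette index**, mean of `(b - a)/max(a, b)` over points, computed
  from the full distance matrix of whichever distance the representation
  uses. Conventions (ours; commonly used): singleton clusters score 0, and
  `a = b = 0` scores 0.
* **Davies-Bouldin index**, with cluster centers kept internal to the
  distance space: centroids for the k-means paths, medoids for the
  k-medoids paths. The index is unbounded above and is reported unclamped.

The number of clusters is chosen by the silhouette over `k = 2..15`, ties
to the smaller k. External evaluation maps each cluster to its majority
true label and reports per-label precision, recall and F1; a label that no
cluster claims gets recall 0 and precision reported as 0 with a warning.
All three indices are verified against exhaustive brute-force
implementations on small random instances for every distance kind, and the
silhouette additionally against `cluster::silhouette`.

## The synthetic cohort

`generate_cohort()` plants the structure the method is meant to find: two
latent disease classes mixed 83/17 (a majority ischemic-stroke-like class
and a minority hemorrhagic-stroke-like class), ~400 diagnosis, 80
procedure and 120 medication concepts of which a subset per class is
*signature* (prevalence drawn from U(0.15, 0.55) in its own class, 4% of
that in the other) and the rest shared low-prevalence background; 60
laboratory items with randomly drawn reference ranges, class-shifted means
for 15 discriminative items, and 8% missing-at-random gaps (~92% coverage,
so a 90% panel threshold keeps most items); class-dependent resource
features (ventilator, ICU) with rates echoing published cluster contrasts;
and class-dependent outcomes excluded from the corpus. One master seed
drives named substreams (classes, each concept panel, labs, missingness,
outcomes), so cohorts are byte-identical given the seed and individual
components are independently reproducible.

What the generator does *not* emulate: code hierarchies and their
semantics, comorbidity correlation structure beyond class-conditional
independence, informative (non-random) lab missingness, temporal visit
sequences, and documentation idiosyncrasies. Passing tests therefore show
that the pipeline recovers planted class structure under realistic shapes
and missingness — not that it reproduces any particular hospital's numbers,
which depend on private data.

## Problem sizes and numerical choices

Desk-scale defaults are chosen so a full run finishes in minutes on one
core: the end-to-end evaluation in the tests and the acceptance script uses
n = 2,000 patients (the generator default is 8,000), d = 200, 20 shuffles,
5 epochs; the planted-block fixture uses 2,000 sentences. Quartile edges
use the standard type-7 sample quantiles. Neighbor rankings break exact
ties lexicographically by token so reports are stable. Degenerate inputs
fail loudly rather than silently: constant columns cannot be quartiled,
zero vectors have no cosine, two empty sets have no Jaccard distance,
identical points have no Hopkins statistic, and coincident cluster centers
make the Davies-Bouldin ratio undefined.

## Known limitations

Single-admission records only (no longitudinal modeling); equal-weight
averaging of concept vectors into patient vectors; the category taxonomy
for neighbor reports is user-supplied (code-grouping dictionaries are
licensed data); and the 2-D projection of embeddings is exported for an
external backend rather than computed here.
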