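---
title: "Quantifying similarity among biomedical entities from their literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying similarity among biomedical entities from their literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litsim)
```

## The model

`litsim` rests on a single assumption: biomedical entities that are similar
or related share more frequently co-occurring words and scientific terms in
their text sources than unrelated entities do. The package therefore
represents each entity not by an embedding but by an explicit, inspectable
vocabulary — the set of its `n_top` most frequent terms — and measures
similarity between entities as overlap between these sets. This keeps every
step auditable: when two genes cluster together you can read off exactly
which shared terms put them there (`top_terms_per_cluster()`), which is not
possible with dense text embeddings.

Formally, entity $e$ is reduced to a binary vector $x_e \in \{0,1\}^T$ over
the union vocabulary $T$, with $x_{et} = 1$ iff $t$ is among the $N$ most
frequent terms of $e$'s collected texts. Similarity is Jaccard:
$d(e, f) = 1 - |x_e \cap x_f| / |x_e \cup x_f|$. Clusters come from
agglomerative hierarchical clustering of $d$ (Ward linkage on the
squared-distance convention), cut at $k$ clusters. Agreement with an
external grouping variable $g$ (e.g. expert-curated disease categories) is
the adjusted Rand index between the cut and $g$: a pair-counting statistic
with expectation 0 under random agreement and maximum 1, invariant to label
renaming.

## Two vocabularies

The **word pipeline** (`text_to_wordmatrix()`) counts raw token occurrences
over all of an entity's texts after quality control. The **concept
pipeline** (`pmids_to_pubtator_matrix()`) instead counts pre-computed
PubTator annotations of biomedical concepts. Two deliberate asymmetries:

* Words are counted by raw occurrence; concepts by per-document presence
  (a concept mentioned five times in one abstract counts once). Concept
  taggers annotate every mention, so raw mention counts would be dominated
  by within-abstract repetition rather than by breadth of support across
  the literature.
* Concepts are normalized to `category:identifier` by default
  (`by_id = TRUE`), merging synonymous surface forms of one concept;
  annotations that the tagger could not ground to an identifier fall back
  to their lowercased mention text. Mention-level normalization
  (`by_id = FALSE`) is available when synonym merging is undesirable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_top` | 50 terms/entity | vocabulary size per entity; larger values add lower-frequency (noisier) terms, smaller ones make profiles brittle |
| `min_token_length` | 3 characters | drops acronym fragments and residue of digit stripping |
| `stopwords` | Snowball English list | extendable via `extra_stopwords` |
| `strip_digits` | on (strip characters) | `"scn1a"` becomes `"scna"` instead of being dropped; `drop_digit_tokens` switches to whole-token dropping |
| `stem` | off | Porter stemming, applied before counting so ranks reflect stems |
| `exclude_self` | on | tokens of the entity's own identifier/query are removed: an entity's name trivially tops its own frequency list and carries no similarity signal |
| `metric` | jaccard | euclidean available; jaccard is the natural choice for presence/absence profiles |
| `linkage` | ward (`ward.D2`) | average/complete available |
| `k` | `"auto"` | number of distinct grouping labels when a grouping is supplied (mirroring validation against expert categories); otherwise the silhouette-maximizing cut over 2..min(10, n−1), ties to the smallest k |

Retrieval defaults: abstracts are fetched in batches of 200 PMIDs,
annotations in batches of 100; the live transport obeys the NCBI rate limit
(3 req/s without an API key, 10 with one) with three exponential-backoff
retries. The article title is prepended to the abstract body by default
(titles are term-dense); `include_title = FALSE` / `--no-title` disables
this.

## The synthetic corpus

`generate_corpus()` emulates the structure the method is designed to
detect: `k_topics` latent topics with pairwise disjoint characteristic
vocabularies plus a shared noise vocabulary disjoint from all of them.
Every entity belongs to one topic; each of its documents draws
`words_per_doc` words i.i.d. — from the shared vocabulary with probability
`noise_fraction`, otherwise uniformly from the topic vocabulary. Synthetic
words are pronounceable letter-only tokens of six characters, screened
against the stopword list, so default tokenization passes them through
unchanged and the generator composes cleanly with the word pipeline.

The default conditions (4 topics × 10 entities, topic vocabularies of 30
words, 100 shared words, 20 documents of 50 words per entity, 30% noise)
give strong but not degenerate separation: about 70% of each entity's
tokens are topic words, so its top-50 list contains the full topic
vocabulary plus a random sample of shared words. `recovery_experiment()`
runs the full pipeline on such a corpus and returns the ARI against the
planted topics; at the defaults it recovers them essentially perfectly,
while `noise_fraction = 1` (no topic signal) yields |ARI| near 0.

What the generator deliberately does **not** emulate: Zipfian word
frequencies, synonymy and polysemy, correlated topics, citation structure,
varying abstract lengths, and entities with little or no literature. A
perfect recovery score on synthetic corpora therefore demonstrates the
pipeline's internal correctness — counting, selection, matrix assembly,
clustering and scoring — not performance on real PubMed text, where topic
vocabularies overlap heavily and signal-to-noise varies by entity. Word
draws are uniform rather than Zipfian by design: it is the simplest model
satisfying the co-occurrence assumption, and frequency ranks under uniform
draws are maximally sensitive to implementation errors in counting and
tie-breaking.

## Numerical choices and degenerate inputs

* **Ties** in frequency ranking (term selection and per-cluster summaries)
  break lexicographically, making every ranking deterministic.
* **All-zero rows** (entities with no usable vocabulary) are kept, flagged
  `ALL_ZERO` in `labels.tsv`, never dropped — dropping them would
  desynchronize partitions from the input table. The Jaccard distance
  between two all-zero rows is defined as 0.
* **ARI degenerate cases**: when both partitions are all singletons or both
  are a single cluster the pair-counting denominator vanishes; the value is
  defined as 1 (the partitions are identical).
* **`k = n` k-means** returns the exact optimum (all singletons, inertia
  0) directly.
* **t-SNE** validates `3 · perplexity ≤ n − 1` and suggests the largest
  admissible perplexity in the error; the default is
  `min(30, (n − 2)/3)`.
* **Determinism**: PCA is exact and deterministic; t-SNE, UMAP, k-means and
  the corpus generator are seeded and reproduce bit-for-bit, and a report
  directory produced twice from the same inputs is file-identical.
* The Porter stemmer is implemented in the package from the reference
  algorithm and validated against canonical stem pairs.

## Design decisions

The TSV column dialect (`ID`, grouping columns, `QUERY`,
`PMID_1..PMID_n`, `ABSTRACT_1..ABSTRACT_n`) lets the pipeline stages chain
through flat files, so each stage is independently runnable and cacheable;
empty cells inside `PMID_n`/`ABSTRACT_n` runs are skipped because entities
legitimately differ in literature depth. PMIDs are kept as strings
throughout. `populate_by_queries(mode = "abstracts")` records the searched
PMIDs as well as the abstracts, since the concept pipeline needs PMIDs and
re-searching would be wasteful. PMIDs without abstracts are dropped with a
logged skip rather than an error — they are common among older records.
The interactive exploration step is replaced by static, testable artifacts
(label/embedding/term tables and plots); every analysis that the
interactive view would support is available programmatically.

## Problem sizes

The bundled tests and the acceptance script run entirely offline at desk
scale: corpora of 12–40 entities with 5–20 documents each, 200-pair ARI
oracle checks, 1000-shuffle calibration, and 20-corpus null experiments.
These sizes were chosen so the full pipeline — including t-SNE and UMAP
determinism checks — exercises every code path in seconds while remaining
statistically meaningful (the calibration bounds are far tighter than the
Monte-Carlo noise at these sizes would forgive if the implementation were
biased).

## Known limitations

Live retrieval quality depends on PubMed query craft and on PubTator
coverage; both services evolve, so live results are not frozen-in-time
reproducible (fixture transports are, and are the basis of all tests).
The word pipeline is monolingual English and unigram-only — no n-grams,
no TF-IDF weighting, no embeddings, by design. Species-aware gene
disambiguation and full-text (PMC) retrieval are out of scope.
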