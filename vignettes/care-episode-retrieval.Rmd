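---
title: "Semantic models for care-episode retrieval: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic models for care-episode retrieval: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiretrieve)
```

This vignette documents the models implemented by **epiretrieve**, the
assumptions behind them, the parameters that matter, and the design choices
made where several reasonable options existed. It also explains what the
synthetic corpus generator does and does not emulate, and therefore what a
passing test suite does and does not say about real clinical data.

## The task

A *care episode* is the ordered sequence of free-text clinical notes
documenting one hospital stay, usually concluded by a discharge summary and
labelled with one primary ICD-10 diagnosis code. The retrieval task: given
one episode as a query, rank a collection of episodes so that episodes
documenting a similar course of care come first. Queries are constructed
without the discharge summary (it does not exist yet for an ongoing
episode) and with any sentence mentioning an ICD-10 code in free text
removed, so the ranking must work from the clinical narrative itself.

Because human relevance judgments for this task are prohibitively
expensive, two automatic proxies stand in for relevance: identity of the
primary ICD-10 code (protocol 1), and overlap with the top-*n* most similar
discharge summaries (protocol 2). Both are imperfect — same-code episodes
can differ in course, different-code episodes can resemble each other — and
the package treats them as *proxies*, reporting MAP, P@k, R-precision and
retrieved-relevant counts under each.

## Semantic models

All six models produce a `word → vector` map of fixed dimensionality
(default 800, the standard choice at which random projections of
desk-to-hospital-scale vocabularies stay near-orthogonal).

### Random indexing

Random indexing assigns every entity a sparse ternary *index vector* —
here 4 nonzero entries, two +1 and two −1, at seeded-hash-determined
coordinates, so vectors are reproducible functions of (key, seed) and no
table needs storing. Context vectors are plain sums of index vectors, which
makes every trainer *incremental*: training on a concatenated corpus equals
the entrywise sum of training on its parts, and the result is independent
of note order. The tests assert both properties at relative tolerance
1e-9 (floating-point summation order is the only source of discrepancy).

* **ri-word** sums the index vectors of window neighbours (5 left + 5
  right), weighted `b^(1-d)` with base 2 in the distance `d`, and rotated
  one coordinate left or right according to the side the neighbour is on
  ("direction vectors"). Two choices were open: windows do **not** cross
  sentence boundaries (the corpus is sentence-split; confining context to
  the sentence is the deterministic, conventional reading), and the focus
  word is excluded from its own context sum. Distance weighting applies to
  this trainer only.
* **ri-note** adds the note's index vector once per token occurrence;
  multiplicity counts.
* **ri-icd** adds the index vectors of the episode's primary code and all
  its taxonomy ancestors, weight 1.0 at the full code and halved per step
  up (J21.1, J21, J2, J at 1.0, 0.5, 0.25, 0.125). A code contributes one
  level per character, the decimal point not being a level; codes without
  a decimal (e.g. I50) have three levels anchored at weight 1.0 for the
  full code. Notes of uncoded episodes are skipped and counted; an
  entirely uncoded corpus is an error.
* **ri-index** uses the index vectors themselves — an exact-match
  bag-of-words model under a random projection, useful as the bridge
  between the distributional models and the TF-IDF baseline (their episode
  cosines correlate above 0.9 when similarity spread dominates the
  projection noise of sd ≈ 0.03 at 4 nonzeros / 800 dims).

### word2vec

**w2v** is CBOW with hierarchical soft-max: the averaged context-word
input vectors are trained to predict the focus word's Huffman path by
logistic updates. "Default parameters" are pinned to window 5, 5 epochs,
initial learning rate 0.025 with linear decay to a floor of 1e-4, no
subsampling, no negative sampling, minimum count 1 — the published
defaults of the original tool for everything its description leaves open.
The Huffman tree breaks frequency ties by lexicographic leaf order, making
training fully deterministic; the single-threaded reference path is
bit-stable for a fixed seed. Input vectors initialize uniformly in
(−0.5/dim, +0.5/dim), internal-node weights at zero.

**w2v-icd** keeps the input and hidden layers but replaces the prediction
task: every token of a coded note is trained against every taxonomy
segment of the note's primary code, the gradient scaled by the segment's
1/0.5/0.25/0.125 weight, so a zero-weight segment provably changes no
parameters. The hierarchical soft-max layer is induced over the segment
vocabulary exactly as for words; segment frequencies are token-weighted
pair counts (one count per training pair containing the segment) — a
note-level alternative was considered and left as a non-default. It trains
for 10 epochs with learning rate decaying linearly from 0.04; the floor,
unspecified in the method's description, is 1e-4. Segments iterate
general→specific within a pair; the order is immaterial in expectation and
fixed for determinism.

## Word weighting

Retrieval-ready vectors are `unit-normalized context vector × idf × boost`
with idf(w) = ln(N/df(w)) counted over clinical notes (documents = notes,
not episodes, so within-episode repetition does not deflate weights). The
natural-log Robertson form is the package's choice where the formula was
open; `log(1 + N/df)` is available as a config switch. Words present in a
metathesaurus term list get their IDF doubled (boost 2, configurable).
Weighting is applied once; re-weighting a weighted model is rejected via a
provenance check, because normalization is not idempotent over idf scaling.

## Episode similarity

Note vectors are raw sums of weighted word vectors over token occurrences
(no division — cosine makes scale irrelevant, and repeated words should
count); episode vectors divide by the occurrence count, which again cancels
in cosine. Cosine is defined as 0 when either vector is zero; an episode
with no in-vocabulary token has *undefined* similarity and ranks last.

* **single** — cosine of pooled episode vectors.
* **avg** — mean cosine over all |A|×|B| note pairs.
* **ha** — maximum-weight one-to-one assignment on the note-cosine matrix
  (Hungarian algorithm, via `clue::solve_LSAP`), scored
  `2·Σ paired cosines / (|A| + |B|)`. The fixed denominator penalizes
  length mismatch. Note pairs with non-positive cosine are left unmatched:
  they can only lower the score, and leaving them out realizes the same
  "zero or one partners" semantics as the alignment's zero-cost gaps —
  and guarantees the alignment score can never exceed the assignment
  score, since monotone partial matchings are a subset of partial
  matchings.
* **nw** — global order-preserving alignment (Needleman–Wunsch) with match
  score = cosine and gap contribution 0 (no extra parameter; negative
  pairs are then never aligned), scored by the same formula over the
  aligned pairs. The raw DP total is deliberately *not* used as the
  episode score.

Ties among equally optimal pairings are broken arbitrarily; the score is
the contract, the pairing is informational. Both scores are validated
against brute-force enumeration of all pairings / all monotone alignments
on hundreds of random episode pairs.

## Evaluation protocols

Queries are sampled seeded among coded episodes with ≥ `min_notes`
clinical notes, pairwise-distinct primary codes, and a non-empty relevance
set; the query is excluded from its own candidate pool. Protocol 1 ranks
the full collection; protocol 2 truncates at `limit` (default 1000),
builds per-model relevance sets from the top-`top_n` (default 100) most
summary-similar episodes, and evaluates every ranker against every
relevance construction. Summaries are excluded from query and
retrieval-side text in protocol 2 — they only define relevance — and the
gold construction for a weighted model uses the same weighting as the
ranker under test. Matched ranker/relevance cells are biased upward; the
cross-design's off-diagonal averages are the less biased estimate, and the
package reports per-row means and ranks. No significance procedures are
applied; raw means are reported.

The TF-IDF baseline is an exact sparse vector-space ranker over
concatenated episode text (same note-level IDF), standing in for a search
engine; the random baseline is a seeded permutation whose P@k matches the
binomial expectation.

## The synthetic corpus generator

Real coded clinical corpora cannot be shared, so the generator produces
structurally analogous data: episodes of 5–10 notes (the last a summary),
one primary code from a synthetic hierarchy (chapter letter → two-digit
category → decimal sub-code), and note text mixing code-specific topic
lexicons with a Zipf-distributed background vocabulary (exponent 1.1 over
2000 words) plus a small closed stopword set. Key levers:

* `lambda` (default 0.7) — probability a non-stopword token is topical;
  at 0 code identity is unrecoverable by construction, at 1 every content
  token is topical.
* Ancestor mixing — topic tokens come from the code's own lexicon, its
  category's, or its chapter's with weights 1 : 0.5 : 0.25, mirroring the
  taxonomy halving, so sibling codes share graded lexical signal and the
  supervised models' taxonomy gradient is testable by construction.
* `active_topic_words` (default 8 of 40 per node) — each episode activates
  its own random lexicon subset, emulating patients presenting different
  subsets of a diagnosis's symptom vocabulary. Without this, same-code
  episodes share so many exact words that every model (including plain
  TF-IDF) retrieves perfectly and model differences vanish; with it,
  exact-match models degrade while models that generalize across related
  words keep their edge.
* Summaries resample the episode's own earlier topic draws (share 0.8)
  rather than copying notes verbatim, so summary-overlap relevance sets
  are non-trivial.
* Notes mention their code in free text with probability 0.15, exercising
  the ICD-sentence stripping in query construction.
* The emitted metathesaurus is exactly the topic lexicon by default
  (`thesaurus_fraction = 1`), matching the idea of a curated domain
  vocabulary; partial coverage is configurable.

All randomness flows from one seed; generation is byte-identical per seed.

What the generator does **not** emulate: morphology and lemmatization
noise (tokens are already clean lemmas; the original setting used an
external morphological analyzer), clinically plausible narrative,
secondary diagnoses, ward transfers, timestamps, negation, misspellings,
and realistic vocabulary sizes. Passing tests therefore demonstrate that
the algorithms implement their definitions and that the expected *relative*
behaviours hold under controlled signal (supervision beats co-occurrence;
boosting genuinely topical terms does not hurt; matched ranker/relevance
pairs are biased upward). They do not predict absolute scores on real
clinical text, where signal is far weaker and noisier.

## Numerical and scale choices

Benchmarks in the tests run at the generator's default scale — 10 codes
across 3 chapters, 20 episodes per code, ~45k tokens — with 10 queries per
protocol run (one per code: queries must carry distinct codes, so a
10-code corpus admits at most 10). Ten-seed repetitions back the
statistical claims. Degenerate inputs are defined rather than special-cased
where possible: empty corpora give empty RI models (word2vec, needing a
vocabulary, errors), zero vectors give cosine 0, undefined similarities
rank last, ranking ties break by ascending episode id so orderings are
permutation-invariant, and a single-leaf Huffman tree gets one forced
branch. Index-vector hashing uses a 31-bit polynomial string hash; at
desk-scale vocabularies the collision probability is negligible, and a
collision merely makes two words share a signature.
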