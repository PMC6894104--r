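---
title: "De-identifying clinical notes with a feature-augmented BiLSTM-CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying clinical notes with a feature-augmented BiLSTM-CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deidtag)
```

## The problem

Clinical notes carry Protected Health Information (PHI) — names, dates,
phone numbers, identifiers, addresses — that must be removed before the
text can be shared for research. `deidtag` approaches de-identification as
a sequence-labeling task: notes are tokenized, each token is tagged in the
BIO scheme over ten harmonized PHI categories (`DATE`, `NAME`, `AGE`, `ID`,
`PHONE`, `WEB`, `INSTITUTE`, `STREET`, `CITY`, `ZIP`), and tagged runs are
converted back to character-offset spans that can be masked or surrogated.

The package's particular concern is the *cross-institute* setting: a tagger
trained on one institution's notes loses accuracy on another's, because
surface formats (date, phone and identifier conventions), vocabularies and
phrasing shift between sites. Two customization strategies are built in:
retraining from scratch on the merged corpora, and *fine-tuning* — continuing
training from the source-site model's weights on the target-site corpus,
which re-uses the pretrained parameters and costs half the epochs.

## The model

The tagger is a bidirectional LSTM-CRF. Per token, the input vector
concatenates

* a word embedding (default 300 dimensions; either learned from the corpus
  or initialized from a pretrained word2vec/fastText text file and
  fine-tuned),
* a character-level encoding: the two final states of a bidirectional LSTM
  over the token's characters (25-dim embeddings, 25 units per direction),
* one embedding per categorical feature stream — part-of-speech and word
  shape as 15-dim *lexical* streams, and the knowledge-lookup triple
  (category, match boundary, match condition) as a 20-dim *semantic*
  stream.

With the default dimensions the word-LSTM input is
`300 + 2×25 + 20 + 15 + 15 = 400` wide (350 with the feature layer
disabled; `input_width()` reports the arithmetic). A bidirectional word
LSTM (100 units per direction) feeds a linear layer producing per-tag
scores, and a linear-chain CRF with learned transition and start/stop
scores models the tag sequence jointly. Decoding is exact Viterbi; exact
score ties resolve to the lexicographically smallest tag-index path so
decoding is fully deterministic.

Training follows the published recipe exactly: per-sentence stochastic
gradient descent with learning rate 0.005 and momentum 0.9, element-wise
gradient clipping to [−5, 5], dropout 0.5 on the word-LSTM input during
training only, 30 epochs from scratch, 15 epochs for fine-tuning, and no
early stopping. All of it is seeded and reproducible. The forward/backward
passes are written in C++ (RcppArmadillo); gradients are verified against
finite differences in the test suite, and the CRF likelihood, its
normalization and Viterbi decoding are verified against exhaustive path
enumeration on small instances.

Design points the architecture description leaves open were fixed as
follows:

* **Mini-batching** — one sentence per update (pure SGD), the literal
  reading of stochastic gradient descent; it also keeps determinism
  trivial.
* **Initialization** — fan-scaled uniform draws from the run seed;
  forget-gate biases start at 1.
* **Momentum on embeddings** — velocity advances only when a row is
  touched (the usual sparse-SGD convention).
* **CRF transitions** — unconstrained; a grammatically invalid decode
  (an orphan `I-` tag) is repaired downstream by promotion to `B-`, the
  same tolerant rule applied when reading third-party CoNLL files.
* **Knowledge-stream wiring** — the lookup triple is embedded as one
  composite 20-dim stream by default (`kb_wiring = "separate"` splits
  category from boundary+condition).
* **Character vocabulary** — training-corpus characters plus printable
  ASCII, with a reserved unknown slot; unseen words fall back from exact
  form to case-folded form to the `UNKNOWN` vector, the replacement used
  for every out-of-vocabulary token at prediction time.

## Pre-processing with offset provenance

Clinical text is messy; the pipeline's contract is that every downstream
artifact lives in *original-text coordinates* so annotations never drift.

* **Run-together words** (`"prnInsulin"`) are repaired by inserting a space
  at a lowercase-to-uppercase transition when both flanking alphabetic runs
  have length ≥ 2 and at least one, case-folded, is in a configurable
  known-word lexicon. Because the only edit is space insertion, the
  returned offset map is piecewise monotone and every token of the
  corrected text maps to an identical slice of the original.
* **Sentences** end at newlines (headers, list items) or at `.?!` followed
  by whitespace and an uppercase letter or digit — except after a single
  capital letter, so initials (`"J. Smith"`) do not fragment a name.
* **Tokens** are maximal letter runs, maximal digit runs, or single marks.
  The aggressive splitting is deliberate: phones, dates and IDs are
  punctuation-laced, and finer tokens give the CRF clean boundaries.
* **Span ↔ BIO conversion** snaps a span edge that falls inside a token to
  the whole token: a de-identifier should over-mask, never under-mask.

## Features

`pos_tag()` is a small deterministic rule-and-lexicon tagger over a fixed
Penn-style tagset (closed-class lexicon, digit and punctuation rules,
suffix heuristics, capitalized → proper noun, `NN` default). It trades
accuracy for exact reproducibility and zero dependencies; the feature
embedding learns from whatever consistent signal the tags carry.

`word_shape()` maps uppercase/lowercase/digit characters to `A`/`a`/`0`
and emits `"full|collapsed"` composites (`"Smith"` → `"Aaaaa|Aa"`).

`fuzzy_lookup()` scans for longest leftmost gazetteer matches. `EXACT`
means case-insensitive equality of every aligned word. `PARTIAL` covers two
situations: a token within Damerau–Levenshtein distance 1 of the entry word
(only for tokens of length ≥ 5 and never for digit strings — edit distance
on zip codes invites false matches), or an exact strict prefix covering at
least half the words of a multi-word entry. Competing matches resolve by
length, then `EXACT` over `PARTIAL`, then dictionary priority rank. Matched
runs carry the dictionary's category with B/I boundaries; everything else
is `NONE/O/NONE`, so removing all dictionaries degrades the feature layer
gracefully.

## Evaluation

`match_spans()` counts per-category true/false positives and negatives.
*Strict* credit requires identical offsets and category; *relax* credit
requires at least one character of overlap with the same category.
Matching is one-to-one and computed as an exact maximum bipartite matching
(augmenting paths, gold processed left-to-right with largest-overlap
preference), so the counts equal the optimal assignment; a greedy
largest-overlap scan can drop a feasible pair in rare configurations, and
the test suite checks optimality against brute-force enumeration.
Micro-averaged precision/recall/F1 pool counts over categories before
dividing, with the `0/0 → 0` convention for degenerate cases (a category
with nothing detected scores 0, not NA). Whether overlapping spans of
*different* categories should earn relax credit is a genuinely open
convention; the stricter same-category reading is used, which can only
understate relax scores.

`classify_errors()` sorts every non-correct span into exactly one of four
classes — boundary mismatch (same category, overlapping, offsets differ),
wrong category (overlapping, categories differ), false positive, false
negative — preferring same-category pairings so a shifted boundary is not
misread as two unrelated errors.

## The synthetic corpus generator

Real de-identification corpora cannot be redistributed, so the package
ships a seeded generator of surrogate notes that exercises every pipeline
stage, including the cross-institute experiment. Each note is a plausible
skeleton — a note-type header line and one sentence per line — whose PHI
slots are filled from an institution *style profile*. Every filled slot is
recorded as a gold span, and generation is byte-identical for a fixed
configuration.

Choices and what they emulate:

* **Category mix** — each slot's category is drawn from weights
  proportional to the single-site totals of `phi_category_counts()`
  (dates ≈ 58%, names ≈ 24%, … , WEB < 0.1%), so rare categories stay
  realistically rare.
* **Note types** — dominated by progress notes, radiology reports and
  history & physical, the three most common types in the reference
  distribution.
* **Two sites** — `site_A` and `site_B` share no date/phone/ID surface
  formats, use disjoint name/city/street/institute vocabularies, and
  phrase their carrier sentences differently; this is the distribution
  shift the cross-institute experiment measures.
* **Note size** — around ten body sentences per note with a 0.7
  probability that a sentence carries one PHI slot (roughly seven
  annotations per note), chosen to keep the bundled experiments tractable
  on one CPU.
* **Typos** — at a configurable rate, inter-word spaces (outside PHI
  spans) are deleted to emulate run-together errors; annotations are
  shifted accordingly and remain exact.

What the generator does *not* model — free narrative, misspelled PHI
values, annotation noise, inter-annotator ambiguity, genuinely out-of-
vocabulary names — bounds what the bundled experiments can show. Template
slots with deterministic context are far easier than real notes: the
within-site scores saturate near 1.0, and no conclusion about absolute
real-data accuracy should be drawn from them. The *qualitative* pattern is
the point: a sharp zero-shot drop across sites, recovered by merging or
fine-tuning, with fine-tuning at least matching target-only training.

## Bundled experiments and problem sizes

The test suite and `scripts/acceptance.R` run the full study design at
reduced scale, the package's own choice for desk-scale reproducibility:
embedding/LSTM dimensions 25/8/8/16 (word/char/char-LSTM/word-LSTM per
direction), feature dimensions 8 and 6; 250 site-A notes (200 train, 50
held out) and 110 site-B notes (60 train, 50 held out); three seeds, with
medians reported. From-scratch training still runs 30 epochs and
fine-tuning 15, the published schedule. The CRF oracle uses 200 random
instances with at most 4 tokens and 5 tags at tolerance 1e-6; round-trips
use 500 generated documents.

## Numerical and degenerate-input conventions

* Offsets are 0-based and half-open everywhere; `substr0()` is the slicing
  convention.
* CRF computations use log-space forward/backward with max-shifted
  `logsumexp`; likelihoods are exactly ≤ 0 and path probabilities sum to 1
  within 1e-6 on enumerable instances.
* Viterbi ties break toward the smallest tag-index path.
* Empty documents predict empty span sets; an empty training corpus is an
  error; a non-finite training loss aborts with a diagnostic rather than
  continuing silently.
* Duplicate tokens in a vector file keep their first row; a declared
  header count that disagrees with the file is an error, not a warning.

## Known limitations

The rule-based POS tagger is crude compared to a trained tagger, and the
typo-repair rule only addresses missing spaces at case transitions — both
are configurable surfaces, not claims about optimality. The generator's
regularity overstates learnability, as discussed above. Training is
single-threaded by design (determinism over speed); the published 300-dim
configuration on a real corpus is hours of CPU time, which is why the
bundled experiments use reduced dimensions.
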