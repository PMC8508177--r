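---
title: "Detecting statements of ignorance: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting statements of ignorance: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ignoranceNLP)
```

This vignette records how the package models statements of ignorance, the
conventions every module assumes, and the reasoning behind the design
choices that were genuinely open. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The task

A *statement of ignorance* is a sentence asserting that scientific
knowledge is missing, incomplete, uncertain or contested. The unit of
annotation is twofold: the *subject* — the full sentence — and one or more
*lexical cues* inside it, each mapped to a knowledge-goal category in a
two-level taxonomy (5 broad, 13 narrow categories). Cues may be
discontinuous ("no … exist"), and some cue surfaces are ambiguous between
categories ("challenge", "if so", "imply"); the dictionary records all
memberships and leaves disambiguation to context, human or model.

Two of the categories — *question answered by this work* and
*anomaly/curious finding* — act at both levels of the hierarchy. They are
stored once, as narrow categories whose parent is themselves; the level
counters treat them as both broad and narrow, which avoids double counting
in corpus statistics.

## Text model and normative conventions

All offsets are 0-based, half-open character offsets into the
LF-normalized document text (CRLF is rewritten before any offset is
computed). These conventions are *normative*: the cue dictionary, the
matcher, the tag codec and all annotation I/O assume them, so they are
fixed rather than configurable.

* **Tokenization.** Tokens are maximal runs of alphanumeric characters or
  maximal runs of non-space punctuation (`"unknown?"` →
  `"unknown"`, `"?"`). This mirrors word-punctuation tokenizers commonly
  used for this task and makes `?` — a listed explicit-question cue — a
  well-defined single-token pattern.
* **Sentence segmentation** is rule-based and deterministic: boundaries at
  newlines and after `. ! ?` followed by whitespace and an uppercase
  letter or digit, guarded by a fixed abbreviation list (`et al.`,
  `Fig.`, `i.e.`, `e.g.`, `vs.`, …). A trained segmenter would be more
  accurate on real articles but would make every downstream offset depend
  on a model version; determinism was judged more valuable for a corpus
  tool. Consequently sentence counts on real articles may differ from
  those produced by other pipelines.

## Dictionary pre-annotation

The matcher compiles the dictionary into token-level patterns
(case-insensitive). Within each sentence:

* at every start token, the **longest contiguous** cue wins (so "need to
  be" suppresses "need" at the same position), while overlapping matches
  of *distinct* cues are all reported — pre-annotation is meant to show
  annotators every candidate;
* a **discontinuous** cue matches when its fragments occur in order within
  one sentence with every gap at most `gap_limit` tokens (default 10).
  The reported placement is the lexicographically earliest valid one,
  found by depth-first search, which makes the matcher's output equal to
  an exhaustive enumeration oracle;
* matches never cross sentence boundaries, because the subject of a cue
  is defined as its sentence.

Pre-annotation never filters negative contexts: "although yin and yang
are contradictory in nature…" still gets its `contradictory` mark.
Deciding that a marked cue does *not* signal ignorance is the job of the
human annotator or the sentence classifier. Morphological variants
(plurals, inflections) are deliberately not matched; they are a known
error source surfaced separately by novel-cue discovery.

## The B/I/O/O- codec

Word-level models are trained on per-token tags: `B` for the first token
of a cue, `I` for further cue tokens, `O` outside, and `O-` for tokens
inside the gap of a discontinuous cue. Two points are under-determined by
that scheme and fixed here:

* tokens of the second and later fragments of a discontinuous cue are
  tagged `I` (the consistent completion of "combine `B`, `I` and `O-`");
* under the category-suffixed scheme, `O-` is *not* suffixed — gap tokens
  are not cue words.

Decoding is **total**: orphan `I` is repaired to `B`, a dangling `O-` is
demoted to `O`, and a category-suffix change inside a run opens a new
annotation. Repairs are counted and returned, since malformed sequences
from a statistical tagger are diagnostic information. For the binary
scheme, decoding necessarily returns category-less annotations, so the
round-trip identity holds on spans (and additionally on categories under
the per-category scheme). One token cannot serve two categories in one
sequence; overlapping cross-category gold is handled by encoding separate
per-category sequences, matching the 13-tagger design.

## Sentence classifiers

Features are raw token counts over a vocabulary built from the *training*
sentences only (lowercased; punctuation-run tokens removed; out-of-vocabulary
test tokens dropped). Splits are stratified 90:10 with per-class counts
preserved to within one example; balancing downsamples the majority class
to the minority size, without replacement, leaving the minority multiset
untouched. All of it is deterministic given the seed.

Two model kinds ship:

* `feedforward_1hidden` — one hidden layer of width 50 (rectified-linear
  units), sigmoid output, cross-entropy loss, trained by minibatch Adam
  with the configured `epochs` (default 8, the midpoint of the
  conventional 6–12 range) and `batch_size` (default 16). Full-batch
  quasi-Newton fitters keep a quadratic-size curvature approximation,
  which a width-50 layer over a count vocabulary rules out; the package
  therefore implements the minibatch trainer directly, with zero
  initialization of the output layer so that tokens never seen in
  training contribute nothing to the initial logit.
* `logistic` — the no-hidden-layer baseline, fitted to *convergence* by
  ridge-penalized maximum likelihood (`glmnet`, fixed small penalty).
  On count features the two are expected to behave comparably; the
  convex fit is deterministic without a seed and is the default for the
  one-vs-rest category bank.

The 13 category models are one-vs-rest; multi-label prediction is the
union of their positive decisions. Their default decision threshold is
0.8 rather than 0.5: balanced training inflates the positive prior to
one half while each model is applied at a prevalence far below that, and
shifting the threshold undoes part of that prior distortion (exact
correction at a typical 5–10% prevalence would push it above 0.9; 0.8 is
a milder default). The threshold is a config field, not a constant.

## The word-level tagger

The shipped tagger is a linear-chain conditional random field implemented
in the package (no CRF engine exists in the R dependency stack): sparse
indicator features, forward–backward gradients, L-BFGS-B on the
L2-penalized negative log-likelihood, zero initialization — training is
fully deterministic. The feature template per token is its lowercased
form, prefixes and suffixes of length 1–3, punctuation-run and
capitalization flags, neighbouring forms in a ±2 window, and a
sentence-initial flag; the template is recorded here because no standard
fixes it. Schemes: `binary` (any cue), `per_category` (one category's
cues only; the model's tag alphabet is closed over that category) and
`combined` (category-suffixed tags in one model). Predicted tag sequences
are decoded with the repairing codec; transformer taggers can be plugged
in by honouring the same `tagger_model` contract.

Novel-cue discovery compares predicted cue surfaces (normalized fragment
token sequences) against the dictionary; the reported fraction counts cue
*instances*, and plural variants of dictionary cues are additionally
counted, since they are the dominant real-world error source.

## Inter-annotator agreement and adjudication

Agreement is F1 between two annotation sets, one treated as reference:
precision = matches/|response|, recall = matches/|reference|; swapping the
sides flips precision and recall and leaves F1 unchanged. Exact cue
matches require identical span lists and categories; fuzzy matches accept
span overlap (≥ 1 character — no stricter threshold is defensible without
more information, and it is configurable) with identical categories, or
identical spans with subsumption-related categories (including a lexical
cue versus the category it implies). Pairing is a deterministic *maximum*
one-to-one matching (greedy seeding in document order plus augmenting
paths) rather than pure greedy: greedy is not always maximum on
overlapping fuzzy chains, and the count of matched pairs should not
depend on annotation order.

Adjudication merging pairs annotations by span overlap, takes the maximum
text span (character union per fragment, aligned by order) and the
narrowest applicable reference (`narrowest()`: a cue is deeper than its
category, a narrow category deeper than its broad parent). Pairs whose
categories sit on disjoint branches, and annotations present on one side
only, are returned as conflicts for human adjudication.

## Corpus statistics

Per-article tables report total, mean, median, min and max annotation
counts per narrow category plus all-categories and subject rows; medians
use R's default convention (mean of the two middle values), which yields
the half-integer medians these tables conventionally print. "Unique" cue
counts are emitted in both defensible readings — corpus-wide distinct keys
and per-article-distinct-then-summed — explicitly labelled
(`total_distinct`, `total_per_article`). Section attribution uses the
section containing the cue's first span; articles without detected
headers are excluded from the section table and listed.

## The synthetic corpus generator

The generator exists so that every stage — matching, codec, classifiers,
agreement, statistics — can be tested end-to-end with known ground truth.
Its defaults are fixed to the corpus conditions the pipeline targets:

* 60 articles of 100–140 sentences (full-text articles in the target
  corpus average roughly 120 sentences);
* a per-category planting rate of 0.04, so that about half of all
  sentences carry a cue and become subjects, matching the observed share
  of subject sentences;
* at most one planted category per sentence, except a `multi_cue_fraction`
  (default 0.1) that receives a second category;
* cue choice within a category is skewed geometrically by dictionary
  rank: in real corpora a handful of cues carry most annotations and over
  half the dictionary never occurs at all, and a generator that sampled
  cues uniformly would systematically overstate out-of-vocabulary effects
  at evaluation time;
* 15% of planted cues are discontinuous (1–`gap_limit` filler tokens in
  the gap); 5% of cue-free sentences are *decoys* — a cue lexeme in a
  sentence that is not a statement of ignorance, drawn from a hand-written
  template set that includes the classic negative contexts ("yin and yang
  are contradictory…", "maximum likelihood … unknown parameters");
* optional section headers (the six standard ones) and an optional
  novel-cue injection mode that plants pluralized variants, gold-annotated
  but absent from the dictionary, to exercise discovery.

The filler vocabulary is constructed to share **no token** with the cue
dictionary (asserted by a test), so planted cues are the only cue-pattern
occurrences and gold annotations are exhaustive. Punctuation-only cue
patterns (`?`) are matchable but never planted as a sentence's sole
marker, because sentence-level features are word-based and such a sentence
would be unlabelable by construction. The generator writes a ledger of
every planting decision.

What passing tests on this corpus do and do not show: synthetic filler is
not scientific prose; cue context carries no semantics, so the classifiers
are tested for *recovery of separable structure*, not for resolving
genuinely ambiguous negative contexts; decoy sentences reuse a small
template set. Results on real articles will be lower, and the synthetic
scores should be read as pipeline-correctness properties, not as expected
field performance.

## Problem sizes and numerical choices

The shipped test suite and acceptance script use: a 60-document corpus at
the default generator settings (decoys off and one category per sentence
for the classifier-recovery checks, i.e. marker-separable positives);
CRF training on 12 documents with evaluation on 6 held-out documents and
an optimizer cap of 60 L-BFGS iterations; 100 documents for the codec
round-trip property; 200 random annotation-set pairs (≤ 8 annotations a
side) for the agreement oracle. The CRF's L2 weight is 1.0; the logistic
ridge penalty is fixed at `1e-4`; Adam uses learning rate 0.1 with the
standard moment constants. Degenerate inputs are defined errors: empty
training sets, single-class training labels, split ratios outside (0, 1),
classes with fewer than two examples, and a matcher gap limit below 1 all
stop with a message, while empty documents and empty annotation sets are
valid and yield empty results.

## Known limitations

* The sentence splitter and tokenizer are deliberately simple; real-text
  boundary errors propagate to every downstream count.
* Bag-of-words sentence models cannot distinguish cue categories that
  share surface tokens in different orders, and see nothing of a
  punctuation-only cue.
* The CRF uses indicator features only — no embeddings — so it
  generalizes to unseen cue surfaces mainly through affix and context
  features.
* Agreement merging aligns fragments by order when fragment counts agree
  and falls back to interval union otherwise; exotic fragment structures
  may merge coarsely.
* Knowtator XML reading covers the annotation/classMention schema with
  span elements; schema dialects beyond that are normalized on a
  best-effort basis with unknown classes kept and reported.
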