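# ignoranceNLP

Scientific articles are full of *statements of ignorance* — sentences
asserting that knowledge is missing, incomplete, uncertain or contested
("the exact molecular function of SEPW1 protein is **unknown** to date").
Each such sentence contains one or more *lexical cues* (words or short
phrases, possibly discontinuous like "no … exist") that signal it, and each
cue maps to a *knowledge goal* in an ignorance taxonomy of 5 broad and 13
narrow categories (full unknown, explicit question, incomplete evidence,
superficial relationship, probable understanding, question answered by this
work, anomaly/curious finding, alternative options/controversy, difficult
task, problem/complication, future work, future prediction, important
consideration).

`ignoranceNLP` is an R toolkit for building and using corpora of such
statements. It is aimed at biomedical text-mining researchers and
annotation teams who want to find, categorise and count knowledge gaps in
full-text articles. It provides:

- the packaged **taxonomy and cue dictionary** (TSV, editable, importable),
  with subsumption queries (`narrowest()`) used during adjudication;
- **dictionary pre-annotation**: token-level, case-insensitive matching of
  contiguous and discontinuous cues, longest-match at each start, bounded
  discontinuity gaps (`pre_annotate()`);
- a **B/I/O/O- codec** between span annotations and per-token tag
  sequences, including the `O-` tag for tokens inside the gap of a
  discontinuous cue, with total (repairing) decoding (`bio_encode()`,
  `bio_decode()`);
- **sentence classifiers**: a binary statement-of-ignorance model and 13
  one-vs-rest category models over token-count vectors (single hidden
  layer of width 50 trained by minibatch gradient descent, plus a
  converged logistic baseline), with stratified 90:10 splitting and
  majority-class downsampling (`train_sentence()`,
  `train_category_models()`, `predict_multilabel()`);
- a **linear-chain CRF word tagger** (binary, per-category and combined
  multiclass schemes) with novel-cue discovery against the dictionary
  (`train_tagger()`, `predict_cues()`, `discover_novel_cues()`);
- **inter-annotator agreement**: exact and fuzzy span/category F1 with the
  reference-swap symmetry property, plus adjudication merging by maximum
  span and narrowest category (`iaa_exact()`, `iaa_fuzzy()`,
  `merge_adjudicate()`);
- **corpus statistics**: per-article annotation counts by category,
  unique-cue counts, per-section counts, dictionary-usage fractions
  (`category_counts()`, `unique_cue_counts()`, `section_counts()`,
  `dictionary_usage()`);
- **standoff I/O** for brat-style `.ann` (read/write) and Knowtator XML
  (read), with article section detection;
- a seeded **synthetic-corpus generator** (`simulate_corpus()`) emulating
  60 articles of ~120 sentences with realistic cue density, decoy
  (negative-context) sentences and section structure, so the whole
  pipeline is testable without downloads.

## Worked example

```r
library(ignoranceNLP)

tax <- default_taxonomy()
tax
#> <ignorance_taxonomy> 5 broad / 13 narrow categories, 97 cue patterns

doc <- soi_document("ex",
  paste("OWING TO the LACK OF other available DATA, we used the annual",
        "number of live births in Iasi county REPORTED on 01 July 2009",
        "to define the size of the reference group."))
ann <- pre_annotate(doc, tax)
cues_df(ann)
#>   doc_id       spans             category    provenance          surface
#> 1     ex         0-8 problem_complication pre_annotated         OWING TO
#> 2     ex 13-20;37-41         full_unknown pre_annotated LACK OF ... DATA
#> 3     ex      99-107  incomplete_evidence pre_annotated         REPORTED
```

The sentence is marked as one subject (a statement of ignorance) holding
three cues: "OWING TO" maps to *problem/complication*, the discontinuous
"LACK OF … DATA" (two span fragments, joined by `;` in the table) to
*full unknown*, and "REPORTED" to *incomplete evidence*. Encoding the
document gives the per-token tag sequence used by the word-level models —
`B O- I` for a discontinuous cue such as "no studies exist":

```r
d2 <- soi_document("d", "no studies exist")
a2 <- soi_annotated(d2, cues = list(
  soi_cue("d", c(0L, 11L), c(2L, 16L), "incomplete_evidence")))
bio_encode(a2, "binary")$tags
#> [1] "B"  "O-" "I"
```

End-to-end on synthetic data:

```r
corpus <- simulate_corpus(generator_config(n_documents = 60,
                                           decoy_rate = 0,
                                           multi_cue_fraction = 0,
                                           seed = 1))
ds <- sentence_dataset(corpus)
sp <- split_corpus(ds$label, ratio = 0.9, seed = 1)
m <- train_sentence(ds$text[sp$train], ds$label[sp$train],
                    training_config(seed = 1))
evaluate_f1(predict(m, ds$text[sp$test]), ds$label[sp$test])$f1
#> [1] 0.9973262
```

(Held-out F1 on the marker-separable synthetic corpus; `scripts/acceptance.R`
recomputes this same quantity.)

A thin command-line wrapper ships in `inst/cli/ignorance-tool` with
subcommands `simulate`, `pre-annotate`, `iaa`, `stats`, `discover-cues`
and `evaluate`.

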