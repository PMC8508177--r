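Package: ignoranceNLP
Title: Identifying and Classifying Statements of Ignorance in Scientific Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for finding and categorising statements of ignorance --
    sentences asserting that scientific knowledge is missing, incomplete,
    uncertain or contested -- in full-text biomedical articles.  Ships a
    knowledge-goal taxonomy (5 broad / 13 narrow categories) with a lexical-cue
    dictionary, dictionary-based pre-annotation supporting discontinuous cues,
    a B/I/O/O- tagging codec, sentence-level neural and logistic classifiers,
    a linear-chain conditional random field word tagger with novel-cue
    discovery, exact and fuzzy inter-annotator agreement with adjudication
    merging, corpus summary statistics, standoff annotation I/O (brat .ann and
    Knowtator XML), and a seeded synthetic-corpus generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
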