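tax <- default_taxonomy()

ann_signature <- function(cues, with_category = TRUE) {
  sort(vapply(cues, function(cu)
    paste(cu$doc_id, paste(cu$starts, cu$ends, collapse = ";"),
          if (with_category) cu$category else ""), ""))
}

test_that("discontinuous cues encode with O- gap tags", {
  doc <- soi_document("d", "no studies exist")
  ad <- soi_annotated(doc, cues = list(
    soi_cue("d", c(0L, 11L), c(2L, 16L), "incomplete_evidence")))
  expect_identical(bio_encode(ad, "binary")$tags, c("B", "O-", "I"))
  expect_identical(bio_encode(ad, "per_category")$tags,
                   c("B-incomplete_evidence", "O-",
                     "I-incomplete_evidence"))
})

test_that("contiguous multi-word cues encode as B I I", {
  doc <- soi_document("d", "need to be")
  ad <- soi_annotated(doc, cues = list(
    soi_cue("d", 0L, 10L, "future_work")))
  expect_identical(bio_encode(ad, "binary")$tags, c("B", "I", "I"))
  expect_identical(bio_encode(ad, "per_category")$tags,
                   c("B-future_work", "I-future_work", "I-future_work"))
  # and an unannotated document is all O
  expect_identical(bio_encode(soi_annotated(doc), "binary")$tags,
                   rep("O", 3L))
})

test_that("number of B tags equals number of annotations", {
  corpus <- make_test_corpus(seed = 23L, n_documents = 5L)
  for (ad in corpus$docs) {
    tags <- bio_encode(ad, "binary")$tags
    expect_identical(sum(tags == "B"), length(ad$cues))
  }
})

test_that("decode inverts encode on generator documents (both schemes)", {
  for (seed in 1:10) {
    corpus <- make_test_corpus(seed = 1000L + seed, n_documents = 10L)
    for (ad in corpus$docs) {
      for (scheme in c("binary", "per_category")) {
        enc <- bio_encode(ad, scheme)
        dec <- bio_decode(ad$document, enc, provenance = "human")
        expect_identical(dec$n_repairs, 0L)
        expect_identical(ann_signature(dec$cues, scheme == "per_category"),
                         ann_signature(ad$cues, scheme == "per_category"))
      }
    }
  }
})

test_that("decode example sequences reassemble the printed cues", {
  doc <- soi_document("d", "no studies exist")
  dec <- bio_decode(doc, c("B", "O-", "I"))
  expect_length(dec$cues, 1L)
  expect_identical(dec$cues[[1]]$starts, c(0L, 11L))
  expect_identical(dec$cues[[1]]$ends, c(2L, 16L))
  expect_identical(cue_surface(dec$cues[[1]], doc$text), "no ... exist")

  doc2 <- soi_document("d", "need to be")
  dec2 <- bio_decode(doc2, c("B", "I", "I"))
  expect_length(dec2$cues, 1L)
  expect_identical(cue_surface(dec2$cues[[1]], doc2$text), "need to be")
})

test_that("decode is total: malformed sequences are repaired, not rejected", {
  doc <- soi_document("d", "alpha beta gamma delta")
  # orphan I becomes B
  dec <- bio_decode(doc, c("O", "I", "O", "O"))
  expect_identical(dec$n_repairs, 1L)
  expect_length(dec$cues, 1L)
  expect_identical(cue_surface(dec$cues[[1]], doc$text), "beta")
  # trailing O- is demoted
  dec2 <- bio_decode(doc, c("B", "O-", "O", "O"))
  expect_identical(dec2$n_repairs, 1L)
  expect_identical(cue_surface(dec2$cues[[1]], doc$text), "alpha")
  # O- with no open cue is demoted
  dec3 <- bio_decode(doc, c("O-", "O", "B", "I"))
  expect_identical(dec3$n_repairs, 1L)
  expect_identical(cue_surface(dec3$cues[[1]], doc$text), "gamma delta")
  # suffix change mid-run starts a new annotation
  dec4 <- bio_decode(doc, c("B-full_unknown", "I-future_work", "O", "O"))
  expect_identical(dec4$n_repairs, 1L)
  expect_length(dec4$cues, 2L)
  # wrong length is the one hard error
  expect_error(bio_decode(doc, c("O", "O")), "token count")
})

test_that("random tag soup always decodes to a valid annotation list", {
  doc <- make_test_corpus(seed = 5L, n_documents = 1L)$docs[[1]]$document
  set.seed(99)
  for (rep in 1:25) {
    tags <- sample(c("O", "B", "I", "O-"), nrow(doc$tokens), replace = TRUE)
    dec <- bio_decode(doc, tags)
    for (cu in dec$cues) {
      expect_true(all(cu$starts < cu$ends))
      # spans stay within one sentence
      s1 <- ignoranceNLP:::sentence_at(doc, cu$starts[1])
      s2 <- ignoranceNLP:::sentence_at(doc, max(cu$ends) - 1L)
      expect_identical(s1, s2)
    }
  }
})

test_that("conflicting token claims are rejected with a named token", {
  doc <- soi_document("d", "need to be established")
  ad <- soi_annotated(doc, cues = list(
    soi_cue("d", 0L, 10L, "future_work"),
    soi_cue("d", 8L, 22L, "full_unknown")), check = TRUE)
  expect_error(bio_encode(ad, "per_category"), "conflicting token claims")
})

test_that("per-category filtering encodes only that category's cues", {
  corpus <- make_test_corpus(seed = 31L, n_documents = 4L)
  for (ad in corpus$docs) {
    cats <- unique(vapply(ad$cues, `[[`, "", "category"))
    if (length(cats) < 2L) next
    tags <- bio_encode(ad, "per_category", categories = cats[1])$tags
    suffixes <- unique(sub("^[BI]-", "",
                           tags[grepl("^[BI]-", tags)]))
    expect_identical(suffixes, cats[1])
  }
})

test_that("CoNLL two-column export round-trips", {
  corpus <- make_test_corpus(seed = 8L, n_documents = 1L)
  ad <- corpus$docs[[1]]
  tags <- bio_encode(ad, "per_category")
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(ad$document, tags, path)
  back <- read_conll(path)
  expect_identical(back$token, ad$document$tokens$text)
  expect_identical(back$tag, tags$tags)
  expect_identical(back$sentence,
                   match(ad$document$tokens$sentence,
                         unique(ad$document$tokens$sentence)))
})
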