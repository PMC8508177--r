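tax <- default_taxonomy()

grid_doc <- function(n_tokens = 30L) {
  soi_document("g", paste0(paste(rep("tok", n_tokens),
                                 collapse = " "), "."))
}

annotated <- function(doc, cues = list(), subjects = list())
  soi_annotated(doc, cues = cues, subjects = subjects, check = FALSE)

test_that("identical sets agree perfectly; disjoint sets not at all", {
  doc <- grid_doc()
  cues <- list(soi_cue("g", 0L, 7L, "full_unknown"),
               soi_cue("g", 12L, 19L, "future_work"))
  A <- annotated(doc, cues)
  expect_identical(iaa_exact(A, A)$cue$f1, 1)
  B <- annotated(doc, list())
  expect_identical(iaa_exact(A, B)$cue$f1, 0)
})

test_that("one agreeing pair out of two per side gives F1 one half", {
  doc <- grid_doc()
  A <- annotated(doc, list(soi_cue("g", 0L, 7L, "c1x"),
                           soi_cue("g", 10L, 17L, "c2x")))
  B <- annotated(doc, list(soi_cue("g", 0L, 7L, "c1x"),
                           soi_cue("g", 20L, 27L, "c2x")))
  r <- iaa_exact(A, B)
  expect_identical(r$cue$precision, 0.5)
  expect_identical(r$cue$recall, 0.5)
  expect_identical(r$cue$f1, 0.5)
})

test_that("fuzzy matching accepts span overlap or category subsumption", {
  text <- "Doses need to be carefully tailored in that cohort."
  doc <- soi_document("g", text)
  # NEED vs NEED TO BE, same category: overlap => fuzzy match
  A <- annotated(doc, list(soi_cue("g", 6L, 10L, "future_work")))
  B <- annotated(doc, list(soi_cue("g", 6L, 16L, "future_work")))
  expect_identical(iaa_exact(A, B)$cue$f1, 0)
  expect_identical(iaa_fuzzy(A, B, tax)$cue$f1, 1)
  # same span, category vs its implying lexical cue => fuzzy match
  C <- annotated(doc, list(soi_cue("g", 6L, 16L, "cue:need to be")))
  expect_identical(iaa_fuzzy(B, C, tax)$cue$f1, 1)
  # disjoint spans with the same category never match
  D <- annotated(doc, list(soi_cue("g", 27L, 35L, "future_work")))
  expect_identical(iaa_fuzzy(A, D, tax)$cue$f1, 0)
  # overlap + different-but-related category only with fuzzy_both
  E <- annotated(doc, list(soi_cue("g", 6L, 10L, "cue:need to be")))
  expect_identical(iaa_fuzzy(B, E, tax)$cue$f1, 0)
  expect_identical(iaa_fuzzy(B, E, tax, fuzzy_both = TRUE)$cue$f1, 1)
})

test_that("subject agreement is exact on spans, fuzzy on overlap", {
  text <- "First sentence here. Second sentence there."
  doc <- soi_document("g", text)
  A <- annotated(doc, subjects = list(soi_subject("g", 0L, 20L)))
  B <- annotated(doc, subjects = list(soi_subject("g", 0L, 20L)))
  expect_identical(iaa_exact(A, B)$subject$f1, 1)
  Bp <- annotated(doc, subjects = list(soi_subject("g", 0L, 14L)))
  expect_identical(iaa_exact(A, Bp)$subject$f1, 0)
  expect_identical(iaa_fuzzy(A, Bp, tax)$subject$f1, 1)
})

test_that("agreement equals the exhaustive matching oracle; F1 symmetric; fuzzy >= exact", {
  doc <- grid_doc(40L)
  cats <- c("full_unknown", "future_work", "levels_of_evidence",
            "cue:unknown", "cue:need to be", "incomplete_evidence")
  set.seed(13)
  for (rep in 1:200) {
    A <- annotated(doc, random_cue_set(doc, sample(1:8, 1), cats))
    B <- annotated(doc, random_cue_set(doc, sample(1:8, 1), cats))
    for (mode in c("exact", "fuzzy")) {
      r_ab <- if (mode == "exact") iaa_exact(A, B) else iaa_fuzzy(A, B, tax)
      r_ba <- if (mode == "exact") iaa_exact(B, A) else iaa_fuzzy(B, A, tax)
      comp <- matrix(FALSE, length(A$cues), length(B$cues))
      for (i in seq_along(A$cues)) for (j in seq_along(B$cues))
        comp[i, j] <- if (mode == "exact")
          ignoranceNLP:::cue_match_exact(A$cues[[i]], B$cues[[j]])
        else ignoranceNLP:::cue_match_fuzzy(A$cues[[i]], B$cues[[j]], tax)
      expect_identical(r_ab$cue$tp, oracle_max_matching(comp))
      expect_equal(r_ab$cue$f1, r_ba$cue$f1)
      expect_identical(r_ab$cue$precision, r_ba$cue$recall)
    }
    expect_gte(iaa_fuzzy(A, B, tax)$cue$f1, iaa_exact(A, B)$cue$f1)
  }
})

test_that("merge takes the maximum span and the narrowest category", {
  text <- paste("Thus doses of D vitamin and calcium supplementation",
                "need to be carefully tailored in patients.")
  doc <- soi_document("g", text)
  start <- regexpr("need to be", text) - 1L
  # one annotator highlights NEED, the other NEED TO BE
  A <- annotated(doc, list(soi_cue("g", start, start + 4L, "future_work")))
  B <- annotated(doc, list(soi_cue("g", start, start + 10L,
                                   "future_work")))
  m <- merge_adjudicate(A, B, tax)
  expect_length(m$conflicts, 0L)
  expect_identical(cue_surface(m$merged$cues[[1]], text), "need to be")
  # category vs implying cue resolves to the cue
  C <- annotated(doc, list(soi_cue("g", start, start + 10L,
                                   "cue:need to be")))
  m2 <- merge_adjudicate(B, C, tax)
  expect_identical(m2$merged$cues[[1]]$category, "cue:need to be")
})

test_that("merging a set with itself returns it unchanged, no conflicts", {
  corpus <- make_test_corpus(seed = 21L, n_documents = 2L)
  for (ad in corpus$docs) {
    m <- merge_adjudicate(ad, ad, tax)
    expect_length(m$conflicts, 0L)
    expect_identical(length(m$merged$cues), length(ad$cues))
    for (k in seq_along(ad$cues)) {
      expect_identical(m$merged$cues[[k]]$starts, ad$cues[[k]]$starts)
      expect_identical(m$merged$cues[[k]]$ends, ad$cues[[k]]$ends)
      expect_identical(m$merged$cues[[k]]$category, ad$cues[[k]]$category)
    }
    expect_identical(length(m$merged$subjects), length(ad$subjects))
  }
})

test_that("unresolvable pairs and one-sided annotations become conflicts", {
  doc <- grid_doc()
  # same span, categories on disjoint branches
  A <- annotated(doc, list(soi_cue("g", 0L, 7L, "cue:unknown")))
  B <- annotated(doc, list(soi_cue("g", 0L, 7L, "cue:reported")))
  m <- merge_adjudicate(A, B, tax)
  expect_length(m$merged$cues, 0L)
  expect_identical(vapply(m$conflicts, `[[`, "", "type"), "cue_category")
  # annotation present on one side only
  C <- annotated(doc, list(soi_cue("g", 0L, 7L, "full_unknown"),
                           soi_cue("g", 12L, 19L, "future_work")))
  D <- annotated(doc, list(soi_cue("g", 0L, 7L, "full_unknown")))
  m2 <- merge_adjudicate(C, D, tax)
  expect_length(m2$merged$cues, 1L)
  types <- vapply(m2$conflicts, `[[`, "", "type")
  expect_identical(types, "cue_only_in_a")
})

test_that("reference swap flips precision and recall on uneven sets", {
  doc <- grid_doc()
  A <- annotated(doc, list(soi_cue("g", 0L, 7L, "full_unknown")))
  B <- annotated(doc, list(soi_cue("g", 0L, 7L, "full_unknown"),
                           soi_cue("g", 12L, 19L, "full_unknown")))
  r1 <- iaa_exact(A, B)
  r2 <- iaa_exact(B, A)
  expect_identical(r1$cue$precision, 0.5)
  expect_identical(r1$cue$recall, 1)
  expect_identical(r2$cue$precision, 1)
  expect_identical(r2$cue$recall, 0.5)
  expect_equal(r1$cue$f1, r2$cue$f1)
})
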