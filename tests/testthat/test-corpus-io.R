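tax <- default_taxonomy()

ann_sig <- function(ad) {
  c(sort(vapply(ad$cues, function(cu)
    paste("C", paste(cu$starts, cu$ends, collapse = ";"), cu$category), "")),
    sort(vapply(ad$subjects, function(s)
      paste("S", s$start, s$end), "")))
}

test_that("standoff lines carry label, span pairs and surface", {
  doc <- soi_document("d", "It stays unknown for now.")
  ad <- soi_annotated(doc, cues = list(
    soi_cue("d", 9L, 16L, "full_unknown")))
  lines <- write_standoff(ad)
  expect_identical(lines, "T1\tfull_unknown 9 16\tunknown")
  # discontinuous cue keeps both span pairs on one line
  doc2 <- soi_document("d", "no studies exist")
  ad2 <- soi_annotated(doc2, cues = list(
    soi_cue("d", c(0L, 11L), c(2L, 16L), "full_unknown")))
  expect_identical(write_standoff(ad2),
                   "T1\tfull_unknown 0 2;11 16\tno exist")
  # empty annotation set gives an empty file
  expect_length(write_standoff(soi_annotated(doc)), 0L)
})

test_that("standoff write/read round-trips generator documents", {
  for (seed in c(3L, 14L)) {
    corpus <- make_test_corpus(seed = seed, n_documents = 5L)
    dir <- withr::local_tempdir()
    for (ad in corpus$docs) write_doc_pair(ad, dir)
    back <- read_corpus_dir(dir)
    expect_identical(length(back), length(corpus$docs))
    for (id in names(corpus$docs)) {
      expect_identical(back[[id]]$document$text,
                       corpus$docs[[id]]$document$text)
      expect_identical(ann_sig(back[[id]]), ann_sig(corpus$docs[[id]]))
    }
  }
})

knowtator_xml <- function(doc_id, anns) {
  # anns: list of list(cls, spans = list(c(start, end)), text)
  items <- vapply(seq_along(anns), function(i) {
    a <- anns[[i]]
    spans <- paste(vapply(a$spans, function(sp) sprintf(
      '<span start="%d" end="%d" />', sp[1], sp[2]), ""), collapse = "")
    paste0('<annotation><mention id="m', i, '" />',
           '<annotator id="x">tester</annotator>', spans,
           "<spannedText>", a$text, "</spannedText></annotation>",
           '<classMention id="m', i, '"><mentionClass id="', a$cls,
           '">', a$text, "</mentionClass></classMention>")
  }, "")
  paste0('<?xml version="1.0" encoding="UTF-8"?><annotations textSource="',
         doc_id, '.txt">', paste(items, collapse = ""), "</annotations>")
}

test_that("knowtator reader maps classes, spans and subjects", {
  text <- "The exact molecular function of SEPW1 protein is unknown to date."
  doc <- soi_document("k1", text)
  xml <- knowtator_xml("k1", list(
    list(cls = "full_unknown", spans = list(c(49L, 56L)), text = "unknown"),
    list(cls = "subject", spans = list(c(0L, nchar(text))), text = text)))
  res <- read_knowtator(xml, doc, tax)
  expect_length(res$annotated$cues, 1L)
  expect_identical(res$annotated$cues[[1]]$category, "full_unknown")
  expect_length(res$annotated$subjects, 1L)
  expect_length(res$unknown_classes, 0L)
})

test_that("two cues in a sentence still give one subject; classes normalize", {
  text <- "Results were contradictory and reported unevenly."
  doc <- soi_document("k2", text)
  xml <- knowtator_xml("k2", list(
    # cue-level class name: normalized via the dictionary
    list(cls = "contradictory", spans = list(c(13L, 26L)),
         text = "contradictory"),
    list(cls = "incomplete_evidence", spans = list(c(31L, 39L)),
         text = "reported"),
    # a sentence-long annotation without a resolvable class is a subject;
    # encoded twice it is only captured once
    list(cls = "subject", spans = list(c(0L, nchar(text))), text = text),
    list(cls = "subject", spans = list(c(0L, nchar(text))), text = text)))
  res <- read_knowtator(xml, doc, tax)
  expect_length(res$annotated$cues, 2L)
  expect_identical(res$annotated$cues[[1]]$category, "cue:contradictory")
  expect_length(res$annotated$subjects, 1L)
})

test_that("unknown classes are kept with a placeholder and reported", {
  text <- "Totally fine sentence here."
  doc <- soi_document("k3", text)
  xml <- knowtator_xml("k3", list(
    list(cls = "mystery_category", spans = list(c(0L, 7L)),
         text = "Totally")))
  res <- read_knowtator(xml, doc, tax)
  expect_length(res$annotated$cues, 1L)
  expect_match(res$annotated$cues[[1]]$category, "^unknown_class:")
  expect_identical(res$unknown_classes, "mystery_category")
  # nothing dropped: parsed + unknown == input annotations
  expect_identical(length(res$annotated$cues) +
                     length(res$annotated$subjects), 1L)
})

test_that("knowtator discontinuous spans become discontinuous cues", {
  text <- "no studies exist"
  doc <- soi_document("k4", text)
  xml <- knowtator_xml("k4", list(
    list(cls = "incomplete_evidence",
         spans = list(c(0L, 2L), c(11L, 16L)), text = "no exist")))
  res <- read_knowtator(xml, doc, tax)
  expect_length(res$annotated$cues, 1L)
  expect_identical(res$annotated$cues[[1]]$starts, c(0L, 11L))
  # offsets out of range abort
  xml_bad <- knowtator_xml("k4", list(
    list(cls = "full_unknown", spans = list(c(0L, 99L)), text = "x")))
  expect_error(read_knowtator(xml_bad, doc, tax), "out of range")
})

test_that("section detection recognizes the six standard headers", {
  text <- paste("Abstract", "One sentence.", "Introduction", "Two.",
                "Materials and Methods", "Three.", "Results", "Four.",
                "Discussion", "Five.", "Conclusions", "Six.", sep = "\n")
  sec <- detect_sections(text)
  expect_identical(sec$name, c("Abstract", "Introduction", "Methods",
                               "Results", "Discussion", "Conclusion"))
  expect_identical(sec$start[1], 0L)
  expect_identical(sec$end[nrow(sec)], nchar(text))
  # contiguous coverage
  expect_identical(sec$start[-1], sec$end[-nrow(sec)])
})

test_that("headerless text yields no sections; leading text maps to Abstract", {
  expect_identical(nrow(detect_sections("Just prose. No headers here?")), 0L)
  text <- paste("Leading teaser text.", "Methods", "Assays ran.",
                "Conclusion", "Done.", sep = "\n")
  sec <- detect_sections(text)
  expect_identical(sec$name, c("Abstract", "Methods", "Conclusion"))
  expect_identical(sec$start[1], 0L)
  expect_identical(sec$end[1], sec$start[2])
})
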