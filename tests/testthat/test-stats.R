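tax <- default_taxonomy()

# hand-built two-document fixture with known counts
fixture_corpus <- function() {
  t1 <- paste("Abstract",
              "The effect stays unknown here.",
              "Methods",
              "Values were unknown and unknown again.",
              "Doses need to be tailored.",
              "Conclusion",
              "This warrants caution.", sep = "\n")
  d1 <- soi_document("a1", t1)
  find_all <- function(text, pat) {
    out <- integer()
    off <- 0L
    while (TRUE) {
      i <- regexpr(pat, substring(text, off + 1L), fixed = TRUE)
      if (i == -1L) break
      out <- c(out, off + i - 1L)
      off <- off + i + nchar(pat) - 1L
    }
    out
  }
  cues1 <- c(
    lapply(find_all(t1, "unknown"), function(s)
      soi_cue("a1", s, s + 7L, "full_unknown")),
    lapply(find_all(t1, "need to be"), function(s)
      soi_cue("a1", s, s + 10L, "future_work")),
    lapply(find_all(t1, "warrants"), function(s)
      soi_cue("a1", s, s + 8L, "future_work")))
  subj1 <- lapply(unique(vapply(cues1, function(cu)
    ignoranceNLP:::sentence_at(d1, cu$starts[1]), integer(1))),
    function(si) soi_subject("a1", d1$sentences$start[si],
                             d1$sentences$end[si]))
  a1 <- soi_annotated(d1, cues1, subj1)

  t2 <- "No headers in this one. It stays unknown."
  d2 <- soi_document("a2", t2)
  s <- find_all(t2, "unknown")
  a2 <- soi_annotated(d2, list(soi_cue("a2", s, s + 7L, "full_unknown")),
                      list(soi_subject("a2", d2$sentences$start[2],
                                       d2$sentences$end[2])))
  list(a1 = a1, a2 = a2)
}

test_that("category counts aggregate totals, means and half-integer medians", {
  corpus <- fixture_corpus()
  tab <- category_counts(corpus, tax)
  row <- function(cat) tab[tab$category == cat, ]
  expect_identical(row("full_unknown")$total, 4L)   # 3 in a1, 1 in a2
  expect_identical(row("full_unknown")$mean, 2)
  expect_identical(row("future_work")$total, 2L)    # both in a1
  expect_identical(row("future_work")$median, 1)
  expect_identical(row("all_categories")$total, 6L)
  expect_identical(row("all_categories")$mean, 3)
  expect_identical(row("subject")$total, 5L)
  # sum of category rows equals the all-categories row
  cats <- tab$category[!tab$category %in% c("all_categories", "subject")]
  expect_identical(sum(tab$total[tab$category %in% cats]),
                   row("all_categories")$total)
  # a half-integer median arises from an even article count
  expect_identical(row("future_work")$median, 1)
  empty <- category_counts(list(), tax)
  expect_true(all(empty$total == 0L))
})

test_that("unique-cue counts use case-insensitive fragment identity", {
  corpus <- fixture_corpus()
  tab <- unique_cue_counts(corpus, tax)
  fu <- tab[tab$category == "full_unknown", ]
  expect_identical(fu$total_distinct, 1L)        # "unknown" only
  expect_identical(fu$total_per_article, 2L)     # once per article
  fw <- tab[tab$category == "future_work", ]
  expect_identical(fw$total_distinct, 2L)        # need to be, warrants
  allr <- tab[tab$category == "all_categories", ]
  expect_identical(allr$total_distinct, 3L)
  # unique counts never exceed raw counts, row-wise
  raw <- category_counts(corpus, tax)
  for (cat in tab$category) {
    if (!cat %in% raw$category) next
    expect_lte(tab$total_distinct[tab$category == cat],
               raw$total[raw$category == cat])
  }
})

test_that("mixed-category same-surface cues stay distinct per category", {
  text <- "alpha beta gamma delta epsilon."
  doc <- soi_document("m", text, sections = FALSE)
  cues <- list(soi_cue("m", 0L, 5L, "cat1"), soi_cue("m", 6L, 10L, "cat1"),
               soi_cue("m", 0L, 5L, "cat2"))
  # {alpha, beta} in cat1 and {alpha} in cat2: overlapping cues allowed in
  # analysis sets even if not encodable as one tag sequence
  ad <- soi_annotated(doc, cues, check = FALSE)
  tab <- unique_cue_counts(list(ad))
  expect_identical(tab$total_distinct[tab$category == "cat1"], 2L)
  expect_identical(tab$total_distinct[tab$category == "cat2"], 1L)
})

test_that("section counts attribute cues and exclude headerless articles", {
  corpus <- fixture_corpus()
  sc <- section_counts(corpus)
  expect_identical(sc$excluded, "a2")
  tab <- sc$table
  expect_identical(tab$total[tab$section == "Abstract"], 1L)
  expect_identical(tab$total[tab$section == "Methods"], 3L)
  expect_identical(tab$total[tab$section == "Conclusion"], 1L)
  expect_true(all(tab$n_articles == 1L))
  # attributed totals never exceed the all-categories total
  expect_lte(sum(tab$total),
             category_counts(corpus)$total[
               category_counts(corpus)$category == "all_categories"])
})

test_that("section counts match the generator's planting ledger", {
  corpus <- make_test_corpus(seed = 55L, n_documents = 4L)
  sc <- section_counts(corpus$docs)
  led <- corpus$ledger[corpus$ledger$type == "planted", ]
  want <- table(led$section)
  for (sec in rownames(want))
    expect_identical(sc$table$total[sc$table$section == sec],
                     as.integer(want[[sec]]))
})

test_that("dictionary usage is the fraction of cues seen at least once", {
  corpus <- fixture_corpus()
  du <- dictionary_usage(corpus, tax)
  expect_identical(du$n_used, 3L)  # unknown, need to be, warrants
  expect_identical(du$fraction, 3L / du$n_dictionary)
  expect_identical(dictionary_usage(list(), tax)$fraction, 0)
  # all planted cues of a generated corpus are counted as used
  gen <- make_test_corpus(seed = 3L, n_documents = 3L)
  du2 <- dictionary_usage(gen$docs, tax)
  planted <- unique(gen$ledger$cue[gen$ledger$type == "planted" &
                                     !gen$ledger$novel])
  expect_gte(du2$n_used, length(planted))
})
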