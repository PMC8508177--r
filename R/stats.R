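# per-article count vectors -> summary row (median may be half-integer)
.summarize_counts <- function(counts) {
  data.frame(total = sum(counts), mean = mean(counts),
             median = stats::median(counts), min = min(counts),
             max = max(counts))
}

.as_doc_list <- function(corpus) {
  if (inherits(corpus, "soi_corpus")) corpus <- corpus$docs
  if (inherits(corpus, "soi_annotated")) corpus <- list(corpus)
  corpus
}

#' Per-article annotation counts by category
#'
#' One row per narrow category plus an all-categories row and a subject
#' row; columns are the corpus total and the per-article mean, median, min
#' and max.  Ambiguous-category cues count under their assigned
#' (adjudicated) category only.
#'
#' @param corpus list of \code{\link{soi_annotated}} (or a
#'   \code{soi_corpus}).
#' @param tax optional \code{ignorance_taxonomy}; when given, every narrow
#'   category appears as a row even with zero annotations.
#' @return data.frame of class \code{soi_stats} keyed by \code{category}.
#' @export
category_counts <- function(corpus, tax = NULL) {
  corpus <- .as_doc_list(corpus)
  n_doc <- length(corpus)
  cats <- if (!is.null(tax)) narrow_categories(tax) else character()
  per_doc <- lapply(corpus, function(ad)
    table(vapply(ad$cues, `[[`, "", "category")))
  cats <- unique(c(cats, unlist(lapply(per_doc, names))))
  rows <- list()
  count_row <- function(name, counts) {
    if (!length(counts)) counts <- 0L
    cbind(data.frame(category = name, stringsAsFactors = FALSE),
          .summarize_counts(counts))
  }
  for (cat in cats) {
    counts <- vapply(per_doc, function(tb)
      if (cat %in% names(tb)) as.integer(tb[[cat]]) else 0L, integer(1))
    rows[[cat]] <- count_row(cat, counts)
  }
  all_counts <- vapply(corpus, function(ad) length(ad$cues), integer(1))
  subj_counts <- vapply(corpus, function(ad) length(ad$subjects),
                        integer(1))
  if (n_doc == 0L) {
    all_counts <- 0L
    subj_counts <- 0L
  }
  rows[["all_categories"]] <- count_row("all_categories", all_counts)
  rows[["subject"]] <- count_row("subject", subj_counts)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("soi_stats", "data.frame")
  out
}

#' Per-article unique-cue counts by category
#'
#' Uniqueness is by case-insensitive cue fragment sequence within a
#' category.  \code{total_distinct} is the corpus-wide distinct count;
#' \code{total_per_article} sums the per-article distinct counts (both
#' readings of "unique" are emitted); mean/median/min/max summarize the
#' per-article distinct counts.
#'
#' @inheritParams category_counts
#' @return data.frame of class \code{soi_stats}.
#' @export
unique_cue_counts <- function(corpus, tax = NULL) {
  corpus <- .as_doc_list(corpus)
  cats <- if (!is.null(tax)) narrow_categories(tax) else character()
  keys <- lapply(corpus, function(ad) {
    if (!length(ad$cues))
      return(data.frame(category = character(), key = character(),
                        stringsAsFactors = FALSE))
    data.frame(
      category = vapply(ad$cues, `[[`, "", "category"),
      key = vapply(ad$cues, function(cu)
        cue_key(cue_surface(cu, ad$document$text)), ""),
      stringsAsFactors = FALSE)
  })
  cats <- unique(c(cats, unlist(lapply(keys, function(k) k$category))))
  rows <- list()
  for (cat in cats) {
    per_doc <- vapply(keys, function(k)
      length(unique(k$key[k$category == cat])), integer(1))
    if (!length(per_doc)) per_doc <- 0L
    distinct <- length(unique(unlist(lapply(keys, function(k)
      k$key[k$category == cat]))))
    row <- cbind(data.frame(category = cat, total_distinct = distinct,
                            total_per_article = sum(per_doc),
                            stringsAsFactors = FALSE),
                 .summarize_counts(per_doc)[-1])
    rows[[cat]] <- row
  }
  per_doc_all <- vapply(keys, function(k)
    length(unique(paste(k$category, k$key))), integer(1))
  if (!length(per_doc_all)) per_doc_all <- 0L
  distinct_all <- length(unique(unlist(lapply(keys, function(k)
    paste(k$category, k$key)))))
  rows[["all_categories"]] <-
    cbind(data.frame(category = "all_categories",
                     total_distinct = distinct_all,
                     total_per_article = sum(per_doc_all),
                     stringsAsFactors = FALSE),
          .summarize_counts(per_doc_all)[-1])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("soi_stats", "data.frame")
  out
}

#' Per-article annotation counts by section
#'
#' A cue is attributed to the section containing its first span.  Articles
#' without section delineation are excluded and reported.
#'
#' @inheritParams category_counts
#' @return list with \code{table} (rows per section: number of articles
#'   having the section, total, mean, median, min, max over those
#'   articles) and \code{excluded} (doc ids without sections).
#' @export
section_counts <- function(corpus) {
  corpus <- .as_doc_list(corpus)
  has_sec <- vapply(corpus, function(ad) nrow(ad$document$sections) > 0L,
                    logical(1))
  excluded <- vapply(corpus[!has_sec], function(ad) ad$document$doc_id, "")
  corpus <- corpus[has_sec]
  rows <- list()
  for (sec in .section_names) {
    in_doc <- vapply(corpus, function(ad)
      sec %in% ad$document$sections$name, logical(1))
    if (!any(in_doc)) next
    counts <- vapply(corpus[in_doc], function(ad) {
      s <- ad$document$sections
      i <- which(s$name == sec)[1]
      sum(vapply(ad$cues, function(cu)
        cu$starts[1] >= s$start[i] && cu$starts[1] < s$end[i], logical(1)))
    }, integer(1))
    rows[[sec]] <- cbind(data.frame(section = sec,
                                    n_articles = sum(in_doc),
                                    stringsAsFactors = FALSE),
                         .summarize_counts(counts))
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) rownames(tab) <- NULL
  list(table = tab, excluded = unname(excluded))
}

#' Fraction of dictionary cues observed in a corpus
#'
#' @inheritParams category_counts
#' @param tax an \code{ignorance_taxonomy}.
#' @return list with \code{fraction} (= used / dictionary size),
#'   \code{n_used}, \code{n_dictionary} and \code{used} (keys).
#' @export
dictionary_usage <- function(corpus, tax) {
  corpus <- .as_doc_list(corpus)
  dict <- setdiff(ls(tax$cue_index), ".__n")
  seen <- unique(unlist(lapply(corpus, function(ad)
    vapply(ad$cues, function(cu)
      cue_key(cue_surface(cu, ad$document$text)), ""))))
  used <- intersect(dict, seen)
  list(fraction = if (length(dict)) length(used) / length(dict) else 0,
       n_used = length(used), n_dictionary = length(dict), used = used)
}
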