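# ---- pair compatibility ----------------------------------------------------

spans_identical <- function(a, b)
  length(a$starts) == length(b$starts) &&
  all(a$starts == b$starts) && all(a$ends == b$ends)

# shared characters between two (possibly discontinuous) span lists
span_overlap <- function(a, b) {
  ov <- 0L
  for (i in seq_along(a$starts))
    for (j in seq_along(b$starts))
      ov <- ov + max(0L, min(a$ends[i], b$ends[j]) -
                       max(a$starts[i], b$starts[j]))
  ov
}

categories_related <- function(tax, a, b) {
  if (identical(a, b)) return(TRUE)
  if (is.na(a) || is.na(b)) return(FALSE)
  ok <- TRUE
  tryCatch(narrowest(tax, a, b), soi_incomparable = function(e) ok <<- FALSE,
           error = function(e) ok <<- FALSE)
  ok
}

# exact: identical span list AND identical category
cue_match_exact <- function(a, b, ...) {
  spans_identical(a, b) && identical(a$category, b$category)
}

# fuzzy: overlap with same category, or same span with subsumption-related
# categories (cue-vs-its-category included); exact matches count as fuzzy.
# fuzzy_both additionally accepts overlap + subsumption simultaneously.
cue_match_fuzzy <- function(a, b, tax, fuzzy_both = FALSE) {
  if (cue_match_exact(a, b)) return(TRUE)
  same_cat <- identical(a$category, b$category)
  ident <- spans_identical(a, b)
  ov <- span_overlap(a, b) >= 1L
  if (ov && same_cat) return(TRUE)
  if (ident && categories_related(tax, a$category, b$category)) return(TRUE)
  if (fuzzy_both && ov && categories_related(tax, a$category, b$category))
    return(TRUE)
  FALSE
}

subject_match_exact <- function(a, b, ...) a$start == b$start && a$end == b$end

subject_match_fuzzy <- function(a, b, ...)
  min(a$end, b$end) > max(a$start, b$start)

# ---- one-to-one matching ---------------------------------------------------

# Deterministic maximum one-to-one matching: greedy seed in document order
# (ties toward larger overlap) followed by augmenting paths, so the matched
# count equals the maximum bipartite matching.
match_sets <- function(A, B, compatible) {
  nA <- length(A); nB <- length(B)
  if (nA == 0L || nB == 0L)
    return(list(pairs = cbind(integer(), integer()), n = 0L))
  comp <- matrix(FALSE, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB))
    comp[i, j] <- compatible(A[[i]], B[[j]])
  match_of_b <- rep(NA_integer_, nB)   # b index -> a index
  # greedy seed in document order, preferring larger overlap
  for (i in seq_len(nA)) {
    js <- which(comp[i, ] & is.na(match_of_b))
    if (!length(js)) next
    if (length(js) > 1L) {
      ov <- vapply(js, function(j) {
        a <- A[[i]]; b <- B[[j]]
        if (!is.null(a$starts)) span_overlap(a, b) else
          max(0L, min(a$end, b$end) - max(a$start, b$start))
      }, integer(1))
      js <- js[order(-ov, js)]
    }
    match_of_b[js[1]] <- i
  }
  # augmenting paths for unmatched A entries
  augment <- function(i, seen) {
    for (j in which(comp[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (is.na(match_of_b[j]) ||
          augment(match_of_b[j], seen)) {
        match_of_b[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  matched_a <- stats::na.omit(match_of_b)
  for (i in setdiff(seq_len(nA), matched_a)) {
    augment(i, rep(FALSE, nB))
  }
  pairs <- cbind(a = match_of_b[!is.na(match_of_b)],
                 b = which(!is.na(match_of_b)))
  list(pairs = pairs, n = nrow(pairs))
}

iaa_report_part <- function(A, B, compatible) {
  m <- match_sets(A, B, compatible)
  res <- prf(m$n, length(B) - m$n, length(A) - m$n)
  res$pairs <- m$pairs
  res$unmatched_a <- setdiff(seq_along(A), m$pairs[, 1])
  res$unmatched_b <- setdiff(seq_along(B), m$pairs[, 2])
  res
}

check_same_document <- function(A, B) {
  if (!identical(A$document$text, B$document$text))
    stop("annotation sets reference different document texts")
}

#' Exact inter-annotator agreement
#'
#' Treats \code{A} as reference and \code{B} as response: precision =
#' matches / |B|, recall = matches / |A|, F1 their harmonic mean (swapping
#' the sides flips precision and recall, leaving F1 unchanged).  A cue pair
#' matches iff the span lists and categories are identical; a subject pair
#' iff the sentence spans are identical.  Pairing is a deterministic
#' maximum one-to-one matching.
#'
#' @param A,B \code{\link{soi_annotated}} objects over the same document
#'   text.
#' @return object of class \code{soi_agreement} with \code{cue} and
#'   \code{subject} components (precision, recall, f1, matched pairs,
#'   unmatched indices per side) and \code{mode = "exact"}.
#' @export
iaa_exact <- function(A, B) {
  check_same_document(A, B)
  structure(list(cue = iaa_report_part(A$cues, B$cues, cue_match_exact),
                 subject = iaa_report_part(A$subjects, B$subjects,
                                           subject_match_exact),
                 mode = "exact"),
            class = "soi_agreement")
}

#' Fuzzy inter-annotator agreement
#'
#' Relaxes exact agreement: a cue pair also matches when the spans overlap
#' by at least one character with identical categories, or when the spans
#' are identical and the categories are related by taxonomy subsumption
#' (annotating to a lexical cue vs the category it implies).  Subjects
#' match on any overlap.  Exact matches count as fuzzy.
#'
#' @inheritParams iaa_exact
#' @param tax an \code{ignorance_taxonomy} for subsumption queries.
#' @param fuzzy_both also accept pairs where spans merely overlap AND
#'   categories are merely related (off by default).
#' @return a \code{soi_agreement} with \code{mode = "fuzzy"}.
#' @export
iaa_fuzzy <- function(A, B, tax = default_taxonomy(), fuzzy_both = FALSE) {
  check_same_document(A, B)
  cue_fun <- function(a, b) cue_match_fuzzy(a, b, tax, fuzzy_both)
  structure(list(cue = iaa_report_part(A$cues, B$cues, cue_fun),
                 subject = iaa_report_part(A$subjects, B$subjects,
                                           subject_match_fuzzy),
                 mode = "fuzzy"),
            class = "soi_agreement")
}

#' @export
print.soi_agreement <- function(x, ...) {
  cat("<soi_agreement> mode=", x$mode, "\n", sep = "")
  for (part in c("cue", "subject"))
    cat(sprintf("  %-8s P=%.3f R=%.3f F1=%.3f (%d matched)\n", part,
                x[[part]]$precision, x[[part]]$recall, x[[part]]$f1,
                x[[part]]$tp))
  invisible(x)
}

# character-union merge of two span lists; aligned by order when fragment
# counts agree, otherwise interval union of all fragments
merge_spans <- function(a, b) {
  if (length(a$starts) == length(b$starts)) {
    starts <- pmin(a$starts, b$starts)
    ends <- pmax(a$ends, b$ends)
  } else {
    starts <- c(a$starts, b$starts)
    ends <- c(a$ends, b$ends)
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  # coalesce overlapping or touching fragments
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(); out_e <- integer()
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me) me <- max(me, ends[k])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[k]; me <- ends[k] }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

#' Merge two annotation sets for adjudication
#'
#' Cue annotations are paired across the two sets by span overlap (at least
#' one shared character; identical spans included), subjects by sentence
#' overlap.  For every pair the merged annotation takes the maximum text
#' span (character union per fragment) and the narrowest applicable
#' category or lexical cue; pairs whose categories are not on one
#' subsumption path, and annotations matched by neither side, land on the
#' conflict list for human adjudication.
#'
#' @inheritParams iaa_fuzzy
#' @return list with \code{merged} (a \code{\link{soi_annotated}}) and
#'   \code{conflicts} (list of descriptive entries).
#' @export
merge_adjudicate <- function(A, B, tax = default_taxonomy()) {
  check_same_document(A, B)
  rep_fuzzy <- list(
    cue = iaa_report_part(A$cues, B$cues,
                          function(a, b) span_overlap(a, b) >= 1L),
    subject = iaa_report_part(A$subjects, B$subjects,
                              subject_match_fuzzy))
  conflicts <- list()
  cues <- list()
  cp <- rep_fuzzy$cue$pairs
  for (k in seq_len(nrow(cp))) {
    a <- A$cues[[cp[k, 1]]]
    b <- B$cues[[cp[k, 2]]]
    sp <- merge_spans(a, b)
    cat_ab <- tryCatch(narrowest(tax, a$category, b$category),
                       soi_incomparable = function(e) NULL,
                       error = function(e) NULL)
    if (is.null(cat_ab)) {
      conflicts[[length(conflicts) + 1L]] <-
        list(type = "cue_category", a = a, b = b)
      next
    }
    cues[[length(cues) + 1L]] <-
      soi_cue(a$doc_id, sp$starts, sp$ends, category = cat_ab,
              provenance = "human")
  }
  for (i in rep_fuzzy$cue$unmatched_a)
    conflicts[[length(conflicts) + 1L]] <-
      list(type = "cue_only_in_a", a = A$cues[[i]], b = NULL)
  for (j in rep_fuzzy$cue$unmatched_b)
    conflicts[[length(conflicts) + 1L]] <-
      list(type = "cue_only_in_b", a = NULL, b = B$cues[[j]])
  subjects <- list()
  sp_pairs <- rep_fuzzy$subject$pairs
  for (k in seq_len(nrow(sp_pairs))) {
    a <- A$subjects[[sp_pairs[k, 1]]]
    b <- B$subjects[[sp_pairs[k, 2]]]
    subjects[[length(subjects) + 1L]] <-
      soi_subject(a$doc_id, min(a$start, b$start), max(a$end, b$end),
                  provenance = "human")
  }
  for (i in rep_fuzzy$subject$unmatched_a)
    conflicts[[length(conflicts) + 1L]] <-
      list(type = "subject_only_in_a", a = A$subjects[[i]], b = NULL)
  for (j in rep_fuzzy$subject$unmatched_b)
    conflicts[[length(conflicts) + 1L]] <-
      list(type = "subject_only_in_b", a = NULL, b = B$subjects[[j]])
  merged <- soi_annotated(A$document, cues = cues, subjects = subjects,
                          check = FALSE)
  list(merged = merged, conflicts = conflicts)
}
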