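#' Compile a taxonomy's cue dictionary into a token-level matcher
#'
#' Cue fragments are tokenized with the package tokenizer and lowercased;
#' contiguous cues are indexed by first token, discontinuous cues carry their
#' fragment list.  Matching is deterministic.
#'
#' @param tax an \code{ignorance_taxonomy}.
#' @param gap_limit maximum number of tokens allowed inside one discontinuity
#'   (must be >= 1); discontinuous matches are additionally bounded by the
#'   sentence.
#' @return object of class \code{soi_matcher}.
#' @export
compile_matcher <- function(tax, gap_limit = 10L) {
  stopifnot(inherits(tax, "ignorance_taxonomy"))
  if (!is.numeric(gap_limit) || length(gap_limit) != 1L || gap_limit < 1L)
    stop("gap_limit must be a single number >= 1")
  keys <- ls(tax$cue_index)
  cues <- lapply(keys, function(k) {
    frags <- key_fragments(k)
    list(key = k, fragments = frags,
         n_tokens = sum(lengths(frags)),
         categories = get(k, envir = tax$cue_index))
  })
  first_tok <- vapply(cues, function(cu) cu$fragments[[1]][1], "")
  by_first <- split(seq_along(cues), first_tok)
  structure(list(cues = cues, by_first = by_first,
                 gap_limit = as.integer(gap_limit)),
            class = "soi_matcher")
}

#' @export
print.soi_matcher <- function(x, ...) {
  cat("<soi_matcher> ", length(x$cues), " cue patterns, gap limit ",
      x$gap_limit, "\n", sep = "")
  invisible(x)
}

# match one cue's fragments starting at token position i of a sentence's
# lowercased token vector; returns list of fragment index ranges or NULL.
# Depth-first search in ascending position order, so the reported placement
# is the lexicographically earliest valid one (each gap <= gap_limit).
match_fragments_at <- function(toks, i, fragments, gap_limit) {
  f1 <- fragments[[1]]
  if (i + length(f1) - 1L > length(toks)) return(NULL)
  if (!all(toks[i:(i + length(f1) - 1L)] == f1)) return(NULL)
  place_rest <- function(fi, pos) {
    if (fi > length(fragments)) return(list())
    f <- fragments[[fi]]
    if (pos > length(toks)) return(NULL)
    for (j in pos:min(pos + gap_limit, length(toks))) {
      if (j + length(f) - 1L > length(toks)) break
      if (all(toks[j:(j + length(f) - 1L)] == f)) {
        rest <- place_rest(fi + 1L, j + length(f))
        if (!is.null(rest))
          return(c(list(c(j, j + length(f) - 1L)), rest))
      }
    }
    NULL
  }
  rest <- place_rest(2L, i + length(f1))
  if (is.null(rest)) return(NULL)
  c(list(c(i, i + length(f1) - 1L)), rest)
}

#' Find all dictionary cues in a document
#'
#' Case-insensitive token-boundary matching within sentences.  At each start
#' token the longest contiguous cue wins; discontinuous cues match when their
#' fragments occur in order within one sentence with every gap at most
#' \code{gap_limit} tokens (earliest placement); overlapping matches of
#' distinct cues are all reported.  Ambiguous cues carry their full category
#' set, with the first dictionary category as the provisional assignment.
#'
#' @param doc a \code{\link{soi_document}}.
#' @param m a \code{\link{compile_matcher}} result.
#' @return list of \code{\link{soi_cue}} (provenance
#'   \code{"pre_annotated"}), ordered by position.
#' @export
match_cues <- function(doc, m) {
  stopifnot(inherits(doc, "soi_document"), inherits(m, "soi_matcher"))
  out <- list()
  tok <- doc$tokens
  if (!nrow(tok)) return(out)
  for (si in unique(tok$sentence)) {
    rows <- which(tok$sentence == si)
    toks <- tolower(tok$text[rows])
    for (i in seq_along(toks)) {
      cand <- m$by_first[[toks[i]]]
      if (is.null(cand)) next
      best_contig <- NULL
      best_len <- -1L
      for (ci in cand) {
        cu <- m$cues[[ci]]
        ranges <- match_fragments_at(toks, i, cu$fragments, m$gap_limit)
        if (is.null(ranges)) next
        if (length(cu$fragments) == 1L) {
          if (cu$n_tokens > best_len) {
            best_len <- cu$n_tokens
            best_contig <- list(cu = cu, ranges = ranges)
          }
        } else {
          out[[length(out) + 1L]] <- .range_cue(doc, rows, ranges, cu)
        }
      }
      if (!is.null(best_contig))
        out[[length(out) + 1L]] <-
          .range_cue(doc, rows, best_contig$ranges, best_contig$cu)
    }
  }
  if (length(out)) {
    o <- order(vapply(out, function(x) x$starts[1], integer(1)),
               vapply(out, function(x) max(x$ends), integer(1)))
    out <- out[o]
  }
  out
}

.range_cue <- function(doc, rows, ranges, cu) {
  starts <- vapply(ranges, function(r) doc$tokens$start[rows[r[1]]],
                   integer(1))
  ends <- vapply(ranges, function(r) doc$tokens$end[rows[r[2]]], integer(1))
  soi_cue(doc$doc_id, starts, ends, category = cu$categories[1],
          provenance = "pre_annotated", categories = cu$categories)
}

#' Dictionary-based pre-annotation
#'
#' Marks every dictionary cue in the document and adds one full-sentence
#' subject per sentence containing at least one cue.  Pre-annotation never
#' filters negative contexts (a cue lexeme in a non-ignorance sentence stays
#' marked); deletion is a downstream human or classifier decision.
#'
#' @param doc a \code{\link{soi_document}}.
#' @param tax an \code{ignorance_taxonomy}.
#' @param gap_limit passed to \code{\link{compile_matcher}}.
#' @return a \code{\link{soi_annotated}}.
#' @export
pre_annotate <- function(doc, tax, gap_limit = 10L) {
  m <- compile_matcher(tax, gap_limit)
  cues <- match_cues(doc, m)
  sent_ids <- sort(unique(vapply(cues, function(cu)
    sentence_at(doc, cu$starts[1]), integer(1))))
  subjects <- lapply(sent_ids, function(si)
    soi_subject(doc$doc_id, doc$sentences$start[si], doc$sentences$end[si],
                provenance = "pre_annotated"))
  soi_annotated(doc, cues = cues, subjects = subjects)
}
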