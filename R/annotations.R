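#' Cue annotation
#'
#' One lexical cue occurrence: one or more ordered, non-overlapping character
#' spans (more than one span means the cue is discontinuous, e.g.
#' \code{"no ... exist"}), a category assignment, and a provenance.
#'
#' The category is either a narrow taxonomy category id (e.g.
#' \code{"full_unknown"}) or a cue-level reference \code{"cue:<key>"} (an
#' annotator may annotate to the lexical cue itself rather than its category).
#' \code{categories} carries the full dictionary set for ambiguous cues;
#' \code{category} is the single assigned (adjudicated) one.
#'
#' @param doc_id document identifier.
#' @param starts,ends integer vectors of 0-based half-open span offsets.
#' @param category assigned category (narrow id or \code{"cue:<key>"}), may be
#'   \code{NA} for category-less predictions.
#' @param provenance one of \code{"pre_annotated"}, \code{"human"},
#'   \code{"predicted"}.
#' @param categories full candidate category set (defaults to
#'   \code{category}).
#' @return object of class \code{soi_cue}.
#' @export
soi_cue <- function(doc_id, starts, ends, category = NA_character_,
                    provenance = c("human", "pre_annotated", "predicted"),
                    categories = NULL) {
  provenance <- match.arg(provenance)
  starts <- as.integer(starts); ends <- as.integer(ends)
  stopifnot(length(starts) >= 1L, length(starts) == length(ends),
            all(starts < ends), all(starts >= 0L))
  if (length(starts) > 1L) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    if (any(starts[-1L] < ends[-length(ends)]))
      stop("cue spans must be non-overlapping")
  }
  if (is.null(categories)) categories <- category
  categories <- categories[!is.na(categories)]
  structure(list(doc_id = doc_id, starts = starts, ends = ends,
                 category = category, categories = categories,
                 provenance = provenance),
            class = "soi_cue")
}

#' Subject annotation
#'
#' The full sentence containing at least one confirmed lexical cue; the
#' scope of a statement of ignorance.
#'
#' @inheritParams soi_cue
#' @param start,end 0-based half-open offsets of one full sentence.
#' @return object of class \code{soi_subject}.
#' @export
soi_subject <- function(doc_id, start, end,
                        provenance = c("human", "pre_annotated", "predicted")) {
  provenance <- match.arg(provenance)
  stopifnot(length(start) == 1L, length(end) == 1L, start < end)
  structure(list(doc_id = doc_id, start = as.integer(start),
                 end = as.integer(end), provenance = provenance),
            class = "soi_subject")
}

#' Annotated document
#'
#' A document together with its cue and subject annotations.  Invariants
#' (checked): every annotation lies inside the document; every cue's spans
#' fall within one sentence; at most one subject per sentence.
#'
#' @param document a \code{\link{soi_document}}.
#' @param cues list of \code{\link{soi_cue}}.
#' @param subjects list of \code{\link{soi_subject}}.
#' @param check validate invariants?
#' @return object of class \code{soi_annotated}.
#' @export
soi_annotated <- function(document, cues = list(), subjects = list(),
                          check = TRUE) {
  stopifnot(inherits(document, "soi_document"))
  if (check) {
    n <- nchar(document$text)
    for (cue in cues) {
      stopifnot(inherits(cue, "soi_cue"))
      if (max(cue$ends) > n) stop("cue span beyond document end")
      s1 <- sentence_at(document, cue$starts[1])
      s2 <- sentence_at(document, max(cue$ends) - 1L)
      if (is.na(s1) || is.na(s2) || s1 != s2)
        stop("cue spans must lie within one sentence")
    }
    ss <- vapply(subjects, function(s) s$start, integer(1))
    if (anyDuplicated(ss)) stop("at most one subject per sentence")
    for (s in subjects) {
      stopifnot(inherits(s, "soi_subject"))
      if (s$end > n) stop("subject span beyond document end")
    }
  }
  structure(list(document = document, cues = cues, subjects = subjects),
            class = "soi_annotated")
}

#' @export
print.soi_cue <- function(x, ...) {
  spans <- paste(sprintf("%d-%d", x$starts, x$ends), collapse = ";")
  cat("<soi_cue> ", x$doc_id, " [", spans, "] ", x$category,
      " (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' @export
print.soi_annotated <- function(x, ...) {
  cat("<soi_annotated> ", x$document$doc_id, ": ", length(x$cues),
      " cues, ", length(x$subjects), " subjects\n", sep = "")
  invisible(x)
}

#' Surface text of a cue annotation's fragments
#'
#' @param cue a \code{\link{soi_cue}}.
#' @param text the document text the offsets refer to.
#' @param collapse separator between fragments.
#' @return character scalar, fragments joined by \code{collapse}.
#' @export
cue_surface <- function(cue, text, collapse = " ... ") {
  paste(span_text(text, cue$starts, cue$ends), collapse = collapse)
}

#' Annotations as a data frame
#'
#' Flattens the cue annotations of one or more annotated documents; spans of
#' discontinuous cues are encoded as \code{"start-end;start-end"}.
#'
#' @param docs a \code{soi_annotated} or list of them.
#' @return data.frame with one row per cue annotation.
#' @export
cues_df <- function(docs) {
  if (inherits(docs, "soi_annotated")) docs <- list(docs)
  rows <- lapply(docs, function(ad) {
    if (!length(ad$cues)) return(NULL)
    data.frame(
      doc_id = vapply(ad$cues, `[[`, "", "doc_id"),
      spans = vapply(ad$cues, function(x)
        paste(sprintf("%d-%d", x$starts, x$ends), collapse = ";"), ""),
      category = vapply(ad$cues, `[[`, "", "category"),
      provenance = vapply(ad$cues, `[[`, "", "provenance"),
      surface = vapply(ad$cues, cue_surface, "", text = ad$document$text),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(), spans = character(),
                      category = character(), provenance = character(),
                      surface = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
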