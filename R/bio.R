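#' Encode span annotations as a B/I/O/O- tag sequence
#'
#' One tag per document token.  The first token of a cue gets \code{B},
#' subsequent cue tokens \code{I} (including tokens of later fragments of a
#' discontinuous cue), tokens inside a discontinuity \code{O-}, everything
#' else \code{O}.  Under the \code{per_category} scheme, \code{B}/\code{I}
#' are suffixed with the annotation's narrow category
#' (\code{B-full_unknown}); gap tokens stay an unsuffixed \code{O-} since
#' they are not cue words.
#'
#' @param adoc a \code{\link{soi_annotated}}.
#' @param scheme \code{"binary"} or \code{"per_category"}.
#' @param categories optional filter: only annotations whose assigned
#'   category is in this set are encoded (used to build the 13 per-category
#'   training sequences).
#' @return object of class \code{soi_tags}: list with \code{doc_id},
#'   \code{tags} (one per token) and \code{scheme}.
#' @export
bio_encode <- function(adoc, scheme = c("binary", "per_category"),
                       categories = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(adoc, "soi_annotated"))
  doc <- adoc$document
  n <- nrow(doc$tokens)
  tags <- rep("O", n)
  claimed <- rep(NA_integer_, n)
  cues <- adoc$cues
  if (!is.null(categories))
    cues <- Filter(function(cu) !is.na(cu$category) &&
                     cu$category %in% categories, cues)
  for (ai in seq_along(cues)) {
    cu <- cues[[ai]]
    cue_tok <- integer()
    for (k in seq_along(cu$starts)) {
      hit <- which(doc$tokens$start < cu$ends[k] &
                     doc$tokens$end > cu$starts[k])
      cue_tok <- c(cue_tok, hit)
    }
    cue_tok <- sort(unique(cue_tok))
    if (!length(cue_tok))
      stop("annotation ", ai, " covers no tokens")
    dup <- cue_tok[!is.na(claimed[cue_tok])]
    if (length(dup))
      stop("conflicting token claims: token ", dup[1], " ('",
           doc$tokens$text[dup[1]], "') claimed by annotations ",
           claimed[dup[1]], " and ", ai)
    claimed[cue_tok] <- ai
    suffix <- if (scheme == "per_category") paste0("-", cu$category) else ""
    gap_tok <- setdiff(seq(min(cue_tok), max(cue_tok)), cue_tok)
    gap_clash <- gap_tok[tags[gap_tok] != "O"]
    if (length(gap_clash))
      stop("conflicting token claims: gap token ", gap_clash[1],
           " of annotation ", ai, " already tagged")
    tags[gap_tok] <- "O-"
    tags[cue_tok[1]] <- paste0("B", suffix)
    if (length(cue_tok) > 1L)
      tags[cue_tok[-1]] <- paste0("I", suffix)
  }
  structure(list(doc_id = doc$doc_id, tags = tags, scheme = scheme),
            class = "soi_tags")
}

#' @export
print.soi_tags <- function(x, ...) {
  cat("<soi_tags> ", x$doc_id, " (", x$scheme, "): ", length(x$tags),
      " tags, ", sum(startsWith(x$tags, "B")), " B\n", sep = "")
  invisible(x)
}

# split "B-full_unknown" into base and suffix
split_tag <- function(tag) {
  if (tag %in% c("O", "O-")) return(c(tag, ""))
  dash <- regexpr("-", tag, fixed = TRUE)
  if (dash == -1L) c(tag, "") else
    c(substr(tag, 1L, dash - 1L), substring(tag, dash + 1L))
}

#' Decode a tag sequence back to cue annotations
#'
#' Maximal \code{B I*} runs become contiguous cues; runs bridged by
#' \code{O-} become one discontinuous cue.  Decoding is total: malformed
#' sequences are repaired rather than rejected (orphan \code{I} is promoted
#' to \code{B}; \code{O-} with no following cue tag is demoted to \code{O};
#' a category-suffix change inside a run starts a new annotation).  Runs
#' never cross sentence boundaries.  Repairs are counted and reported for
#' error analysis.
#'
#' @param doc the \code{\link{soi_document}} the tags refer to.
#' @param tags a \code{soi_tags} (or bare character vector, one tag per
#'   token).
#' @param provenance provenance recorded on decoded annotations.
#' @return list with \code{cues} (list of \code{\link{soi_cue}}),
#'   \code{n_repairs} and \code{repairs} (messages).
#' @export
bio_decode <- function(doc, tags, provenance = "predicted") {
  stopifnot(inherits(doc, "soi_document"))
  if (inherits(tags, "soi_tags")) tags <- tags$tags
  n <- nrow(doc$tokens)
  if (length(tags) != n)
    stop("tag count (", length(tags), ") != token count (", n, ")")
  cues <- list()
  repairs <- character()

  cur_frags <- NULL   # list of integer vectors (token indices)
  cur_suffix <- ""
  pending_gap <- integer()

  close_run <- function() {
    if (is.null(cur_frags)) return()
    if (length(pending_gap)) {
      repairs <<- c(repairs, paste0("dangling O- demoted to O at token ",
                                    pending_gap[1]))
      pending_gap <<- integer()
    }
    starts <- vapply(cur_frags, function(f) doc$tokens$start[f[1]],
                     integer(1))
    ends <- vapply(cur_frags, function(f) doc$tokens$end[f[length(f)]],
                   integer(1))
    category <- if (nzchar(cur_suffix)) cur_suffix else NA_character_
    cues[[length(cues) + 1L]] <<- soi_cue(doc$doc_id, starts, ends,
                                          category = category,
                                          provenance = provenance)
    cur_frags <<- NULL
    cur_suffix <<- ""
  }

  start_run <- function(t, suffix) {
    cur_frags <<- list(t)
    cur_suffix <<- suffix
    pending_gap <<- integer()
  }

  prev_sentence <- NA_integer_
  for (t in seq_len(n)) {
    sent <- doc$tokens$sentence[t]
    if (!is.na(prev_sentence) && sent != prev_sentence) close_run()
    prev_sentence <- sent
    parts <- split_tag(tags[t])
    base <- parts[1]; suffix <- parts[2]
    if (base == "B") {
      close_run()
      start_run(t, suffix)
    } else if (base == "I") {
      if (is.null(cur_frags)) {
        repairs <- c(repairs, paste0("orphan I repaired to B at token ", t))
        start_run(t, suffix)
      } else if (nzchar(suffix) && !identical(suffix, cur_suffix)) {
        repairs <- c(repairs,
                     paste0("suffix change inside run at token ", t,
                            " treated as new B"))
        close_run()
        start_run(t, suffix)
      } else if (length(pending_gap)) {
        cur_frags[[length(cur_frags) + 1L]] <- t
        pending_gap <- integer()
      } else {
        k <- length(cur_frags)
        cur_frags[[k]] <- c(cur_frags[[k]], t)
      }
    } else if (base == "O-") {
      if (is.null(cur_frags)) {
        repairs <- c(repairs, paste0("O- outside a cue demoted to O at token ",
                                     t))
      } else {
        pending_gap <- c(pending_gap, t)
      }
    } else {  # O
      close_run()
    }
  }
  close_run()
  list(cues = cues, n_repairs = length(repairs), repairs = repairs)
}

#' Write token/tag pairs in CoNLL-style two-column text
#'
#' One \code{token<TAB>tag} line per token, a blank line between sentences.
#'
#' @param doc a \code{\link{soi_document}}.
#' @param tags a \code{soi_tags} for the document.
#' @param path output file; when \code{NULL} the lines are returned.
#' @return the lines, invisibly when written to \code{path}.
#' @export
write_conll <- function(doc, tags, path = NULL) {
  if (inherits(tags, "soi_tags")) tags <- tags$tags
  stopifnot(length(tags) == nrow(doc$tokens))
  lines <- character()
  prev <- NA_integer_
  for (t in seq_along(tags)) {
    sent <- doc$tokens$sentence[t]
    if (!is.na(prev) && sent != prev) lines <- c(lines, "")
    prev <- sent
    lines <- c(lines, paste0(doc$tokens$text[t], "\t", tags[t]))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read CoNLL-style token/tag lines
#'
#' @param path file path or character vector of lines.
#' @return data.frame with \code{token}, \code{tag} and \code{sentence}
#'   columns.
#' @export
read_conll <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
  else path
  sent <- 1L
  tok <- character(); tag <- character(); sid <- integer()
  for (ln in lines) {
    if (!nzchar(ln)) { sent <- sent + 1L; next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tok <- c(tok, parts[1]); tag <- c(tag, parts[2]); sid <- c(sid, sent)
  }
  data.frame(token = tok, tag = tag, sentence = sid, stringsAsFactors = FALSE)
}
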