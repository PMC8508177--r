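#' Word/punctuation-run tokenization
#'
#' Tokens are maximal runs of alphanumeric characters or maximal runs of
#' non-space punctuation, so \code{"unknown?"} yields \code{"unknown"} and
#' \code{"?"}.  This is the normative tokenization dialect for the whole
#' package: cue dictionaries, matchers and BIO tag sequences all assume it.
#'
#' @param text character scalar.
#' @return data.frame with columns \code{start}, \code{end} (0-based,
#'   half-open character offsets) and \code{text}.
#' @export
tokenize_spans <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || nchar(text) == 0L) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9]+|[^\\sA-Za-z0-9]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len,
             text = substring(text, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

#' Tokenize to a character vector
#'
#' @param text character scalar.
#' @param lower lowercase the tokens?
#' @return character vector of token strings.
#' @export
tokenize <- function(text, lower = FALSE) {
  tok <- tokenize_spans(text)$text
  if (lower) tolower(tok) else tok
}

# Abbreviations whose trailing period never ends a sentence.  Matched against
# the lowercased alphabetic run immediately before the terminal punctuation;
# single letters (initials, "i.e."/"e.g." pieces) are always guarded.
.sentence_abbrev <- c("al", "fig", "figs", "vs", "cf", "ca", "dr", "st",
                      "no", "approx", "resp")

#' Rule-based sentence segmentation
#'
#' Boundaries are placed at newlines and after sentence-final punctuation
#' (\code{. ! ?}) followed by whitespace and an uppercase letter or digit,
#' with a fixed abbreviation guard list (\code{et al.}, \code{Fig.},
#' \code{i.e.}, ...).  Deterministic by construction; no trained model.
#' Returned spans are trimmed to their non-whitespace extent and jointly
#' cover all non-whitespace text.
#'
#' @param text character scalar (assumed LF line endings; see
#'   \code{\link{soi_document}}).
#' @return data.frame with 0-based half-open \code{start}, \code{end} columns,
#'   one row per sentence, in document order.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer())
  if (is.na(text) || nchar(text) == 0L) return(empty)

  # segment at newlines first (section headers sit on their own lines)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) return(empty)
  line_off <- c(0L, cumsum(nchar(lines) + 1L))  # offset of each line start

  out_start <- integer()
  out_end <- integer()
  for (li in seq_along(lines)) {
    ln <- lines[li]
    if (!nzchar(trimws(ln))) next
    off <- line_off[li]
    # candidate boundaries: terminal punctuation run, whitespace, then
    # uppercase or digit
    m <- gregexpr("[.!?]+(?=\\s+[A-Z0-9])", ln, perl = TRUE)[[1]]
    cuts <- integer()
    if (m[1] != -1L) {
      for (k in seq_along(m)) {
        p_start <- as.integer(m[k])
        p_len <- attr(m, "match.length")[k]
        before <- substr(ln, max(1L, p_start - 20L), p_start - 1L)
        mm <- regmatches(before, regexpr("[A-Za-z]+$", before))
        prev <- if (length(mm)) tolower(mm) else ""
        # only '.' can belong to an abbreviation; "i.e."/"e.g." need the
        # dotted context, plain abbreviations just the preceding word
        is_abbrev <- substr(ln, p_start, p_start) == "." &&
          (prev %in% .sentence_abbrev ||
             grepl("(^|[^A-Za-z])(i\\.e|e\\.g)$", before, ignore.case = TRUE))
        if (is_abbrev) next
        cuts <- c(cuts, p_start + p_len - 1L)  # 1-based last char of sentence
      }
    }
    seg_start <- c(1L, cuts + 1L)
    seg_end <- c(cuts, nchar(ln))
    for (k in seq_along(seg_start)) {
      seg <- substr(ln, seg_start[k], seg_end[k])
      lead <- regmatches(seg, regexpr("^\\s*", seg))
      trail <- regmatches(seg, regexpr("\\s*$", seg))
      a <- seg_start[k] + nchar(lead)
      b <- seg_end[k] - nchar(trail)
      if (a > b) next
      out_start <- c(out_start, off + a - 1L)
      out_end <- c(out_end, off + b)
    }
  }
  data.frame(start = out_start, end = out_end)
}

#' Build a document with sentence and token spans
#'
#' Normalizes CRLF to LF (offsets refer to the normalized text), segments
#' sentences, tokenizes, assigns each token to its containing sentence, and
#' optionally detects article sections.
#'
#' @param doc_id document identifier.
#' @param text full article text (UTF-8).
#' @param sections detect section headers? (see \code{\link{detect_sections}})
#' @return object of class \code{soi_document}: a list with \code{doc_id},
#'   \code{text}, \code{sentences}, \code{tokens} (with a \code{sentence}
#'   index column) and \code{sections}.
#' @export
soi_document <- function(doc_id, text, sections = TRUE) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  text <- gsub("\r\n", "\n", text, fixed = TRUE)
  sent <- split_sentences(text)
  tok <- tokenize_spans(text)
  if (nrow(tok)) {
    # a token never crosses whitespace, hence never a sentence boundary
    idx <- findInterval(tok$start, sent$start)
    idx[idx == 0L] <- NA_integer_
    bad <- !is.na(idx) & tok$end > sent$end[idx]
    idx[bad] <- NA_integer_
    tok$sentence <- idx
    tok <- tok[!is.na(tok$sentence), , drop = FALSE]
    rownames(tok) <- NULL
  } else {
    tok$sentence <- integer()
  }
  sec <- if (isTRUE(sections)) detect_sections(text) else
    data.frame(name = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  structure(list(doc_id = doc_id, text = text, sentences = sent,
                 tokens = tok, sections = sec),
            class = "soi_document")
}

#' @export
print.soi_document <- function(x, ...) {
  cat("<soi_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$sentences), " sentences, ", nrow(x$tokens), " tokens",
      if (nrow(x$sections)) paste0(", ", nrow(x$sections), " sections"),
      "\n", sep = "")
  invisible(x)
}

#' Substring for 0-based half-open spans
#'
#' All offsets in this package are 0-based, half-open characters.
#'
#' @param text document text.
#' @param start,end span offsets (vectorized).
#' @return character vector of span texts.
#' @export
span_text <- function(text, start, end) substring(text, start + 1L, end)

# sentence index containing a 0-based offset, NA when outside all sentences
sentence_at <- function(doc, offset) {
  i <- findInterval(offset, doc$sentences$start)
  if (i == 0L || offset >= doc$sentences$end[i]) NA_integer_ else i
}
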