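.section_names <- c("Abstract", "Introduction", "Methods", "Results",
                    "Discussion", "Conclusion")

.section_aliases <- c(
  "abstract" = "Abstract", "introduction" = "Introduction",
  "methods" = "Methods", "materials and methods" = "Methods",
  "results" = "Results", "discussion" = "Discussion",
  "conclusion" = "Conclusion", "conclusions" = "Conclusion")

#' Detect article sections from header lines
#'
#' A header is a line whose trimmed text (optionally ending in \code{:})
#' matches one of Abstract, Introduction, Methods / Materials and Methods,
#' Results, Discussion, Conclusion(s), case-insensitively.  Each section
#' runs from its header to the next header (or document end).  Text before
#' the first header is assigned to Abstract.  Articles without any header
#' yield an empty table (no section delineation).
#'
#' @param text article text (LF line endings).
#' @return data.frame with \code{name}, \code{start}, \code{end} columns
#'   (0-based half-open spans), in document order.
#' @export
detect_sections <- function(text) {
  empty <- data.frame(name = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) return(empty)
  off <- c(0L, cumsum(nchar(lines) + 1L))
  key <- tolower(sub(":$", "", trimws(lines)))
  hit <- which(key %in% names(.section_aliases))
  if (!length(hit)) return(empty)
  name <- unname(.section_aliases[key[hit]])
  start <- off[hit]
  end <- c(off[hit[-1]], nchar(text))
  if (hit[1] > 1L && nzchar(trimws(paste(lines[seq_len(hit[1] - 1L)],
                                         collapse = "")))) {
    name <- c("Abstract", name)
    end <- c(start[1], end)
    start <- c(0L, start)
  }
  data.frame(name = name, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# category field <-> .ann label (labels cannot contain whitespace)
.label_of <- function(category) {
  if (is.na(category)) "cue" else gsub(" ", "_", category, fixed = TRUE)
}
.category_of <- function(label) {
  if (label == "cue") return(NA_character_)
  if (startsWith(label, "cue:"))
    paste0("cue:", gsub("_", " ", substring(label, 5L), fixed = TRUE))
  else label
}

#' Write annotations as brat-style standoff
#'
#' One line per annotation: id, label, semicolon-separated
#' \code{start end} pairs (discontinuity preserved), and the surface text
#' with fragments joined by a space.  Subjects carry the label
#' \code{subject}.
#'
#' @param adoc a \code{\link{soi_annotated}}.
#' @param path output \code{.ann} file; when \code{NULL}, lines are
#'   returned.
#' @return the lines (invisibly when written).
#' @export
write_standoff <- function(adoc, path = NULL) {
  stopifnot(inherits(adoc, "soi_annotated"))
  text <- adoc$document$text
  lines <- character()
  i <- 0L
  for (cu in adoc$cues) {
    i <- i + 1L
    spans <- paste(sprintf("%d %d", cu$starts, cu$ends), collapse = ";")
    surf <- paste(span_text(text, cu$starts, cu$ends), collapse = " ")
    lines <- c(lines, paste0("T", i, "\t", .label_of(cu$category), " ",
                             spans, "\t", surf))
  }
  for (s in adoc$subjects) {
    i <- i + 1L
    lines <- c(lines, paste0("T", i, "\tsubject ", s$start, " ", s$end,
                             "\t", span_text(text, s$start, s$end)))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read brat-style standoff annotations
#'
#' Annotations labelled \code{subject}, or whose single span equals a
#' sentence span of the document, become subjects; all others cues.
#'
#' @param ann path to an \code{.ann} file or a character vector of lines.
#' @param doc the companion \code{\link{soi_document}}.
#' @param provenance provenance recorded on the annotations.
#' @return a \code{\link{soi_annotated}}.
#' @export
read_standoff <- function(ann, doc, provenance = "human") {
  stopifnot(inherits(doc, "soi_document"))
  lines <- if (length(ann) == 1L && file.exists(ann)) readLines(ann) else ann
  lines <- lines[nzchar(lines)]
  cues <- list()
  subjects <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed standoff line: ", ln)
    body <- parts[2]
    sp <- regexpr(" ", body, fixed = TRUE)
    label <- substr(body, 1L, sp - 1L)
    span_str <- substring(body, sp + 1L)
    pairs <- strsplit(strsplit(span_str, ";", fixed = TRUE)[[1]], " ")
    starts <- vapply(pairs, function(p) as.integer(p[1]), integer(1))
    ends <- vapply(pairs, function(p) as.integer(p[2]), integer(1))
    if (any(ends > nchar(doc$text)))
      stop("span offset beyond document end in: ", ln)
    if (label == "subject") {
      subjects[[length(subjects) + 1L]] <-
        soi_subject(doc$doc_id, starts[1], ends[1], provenance = provenance)
    } else {
      cues[[length(cues) + 1L]] <-
        soi_cue(doc$doc_id, starts, ends, category = .category_of(label),
                provenance = provenance)
    }
  }
  soi_annotated(doc, cues = cues, subjects = subjects)
}

#' Read a Knowtator XML annotation file
#'
#' Parses the standoff XML schema used by the Knowtator annotation tool:
#' \code{<annotation>} elements holding a mention reference, one or more
#' \code{<span>} elements and the spanned text, with \code{<classMention>}
#' elements mapping mentions to class names.  Class names are normalized
#' against the taxonomy: a narrow category id or name maps to that
#' category; a dictionary cue surface maps to a cue-level reference; an
#' annotation whose single span equals a sentence (or whose class is
#' "subject") becomes a subject.  Unknown class names do not abort parsing:
#' the annotation is kept with an \code{unknown_class:} placeholder and
#' reported.
#'
#' @param xml path to a Knowtator XML file (or XML string).
#' @param doc the companion \code{\link{soi_document}}.
#' @param tax an \code{ignorance_taxonomy} used to normalize class names.
#' @return list with \code{annotated} (a \code{\link{soi_annotated}}) and
#'   \code{unknown_classes} (character vector of unmapped class names).
#' @export
read_knowtator <- function(xml, doc, tax = default_taxonomy()) {
  stopifnot(inherits(doc, "soi_document"))
  x <- xml2::read_xml(xml)
  class_of <- new.env(parent = emptyenv())
  for (cm in xml2::xml_find_all(x, ".//classMention")) {
    id <- xml2::xml_attr(cm, "id")
    mc <- xml2::xml_find_first(cm, ".//mentionClass")
    cls <- xml2::xml_attr(mc, "id")
    if (is.na(cls)) cls <- xml2::xml_text(mc)
    assign(id, cls, envir = class_of)
  }
  normalize_class <- function(cls) {
    k <- tolower(gsub("[^a-z0-9]+", "_", tolower(cls)))
    k <- gsub("^_+|_+$", "", k)
    if (k == "subject") return("subject")
    ids <- tax$categories$id
    if (k %in% ids) return(k)
    nm <- gsub("[^a-z0-9]+", "_", tolower(tax$categories$name))
    hit <- match(k, nm)
    if (!is.na(hit)) return(ids[hit])
    key <- cue_key(gsub("_", " ", k, fixed = TRUE))
    if (nzchar(key) && exists(key, envir = tax$cue_index))
      return(paste0("cue:", key))
    NA_character_
  }
  cues <- list()
  subjects <- list()
  unknown <- character()
  for (ann in xml2::xml_find_all(x, ".//annotation")) {
    mention <- xml2::xml_attr(xml2::xml_find_first(ann, ".//mention"), "id")
    spans <- xml2::xml_find_all(ann, ".//span")
    if (!length(spans)) next
    starts <- as.integer(xml2::xml_attr(spans, "start"))
    ends <- as.integer(xml2::xml_attr(spans, "end"))
    if (any(is.na(starts)) || any(ends > nchar(doc$text)))
      stop("span offset out of range in Knowtator annotation")
    cls <- if (!is.na(mention) && exists(mention, envir = class_of))
      get(mention, envir = class_of) else NA_character_
    norm <- if (is.na(cls)) NA_character_ else normalize_class(cls)
    is_sentence <- length(starts) == 1L &&
      any(doc$sentences$start == starts[1] & doc$sentences$end == ends[1])
    if (identical(norm, "subject") || (is_sentence && is.na(norm))) {
      subjects[[length(subjects) + 1L]] <-
        soi_subject(doc$doc_id, starts[1], ends[1], provenance = "human")
      next
    }
    if (is.na(norm)) {
      unknown <- c(unknown, cls)
      norm <- paste0("unknown_class:", cls)
    }
    cues[[length(cues) + 1L]] <-
      soi_cue(doc$doc_id, starts, ends, category = norm,
              provenance = "human")
  }
  # one subject per sentence even if encoded twice
  if (length(subjects)) {
    keys <- vapply(subjects, function(s) s$start, integer(1))
    subjects <- subjects[!duplicated(keys)]
  }
  list(annotated = soi_annotated(doc, cues = cues, subjects = subjects),
       unknown_classes = unique(unknown))
}

#' Write a document/annotation pair to disk
#'
#' @param adoc a \code{\link{soi_annotated}}.
#' @param dir output directory.
#' @return paths of the \code{.txt} and \code{.ann} files, invisibly.
#' @export
write_doc_pair <- function(adoc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, adoc$document$doc_id)
  txt <- paste0(base, ".txt")
  ann <- paste0(base, ".ann")
  writeLines(adoc$document$text, txt, sep = "")
  write_standoff(adoc, ann)
  invisible(c(txt = txt, ann = ann))
}

#' Read a directory of .txt/.ann pairs
#'
#' @param dir directory containing \code{<id>.txt} and \code{<id>.ann}
#'   files.
#' @param provenance provenance recorded on the annotations.
#' @return list of \code{\link{soi_annotated}}, named by doc id.
#' @export
read_corpus_dir <- function(dir, provenance = "human") {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- list()
  for (txt in txts) {
    id <- sub("\\.txt$", "", basename(txt))
    text <- readChar(txt, file.size(txt), useBytes = TRUE)
    Encoding(text) <- "UTF-8"
    doc <- soi_document(id, text)
    ann <- file.path(dir, paste0(id, ".ann"))
    out[[id]] <- if (file.exists(ann))
      read_standoff(ann, doc, provenance = provenance)
    else soi_annotated(doc)
  }
  out
}
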