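#' Normalized dictionary key of a cue pattern
#'
#' Fragments are split on \code{"..."}, tokenized with the package
#' tokenizer and lowercased; tokens are joined by single spaces and
#' fragments by \code{" ... "}.  Two surfaces are the same dictionary cue
#' iff their keys are identical.
#'
#' @param pattern character vector of cue surfaces.
#' @return character vector of keys.
#' @export
cue_key <- function(pattern) {
  vapply(pattern, function(p) {
    frags <- strsplit(p, "...", fixed = TRUE)[[1]]
    frags <- frags[nzchar(trimws(frags))]
    paste(vapply(frags, function(f) paste(tokenize(f, lower = TRUE),
                                          collapse = " "), ""),
          collapse = " ... ")
  }, "", USE.NAMES = FALSE)
}

# fragments of a normalized key as a list of token vectors
key_fragments <- function(key) {
  frags <- strsplit(key, " ... ", fixed = TRUE)[[1]]
  strsplit(frags, " ", fixed = TRUE)
}

build_cue_index <- function(cues) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(cues))) {
    key <- cues$key[i]
    cats <- strsplit(cues$category_ids[i], ",", fixed = TRUE)[[1]]
    prev <- if (exists(key, envir = idx)) get(key, envir = idx) else character()
    assign(key, unique(c(prev, trimws(cats))), envir = idx)
  }
  idx
}

new_taxonomy <- function(categories, cues) {
  cues$key <- cue_key(cues$pattern)
  structure(list(categories = categories, cues = cues,
                 cue_index = build_cue_index(cues)),
            class = "ignorance_taxonomy")
}

#' Load an ignorance taxonomy
#'
#' Reads the two-table plain-text serialization: a categories TSV
#' (\code{id, name, level, parent, definition, knowledge_goal}) and a cues
#' TSV (\code{pattern, category_ids, source}); discontinuous cue patterns are
#' written with a literal \code{"..."} between fragments.  The loaded
#' taxonomy is validated and the load is rejected with an itemized report if
#' any invariant fails.
#'
#' @param path directory containing \code{ignorance_taxonomy_categories.tsv}
#'   and \code{ignorance_taxonomy_cues.tsv}, or a length-2 character vector
#'   \code{c(categories =, cues =)} of file paths.
#' @return an \code{ignorance_taxonomy}: list with \code{categories} and
#'   \code{cues} data frames plus a compiled case-insensitive cue index.
#' @seealso \code{\link{default_taxonomy}}, \code{\link{validate_taxonomy}}
#' @export
load_taxonomy <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    path <- c(categories = file.path(path, "ignorance_taxonomy_categories.tsv"),
              cues = file.path(path, "ignorance_taxonomy_cues.tsv"))
  }
  stopifnot(length(path) == 2L)
  if (is.null(names(path))) names(path) <- c("categories", "cues")
  for (p in path) if (!file.exists(p)) stop("no such file: ", p)
  categories <- utils::read.delim(path[["categories"]], sep = "\t",
                                  quote = "", stringsAsFactors = FALSE,
                                  colClasses = "character")
  cues <- utils::read.delim(path[["cues"]], sep = "\t", quote = "",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  need_cat <- c("id", "name", "level", "parent", "definition",
                "knowledge_goal")
  need_cue <- c("pattern", "category_ids", "source")
  if (!all(need_cat %in% names(categories)))
    stop("categories table must have columns: ",
         paste(need_cat, collapse = ", "))
  if (!all(need_cue %in% names(cues)))
    stop("cues table must have columns: ", paste(need_cue, collapse = ", "))
  tax <- new_taxonomy(categories, cues)
  viol <- validate_taxonomy(tax)
  if (length(viol))
    stop("taxonomy failed validation:\n  ",
         paste(viol, collapse = "\n  "))
  tax
}

#' Write a taxonomy back to its two-table TSV serialization
#'
#' \code{load_taxonomy(write_taxonomy(tax, dir))} reproduces \code{tax}.
#'
#' @param tax an \code{ignorance_taxonomy}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_taxonomy <- function(tax, dir) {
  stopifnot(inherits(tax, "ignorance_taxonomy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(tax$categories,
                     file.path(dir, "ignorance_taxonomy_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cues <- tax$cues[, c("pattern", "category_ids", "source")]
  utils::write.table(cues, file.path(dir, "ignorance_taxonomy_cues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' The packaged ignorance taxonomy
#'
#' Five broad knowledge-goal categories composed of 13 narrow ones, with the
#' lexical-cue dictionary.  "Question answered by this work" and
#' "Anomaly/curious finding" are both broad and narrow: they are stored once
#' at narrow level with a self-parent marker and counted at both levels.
#'
#' @return an \code{ignorance_taxonomy}.
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", package = "ignoranceNLP"))
}

#' Validate a taxonomy
#'
#' @param tax an \code{ignorance_taxonomy}.
#' @return character vector of violations (empty iff all invariants hold);
#'   each entry names the offending entity and the rule broken.
#' @export
validate_taxonomy <- function(tax) {
  v <- character()
  cat <- tax$categories
  dup <- unique(cat$id[duplicated(cat$id)])
  if (length(dup))
    v <- c(v, paste0("duplicate category id: ", dup))
  bad_level <- cat$id[!cat$level %in% c("broad", "narrow")]
  if (length(bad_level))
    v <- c(v, paste0("category ", bad_level,
                     ": level must be 'broad' or 'narrow'"))
  for (i in seq_len(nrow(cat))) {
    id <- cat$id[i]; parent <- cat$parent[i]; level <- cat$level[i]
    if (level == "broad") {
      if (nzchar(parent))
        v <- c(v, paste0("category ", id, ": broad category with a parent"))
    } else {
      if (!nzchar(parent)) {
        v <- c(v, paste0("category ", id, ": narrow category without parent"))
      } else if (!parent %in% cat$id) {
        v <- c(v, paste0("category ", id, ": parent '", parent,
                         "' does not exist"))
      } else if (parent != id &&
                 cat$level[match(parent, cat$id)] != "broad") {
        v <- c(v, paste0("category ", id,
                         ": parent must be broad or the category itself ",
                         "(dual-level); cycle through narrow categories"))
      }
    }
  }
  for (i in seq_len(nrow(tax$cues))) {
    pat <- tax$cues$pattern[i]
    if (!nzchar(tax$cues$key[i])) {
      v <- c(v, paste0("cue '", pat, "': empty fragment list"))
      next
    }
    cats <- trimws(strsplit(tax$cues$category_ids[i], ",")[[1]])
    if (!length(cats))
      v <- c(v, paste0("cue '", pat, "': no categories"))
    for (cid in cats) {
      j <- match(cid, cat$id)
      if (is.na(j))
        v <- c(v, paste0("cue '", pat, "': references nonexistent category '",
                         cid, "'"))
      else if (cat$level[j] != "narrow")
        v <- c(v, paste0("cue '", pat, "': category '", cid,
                         "' is not narrow-level"))
    }
  }
  v
}

#' Narrow / broad category counts
#'
#' Dual-level categories (narrow with self-parent) count at both levels.
#'
#' @param tax an \code{ignorance_taxonomy}.
#' @return named integer vector \code{c(broad =, narrow =)}.
#' @export
taxonomy_counts <- function(tax) {
  cat <- tax$categories
  n_narrow <- sum(cat$level == "narrow")
  n_broad <- sum(cat$level == "broad") +
    sum(cat$level == "narrow" & cat$parent == cat$id)
  c(broad = n_broad, narrow = n_narrow)
}

#' Narrow category ids
#' @param tax an \code{ignorance_taxonomy}.
#' @return character vector of narrow-level category ids, in table order.
#' @export
narrow_categories <- function(tax)
  tax$categories$id[tax$categories$level == "narrow"]

#' Dictionary categories of a cue surface
#'
#' Case-insensitive lookup of a (possibly discontinuous, \code{"..."}
#' separated) surface form in the cue dictionary.
#'
#' @param tax an \code{ignorance_taxonomy}.
#' @param surface cue surface, e.g. \code{"UNKNOWN"} or
#'   \code{"no ... exist"}.
#' @return character vector of narrow-category ids (length 0 when the
#'   surface is not a dictionary cue; length > 1 for ambiguous cues).
#' @export
categories_for_cue <- function(tax, surface) {
  key <- cue_key(surface)
  if (!nzchar(key) || !exists(key, envir = tax$cue_index)) return(character())
  get(key, envir = tax$cue_index)
}

# ---- subsumption -----------------------------------------------------------

# A reference is a broad id, a narrow id, or a cue ("cue:<key>" or any
# dictionary surface).  Returns list(kind, id, ancestors) where ancestors is
# the chain above the reference (excluding itself), or NULL if unknown.
resolve_ref <- function(tax, ref) {
  stopifnot(is.character(ref), length(ref) == 1L)
  cat <- tax$categories
  if (startsWith(ref, "cue:")) key <- cue_key(substring(ref, 5L))
  else if (ref %in% cat$id) {
    i <- match(ref, cat$id)
    if (cat$level[i] == "broad")
      return(list(kind = "broad", id = ref, ancestors = character()))
    parent <- cat$parent[i]
    anc <- if (nzchar(parent) && parent != ref) parent else character()
    return(list(kind = "narrow", id = ref, ancestors = anc))
  } else key <- cue_key(ref)
  if (nzchar(key) && exists(key, envir = tax$cue_index)) {
    cats <- get(key, envir = tax$cue_index)
    anc <- cats
    for (cid in cats) {
      i <- match(cid, cat$id)
      if (!is.na(i) && nzchar(cat$parent[i]) && cat$parent[i] != cid)
        anc <- c(anc, cat$parent[i])
    }
    return(list(kind = "cue", id = paste0("cue:", key),
                ancestors = unique(anc)))
  }
  NULL
}

#' The narrower of two taxonomy references
#'
#' Adjudication rule: when two annotations differ only in specificity (one
#' subsumes the other along a root-to-leaf path, where a specific lexical cue
#' counts as a leaf under each of its categories), keep the more specific
#' reference.  Incomparable pairs are signalled with a condition of class
#' \code{soi_incomparable} so callers can route them to human adjudication.
#'
#' @param tax an \code{ignorance_taxonomy}.
#' @param a,b category ids or cue references (\code{"cue:<pattern>"} or a
#'   dictionary surface form).
#' @return the deeper of the two references (canonicalized: cues as
#'   \code{"cue:<key>"}).
#' @export
narrowest <- function(tax, a, b) {
  ra <- resolve_ref(tax, a)
  rb <- resolve_ref(tax, b)
  if (is.null(ra)) stop("unknown reference: ", a)
  if (is.null(rb)) stop("unknown reference: ", b)
  if (identical(ra$id, rb$id)) return(ra$id)
  if (ra$id %in% rb$ancestors) return(rb$id)
  if (rb$id %in% ra$ancestors) return(ra$id)
  stop(structure(class = c("soi_incomparable", "error", "condition"),
                 list(message = paste0("references '", ra$id, "' and '",
                                       rb$id,
                                       "' do not lie on one root-to-leaf ",
                                       "path; flag for adjudication"),
                      call = sys.call())))
}

#' Merge an external cue list into a taxonomy
#'
#' Cues are merged by (fragments, category) identity; duplicates collapse so
#' unique-cue counts are unaffected by re-imports.
#'
#' @param tax an \code{ignorance_taxonomy}.
#' @param cues data.frame with \code{pattern} and \code{category_ids}
#'   columns (comma-separated ids), or path to such a TSV.
#' @param source provenance label recorded on the new entries.
#' @return the updated \code{ignorance_taxonomy}.
#' @export
import_cue_list <- function(tax, cues, source = "imported") {
  if (is.character(cues))
    cues <- utils::read.delim(cues, sep = "\t", quote = "",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  stopifnot(all(c("pattern", "category_ids") %in% names(cues)))
  add <- data.frame(pattern = cues$pattern,
                    category_ids = cues$category_ids,
                    source = source, stringsAsFactors = FALSE)
  # explode to (key, category) pairs, drop pairs already present
  all_cues <- rbind(tax$cues[, c("pattern", "category_ids", "source")], add)
  key <- cue_key(all_cues$pattern)
  seen <- new.env(parent = emptyenv())
  keep <- logical(nrow(all_cues))
  out <- all_cues
  for (i in seq_len(nrow(all_cues))) {
    cats <- trimws(strsplit(all_cues$category_ids[i], ",")[[1]])
    new_cats <- character()
    for (cid in cats) {
      pair <- paste0(key[i], "\r", cid)
      if (!exists(pair, envir = seen)) {
        assign(pair, TRUE, envir = seen)
        new_cats <- c(new_cats, cid)
      }
    }
    keep[i] <- length(new_cats) > 0L
    out$category_ids[i] <- paste(new_cats, collapse = ",")
  }
  tax2 <- new_taxonomy(tax$categories, out[keep, , drop = FALSE])
  viol <- validate_taxonomy(tax2)
  if (length(viol))
    stop("imported cue list failed validation:\n  ",
         paste(viol, collapse = "\n  "))
  tax2
}

#' @export
print.ignorance_taxonomy <- function(x, ...) {
  n <- taxonomy_counts(x)
  cat("<ignorance_taxonomy> ", n[["broad"]], " broad / ", n[["narrow"]],
      " narrow categories, ", nrow(x$cues), " cue patterns\n", sep = "")
  invisible(x)
}
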