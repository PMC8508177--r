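# Filler vocabulary for synthetic articles.  Deliberately disjoint from every
# token occurring in the packaged cue dictionary (asserted in the test suite)
# so that filler text can never complete a dictionary cue.
.neutral_words <- c(
  "cohort", "participants", "serum", "ferritin", "iodine", "selenium",
  "zinc", "folate", "riboflavin", "infants", "mothers", "trimester",
  "gestation", "sampling", "aliquots", "concentrations", "registry",
  "villages", "clinics", "households", "questionnaires", "midwives",
  "anthropometry", "birthweight", "placenta", "biomarkers", "centrifuge",
  "freezer", "dietary", "intake", "records", "visits", "enrolment",
  "protocol", "fieldwork", "laboratory", "storage", "transport", "season",
  "harvest", "kitchens", "markets", "supplements", "capsules", "tablets")

.neutral_function <- c("in", "with", "from", "and", "were", "was",
                       "at", "during", "between", "across", "within",
                       "per", "two", "three", "four", "several")

# Negative-context sentences: a cue lexeme occurs but the sentence is not a
# statement of ignorance, so it carries no gold annotation.
.decoy_templates <- c(
  "Although yin and yang are contradictory in nature, they depend on each other for existence.",
  "To make inference, the maximum likelihood method is applied to estimate the unknown parameters in the empirical log-odds ratio models.",
  "The error bars in the calibration figure denote one standard deviation.",
  "The assay protocol will saturate at high ligand concentrations.",
  "Participants tend the communal gardens during the wet season.",
  "The support brackets of the centrifuge were replaced before sampling.")

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the annotated-corpus conditions the pipeline assumes:
#' 60 articles of roughly 120 sentences; about half of all sentences carry
#' a cue and become subjects (planting rate 0.04 over 13 categories); cue
#' choice within a category is skewed geometrically, mirroring the heavy
#' reuse of a few cues in real corpora; a modest fraction of cues are
#' discontinuous; section headers on.
#'
#' @param n_documents number of articles.
#' @param sentences_range inclusive range of sentences per article
#'   (excluding section header lines).
#' @param planting_rate per-category probability that a sentence receives a
#'   cue of that category (at most one category fires per sentence, plus
#'   the multi-cue fraction); scalar or named vector over narrow
#'   categories.
#' @param decoy_rate probability that a cue-free sentence becomes a
#'   negative-context decoy (cue lexeme present, no annotation).
#' @param discontinuous_fraction probability that a planted cue is drawn
#'   from the discontinuous patterns of its category (falls back to a
#'   contiguous cue when the category has none).
#' @param multi_cue_fraction probability that a sentence with exactly one
#'   planted cue receives a second cue of another category.
#' @param novel_cue_rate probability that a planted contiguous cue is
#'   replaced by a perturbed variant (pluralized last token) absent from the
#'   dictionary but still gold-annotated; exercises novel-cue discovery.
#' @param sections insert the six standard section headers?
#' @param gap_limit maximum filler tokens planted inside a discontinuity.
#' @param seed RNG seed (mandatory).
#' @return list of class \code{soi_generator_config}.
#' @export
generator_config <- function(n_documents = 60L,
                             sentences_range = c(100L, 140L),
                             planting_rate = 0.04,
                             decoy_rate = 0.05,
                             discontinuous_fraction = 0.15,
                             multi_cue_fraction = 0.1,
                             novel_cue_rate = 0,
                             sections = TRUE,
                             gap_limit = 3L,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  rates <- c(planting_rate, decoy_rate, discontinuous_fraction,
             multi_cue_fraction, novel_cue_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  stopifnot(n_documents >= 1L, length(sentences_range) == 2L,
            sentences_range[1] <= sentences_range[2], gap_limit >= 1L)
  structure(list(n_documents = as.integer(n_documents),
                 sentences_range = as.integer(sentences_range),
                 planting_rate = planting_rate, decoy_rate = decoy_rate,
                 discontinuous_fraction = discontinuous_fraction,
                 multi_cue_fraction = multi_cue_fraction,
                 novel_cue_rate = novel_cue_rate,
                 sections = isTRUE(sections),
                 gap_limit = as.integer(gap_limit),
                 seed = as.integer(seed)),
            class = "soi_generator_config")
}

# cue pools by primary (first-listed) category; punctuation-only patterns
# (the explicit-question "?") are matchable but never planted as a
# sentence's sole marker, since sentence-level features are word-based
.cue_pools <- function(tax) {
  keys <- ls(tax$cue_index)
  keys <- keys[grepl("[a-z0-9]", keys)]
  primary <- vapply(keys, function(k) get(k, envir = tax$cue_index)[1], "")
  disc <- vapply(keys, function(k) length(key_fragments(k)) > 1L, logical(1))
  list(keys = keys, primary = primary, disc = disc)
}

# build one planted sentence; returns list(text, cues = list of
# list(rel_starts, rel_ends, category, key, novel))
.build_sentence <- function(planted, cfg) {
  words <- function(n) {
    pool <- c(.neutral_words, .neutral_function)
    sample(pool, n, replace = TRUE)
  }
  parts <- character()   # tokens
  cue_pos <- list()      # per planted cue: token index vector per fragment
  add <- function(tok) parts <<- c(parts, tok)
  add(words(sample(2:5, 1)))
  for (ci in seq_along(planted)) {
    p <- planted[[ci]]
    frags <- key_fragments(p$key)
    if (isTRUE(p$novel)) {
      last <- frags[[length(frags)]]
      last[length(last)] <- paste0(last[length(last)], "s")
      frags[[length(frags)]] <- last
    }
    idx <- list()
    for (fi in seq_along(frags)) {
      if (fi > 1L) add(words(sample(seq_len(cfg$gap_limit), 1)))
      start <- length(parts) + 1L
      add(frags[[fi]])
      idx[[fi]] <- seq(start, length(parts))
    }
    cue_pos[[ci]] <- idx
    add(words(sample(2:4, 1)))
  }
  # character offsets: tokens joined by single spaces, capital first letter,
  # terminal period
  parts[1] <- paste0(toupper(substr(parts[1], 1, 1)),
                     substring(parts[1], 2))
  off <- cumsum(c(0L, nchar(parts) + 1L))  # token start offsets
  text <- paste0(paste(parts, collapse = " "), ".")
  cues <- lapply(seq_along(planted), function(ci) {
    idx <- cue_pos[[ci]]
    rel_starts <- vapply(idx, function(ix) off[ix[1]], integer(1))
    rel_ends <- vapply(idx, function(ix)
      off[ix[length(ix)]] + nchar(parts[ix[length(ix)]]), integer(1))
    list(rel_starts = rel_starts, rel_ends = rel_ends,
         category = planted[[ci]]$category, key = planted[[ci]]$key,
         novel = isTRUE(planted[[ci]]$novel))
  })
  list(text = text, cues = cues)
}

#' Generate a synthetic annotated corpus
#'
#' Seeded generator of synthetic articles with the structure the pipeline
#' assumes: filler sentences from a neutral template bank, planted sentences
#' embedding dictionary cues verbatim (discontinuous cues receive 1 to
#' \code{gap_limit} filler tokens inside the gap), decoy sentences containing
#' a cue lexeme without an annotation, and optional section headers.  Gold
#' annotations are exactly the planted cues plus one full-sentence subject
#' per planted sentence; a ledger records every planting decision.
#'
#' @param config a \code{\link{generator_config}}.
#' @param tax an \code{ignorance_taxonomy}.
#' @return list of class \code{soi_corpus} with \code{docs} (list of
#'   \code{\link{soi_annotated}}), \code{ledger} (data.frame of planting
#'   decisions) and \code{config}.
#' @export
simulate_corpus <- function(config, tax = default_taxonomy()) {
  stopifnot(inherits(config, "soi_generator_config"),
            inherits(tax, "ignorance_taxonomy"))
  set.seed(config$seed)
  pools <- .cue_pools(tax)
  cats <- narrow_categories(tax)
  if (!length(cats)) stop("taxonomy has no narrow categories")
  rate <- config$planting_rate
  if (length(rate) == 1L) rate <- stats::setNames(rep(rate, length(cats)),
                                                  cats)
  if (config$discontinuous_fraction > 0 && !any(pools$disc))
    stop("discontinuous planting requested but the taxonomy has no ",
         "discontinuous cue")

  pick_cue <- function(cat) {
    want_disc <- stats::runif(1) < config$discontinuous_fraction
    in_cat <- pools$keys[pools$primary == cat]
    if (!length(in_cat)) return(NULL)
    disc_in_cat <- in_cat[pools$disc[match(in_cat, pools$keys)]]
    pool <- if (want_disc && length(disc_in_cat)) disc_in_cat else
      in_cat[!pools$disc[match(in_cat, pools$keys)]]
    if (!length(pool)) pool <- in_cat
    # cue reuse in real corpora is heavily skewed: a handful of cues carry
    # most annotations and over half the dictionary never occurs at all, so
    # draw with geometrically decaying weight by within-category rank
    key <- if (length(pool) == 1L) pool else
      sample(pool, 1L, prob = 0.6^seq_along(pool))
    novel <- !key %in% disc_in_cat && config$novel_cue_rate > 0 &&
      stats::runif(1) < config$novel_cue_rate
    list(key = key, category = cat, novel = novel)
  }

  docs <- list()
  ledger <- list()
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc%03d", d)
    n_sent <- config$sentences_range[1] +
      sample.int(config$sentences_range[2] - config$sentences_range[1] + 1L,
                 1L) - 1L
    sent_text <- character(n_sent)
    sent_cues <- vector("list", n_sent)
    sent_type <- character(n_sent)
    for (s in seq_len(n_sent)) {
      # at most one planted category per sentence, except a multi_cue
      # fraction which receive a second category; P(category c) = rate[c]
      p_plant <- min(sum(rate[cats]), 1)
      fire <- character()
      if (stats::runif(1) < p_plant) {
        fire <- sample(cats, 1L, prob = rate[cats])
        if (stats::runif(1) < config$multi_cue_fraction)
          fire <- c(fire, sample(setdiff(cats, fire), 1L))
      }
      planted <- Filter(Negate(is.null), lapply(fire, pick_cue))
      if (length(planted)) {
        built <- .build_sentence(planted, config)
        sent_text[s] <- built$text
        sent_cues[[s]] <- built$cues
        sent_type[s] <- "planted"
      } else if (stats::runif(1) < config$decoy_rate) {
        sent_text[s] <- sample(.decoy_templates, 1L)
        sent_cues[[s]] <- list()
        sent_type[s] <- "decoy"
      } else {
        built <- .build_sentence(list(), config)
        sent_text[s] <- built$text
        sent_cues[[s]] <- list()
        sent_type[s] <- "filler"
      }
    }
    # assemble document text; record absolute sentence offsets
    section_of <- rep(NA_character_, n_sent)
    text <- ""
    sent_start <- integer(n_sent)
    if (config$sections) {
      bounds <- round(seq(0, n_sent, length.out = 7L))
      for (sec in seq_len(6L)) {
        text <- paste0(text, .section_names[sec], "\n")
        lo <- bounds[sec] + 1L; hi <- bounds[sec + 1L]
        for (s in seq_len(n_sent)[seq_len(n_sent) >= lo &
                                    seq_len(n_sent) <= hi]) {
          section_of[s] <- .section_names[sec]
          sent_start[s] <- nchar(text)
          text <- paste0(text, sent_text[s], "\n")
        }
      }
    } else {
      for (s in seq_len(n_sent)) {
        sent_start[s] <- nchar(text)
        text <- paste0(text, sent_text[s], "\n")
      }
    }
    doc <- soi_document(doc_id, text, sections = config$sections)
    cues <- list()
    subjects <- list()
    for (s in seq_len(n_sent)) {
      for (cu in sent_cues[[s]]) {
        cues[[length(cues) + 1L]] <-
          soi_cue(doc_id, sent_start[s] + cu$rel_starts,
                  sent_start[s] + cu$rel_ends, category = cu$category,
                  provenance = "human")
        ledger[[length(ledger) + 1L]] <-
          data.frame(doc_id = doc_id, sentence = s,
                     section = section_of[s], type = "planted",
                     category = cu$category, cue = cu$key,
                     discontinuous = length(cu$rel_starts) > 1L,
                     novel = cu$novel, stringsAsFactors = FALSE)
      }
      if (length(sent_cues[[s]])) {
        subjects[[length(subjects) + 1L]] <-
          soi_subject(doc_id, sent_start[s],
                      sent_start[s] + nchar(sent_text[s]),
                      provenance = "human")
      } else if (sent_type[s] == "decoy") {
        ledger[[length(ledger) + 1L]] <-
          data.frame(doc_id = doc_id, sentence = s,
                     section = section_of[s], type = "decoy",
                     category = NA_character_, cue = NA_character_,
                     discontinuous = FALSE, novel = FALSE,
                     stringsAsFactors = FALSE)
      }
    }
    docs[[doc_id]] <- soi_annotated(doc, cues = cues, subjects = subjects)
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(doc_id = character(), sentence = integer(),
               section = character(), type = character(),
               category = character(), cue = character(),
               discontinuous = logical(), novel = logical(),
               stringsAsFactors = FALSE)
  structure(list(docs = docs, ledger = ledger, config = config),
            class = "soi_corpus")
}

#' @export
print.soi_corpus <- function(x, ...) {
  cat("<soi_corpus> ", length(x$docs), " documents, ",
      sum(x$ledger$type == "planted"), " planted cues, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus to .txt/.ann pairs plus a JSON ledger
#'
#' @param corpus a \code{\link{simulate_corpus}} result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "soi_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ad in corpus$docs) write_doc_pair(ad, dir)
  jsonlite::write_json(
    list(config = unclass(corpus$config), ledger = corpus$ledger),
    file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
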