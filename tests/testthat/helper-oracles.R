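# Independent oracles used by the unit tests.  These deliberately avoid the
# package's own implementation paths: the tokenizer oracle is a character
# scan, the matcher oracle enumerates token windows, the matching oracle is
# an exhaustive maximum-bipartite search.

# character-class scanner equivalent to the normative tokenizer
oracle_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  cls <- function(ch) {
    if (grepl("[A-Za-z0-9]", ch)) "w"
    else if (grepl("\\s", ch)) "s"
    else "p"
  }
  toks <- character()
  starts <- integer()
  cur <- ""
  cur_cls <- ""
  cur_start <- 0L
  flush <- function() {
    if (nzchar(cur) && cur_cls != "s") {
      toks <<- c(toks, cur)
      starts <<- c(starts, cur_start)
    }
    cur <<- ""
  }
  for (i in seq_along(chars)) {
    k <- cls(chars[i])
    if (k != cur_cls) {
      flush()
      cur_cls <- k
      cur_start <- i - 1L
    }
    cur <- paste0(cur, chars[i])
  }
  flush()
  data.frame(start = starts, end = starts + nchar(toks), text = toks,
             stringsAsFactors = FALSE)
}

# brute-force dictionary matcher: enumerate all windows / fragment
# placements per sentence, then apply longest-contiguous-at-start and
# earliest-placement rules
oracle_match_cues <- function(doc, tax, gap_limit = 10L) {
  dict <- ls(tax$cue_index)
  frag_list <- lapply(dict, ignoranceNLP:::key_fragments)
  out <- list()
  for (si in unique(doc$tokens$sentence)) {
    rows <- which(doc$tokens$sentence == si)
    toks <- tolower(doc$tokens$text[rows])
    n <- length(toks)
    # all contiguous windows that are dictionary cues
    contig <- list()
    for (i in seq_len(n)) for (j in i:n) {
      key <- paste(toks[i:j], collapse = " ")
      if (key %in% dict && length(frag_list[[match(key, dict)]]) == 1L)
        contig[[length(contig) + 1L]] <- list(i = i, j = j, key = key)
    }
    for (i in seq_len(n)) {
      here <- Filter(function(w) w$i == i, contig)
      if (!length(here)) next
      best <- here[[which.max(vapply(here, function(w) w$j, 1L))]]
      out[[length(out) + 1L]] <-
        list(sentence = si, key = best$key,
             frags = list(c(best$i, best$j)))
    }
    # discontinuous cues: enumerate every in-order placement, keep the
    # lexicographically earliest per first-fragment position
    for (d in seq_along(dict)) {
      frags <- frag_list[[d]]
      if (length(frags) < 2L) next
      occ <- lapply(frags, function(f) {
        hits <- integer()
        L <- length(f)
        if (L <= n) for (i in seq_len(n - L + 1L))
          if (all(toks[i:(i + L - 1L)] == f)) hits <- c(hits, i)
        hits
      })
      if (any(lengths(occ) == 0L)) next
      grid <- expand.grid(rev(occ))  # rev so first fragment varies slowest
      grid <- grid[, rev(seq_along(occ)), drop = FALSE]
      ok <- apply(grid, 1L, function(g) {
        ends <- g + lengths(frags) - 1L
        all(diff(g) > 0) &&
          all(g[-1L] - ends[-length(ends)] - 1L >= 0) &&
          all(g[-1L] - ends[-length(ends)] - 1L <= gap_limit) &&
          all(g[-1L] > ends[-length(ends)])
      })
      grid <- grid[ok, , drop = FALSE]
      if (!nrow(grid)) next
      for (i1 in unique(grid[, 1])) {
        sub <- grid[grid[, 1] == i1, , drop = FALSE]
        sub <- sub[do.call(order, as.data.frame(sub)), , drop = FALSE]
        g <- as.integer(sub[1, ])
        out[[length(out) + 1L]] <-
          list(sentence = si, key = dict[d],
               frags = Map(function(s, f) c(s, s + length(f) - 1L),
                           g, frags))
      }
    }
  }
  out
}

# canonical key for comparing matcher output to the oracle
match_signature <- function(doc, cues) {
  sort(vapply(cues, function(cu)
    paste(cu$doc_id, paste(cu$starts, cu$ends, collapse = ";")), ""))
}

oracle_signature <- function(doc, oracle_out) {
  sort(vapply(oracle_out, function(m) {
    rows <- which(doc$tokens$sentence == m$sentence)
    starts <- vapply(m$frags, function(fr) doc$tokens$start[rows[fr[1]]], 1L)
    ends <- vapply(m$frags, function(fr) doc$tokens$end[rows[fr[2]]], 1L)
    paste(doc$doc_id, paste(starts, ends, collapse = ";"))
  }, ""))
}

# exhaustive maximum one-to-one matching size
oracle_max_matching <- function(comp) {
  nA <- nrow(comp)
  rec <- function(i, used) {
    if (i > nA) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(comp[i, ])) {
      if (used[j]) next
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  if (nA == 0L || ncol(comp) == 0L) return(0L)
  rec(1L, rep(FALSE, ncol(comp)))
}

# random cue-annotation set over a one-sentence token grid, for agreement
# oracle tests
random_cue_set <- function(doc, n, cats, p_cue_ref = 0.2) {
  toks <- doc$tokens
  lapply(seq_len(n), function(i) {
    a <- sample(nrow(toks) - 2L, 1L)
    b <- a + sample(0:2, 1L)
    c2 <- b + sample(2:3, 1L)
    if (runif(1) < 0.3 && c2 <= nrow(toks)) {  # discontinuous
      starts <- c(toks$start[a], toks$start[c2])
      ends <- c(toks$end[b], toks$end[c2])
    } else {
      starts <- toks$start[a]
      ends <- toks$end[b]
    }
    soi_cue(doc$doc_id, starts, ends, category = sample(cats, 1L))
  })
}

# small fixed-seed synthetic corpus shared by several test files; unit
# tests use short documents to stay fast (the generator default emulates
# full-length articles)
make_test_corpus <- function(seed = 42L, n_documents = 6L, decoy_rate = 0,
                             sections = TRUE,
                             sentences_range = c(12L, 20L), ...) {
  simulate_corpus(generator_config(n_documents = n_documents,
                                   decoy_rate = decoy_rate,
                                   sections = sections, seed = seed,
                                   sentences_range = sentences_range, ...))
}
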