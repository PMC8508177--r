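# ---- token features --------------------------------------------------------

# Feature template for the linear-chain tagger.  All features are computable
# from the document alone (no gold leakage): lowercased form, prefixes and
# suffixes of length 1-3, punctuation-run flag, capitalization, neighbour
# forms in a +/-2 window, sentence-initial flag.
token_features <- function(tokens, sentence_ids) {
  lower <- tolower(tokens)
  n <- length(tokens)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    w <- lower[t]
    f <- c(paste0("w0=", w),
           paste0("p", 1:min(3L, nchar(w)), "=",
                  substring(w, 1L, 1:min(3L, nchar(w)))),
           paste0("s", 1:min(3L, nchar(w)), "=",
                  substring(w, nchar(w) - (1:min(3L, nchar(w))) + 1L,
                            nchar(w))))
    if (!grepl("[a-z0-9]", w)) f <- c(f, "punct")
    if (grepl("^[A-Z]", tokens[t])) f <- c(f, "cap")
    if (t == 1L || sentence_ids[t] != sentence_ids[t - 1L]) f <- c(f, "init")
    for (d in c(-2L, -1L, 1L, 2L)) {
      u <- t + d
      val <- if (u >= 1L && u <= n && sentence_ids[u] == sentence_ids[t])
        lower[u] else "<PAD>"
      f <- c(f, paste0("w", ifelse(d > 0, "+", ""), d, "=", val))
    }
    out[[t]] <- f
  }
  out
}

# map feature strings to indices; when frozen=TRUE unknown features drop out.
# A ".__n" binding in the map holds the running feature count.
index_features <- function(feat_lists, featmap, frozen = FALSE) {
  if (!exists(".__n", envir = featmap)) assign(".__n", 0L, envir = featmap)
  idx <- vector("list", length(feat_lists))
  for (t in seq_along(feat_lists)) {
    f <- feat_lists[[t]]
    ix <- integer(length(f))
    for (k in seq_along(f)) {
      key <- f[k]
      if (exists(key, envir = featmap)) {
        ix[k] <- get(key, envir = featmap)
      } else if (frozen) {
        ix[k] <- NA_integer_
      } else {
        n <- get(".__n", envir = featmap) + 1L
        assign(".__n", n, envir = featmap)
        assign(key, n, envir = featmap)
        ix[k] <- n
      }
    }
    idx[[t]] <- ix[!is.na(ix)]
  }
  idx
}

n_feat <- function(featmap)
  if (exists(".__n", envir = featmap)) get(".__n", envir = featmap) else 0L

feature_matrix <- function(feat_idx, n_features) {
  ii <- rep(seq_along(feat_idx), lengths(feat_idx))
  jj <- unlist(feat_idx, use.names = FALSE)
  if (!length(jj))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(feat_idx), n_features)))
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(feat_idx), n_features))
}

lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }

# ---- linear-chain CRF ------------------------------------------------------

crf_unpack <- function(par, L, F_) {
  W <- matrix(par[seq_len(L * F_)], nrow = L)
  off <- L * F_
  Trans <- matrix(par[off + seq_len(L * L)], nrow = L)
  off <- off + L * L
  list(W = W, Trans = Trans,
       start = par[off + seq_len(L)], stop = par[off + L + seq_len(L)])
}

# negative log-likelihood and gradient over all sequences
crf_nll_grad <- function(par, X, y, seqs, L, l2) {
  F_ <- ncol(X)
  pp <- crf_unpack(par, L, F_)
  E <- as.matrix(X %*% t(pp$W))   # n_tokens x L emission scores
  nll <- 0
  M <- matrix(0, nrow(E), L)      # token marginals
  gTrans <- matrix(0, L, L)
  gStart <- numeric(L); gStop <- numeric(L)
  for (sq in seqs) {
    Tn <- length(sq)
    e <- E[sq, , drop = FALSE]
    a <- matrix(0, Tn, L)
    a[1, ] <- pp$start + e[1, ]
    if (Tn > 1L) for (t in 2:Tn) {
      S <- a[t - 1L, ] + pp$Trans      # recycles a over columns: S[i,j]
      mx <- apply(S, 2L, max)
      a[t, ] <- e[t, ] + mx + log(colSums(exp(sweep(S, 2L, mx))))
    }
    logZ <- lse(a[Tn, ] + pp$stop)
    b <- matrix(0, Tn, L)
    b[Tn, ] <- pp$stop
    if (Tn > 1L) for (t in (Tn - 1L):1L) {
      S <- sweep(pp$Trans, 2L, e[t + 1L, ] + b[t + 1L, ], `+`)
      mx <- apply(S, 1L, max)
      b[t, ] <- mx + log(rowSums(exp(S - mx)))
    }
    M[sq, ] <- exp(a + b - logZ)
    yy <- y[sq]
    gold <- pp$start[yy[1]] + sum(e[cbind(seq_len(Tn), yy)]) + pp$stop[yy[Tn]]
    if (Tn > 1L) {
      gold <- gold + sum(pp$Trans[cbind(yy[-Tn], yy[-1L])])
      for (t in seq_len(Tn - 1L)) {
        P <- exp(outer(a[t, ], e[t + 1L, ] + b[t + 1L, ], `+`) +
                   pp$Trans - logZ)
        gTrans <- gTrans + P
        gTrans[yy[t], yy[t + 1L]] <- gTrans[yy[t], yy[t + 1L]] - 1
      }
    }
    nll <- nll + logZ - gold
    gStart <- gStart + M[sq[1], ]
    gStart[yy[1]] <- gStart[yy[1]] - 1
    gStop <- gStop + M[sq[Tn], ]
    gStop[yy[Tn]] <- gStop[yy[Tn]] - 1
  }
  D <- M
  D[cbind(seq_along(y), y)] <- D[cbind(seq_along(y), y)] - 1
  gW <- t(as.matrix(Matrix::crossprod(X, D)))   # L x F
  grad <- c(as.numeric(gW), as.numeric(gTrans), gStart, gStop) + l2 * par
  list(nll = nll + l2 / 2 * sum(par^2), grad = grad)
}

crf_fit <- function(X, y, seqs, L, l2 = 1.0, maxit = 80L) {
  n_par <- L * ncol(X) + L * L + 2L * L
  cache <- new.env(parent = emptyenv())
  evalpt <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    val <- crf_nll_grad(par, X, y, seqs, L, l2)
    cache$par <- par; cache$val <- val
    val
  }
  opt <- stats::optim(rep(0, n_par),
                      fn = function(p) evalpt(p)$nll,
                      gr = function(p) evalpt(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e9))
  opt$par
}

crf_viterbi <- function(pp, E, seqs, labels) {
  out <- character(nrow(E))
  L <- length(labels)
  for (sq in seqs) {
    Tn <- length(sq)
    e <- E[sq, , drop = FALSE]
    v <- matrix(-Inf, Tn, L)
    bp <- matrix(0L, Tn, L)
    v[1, ] <- pp$start + e[1, ]
    if (Tn > 1L) for (t in 2:Tn) {
      S <- v[t - 1L, ] + pp$Trans
      bp[t, ] <- max.col(t(S), ties.method = "first")
      v[t, ] <- e[t, ] + S[cbind(bp[t, ], seq_len(L))]
    }
    last <- which.max(v[Tn, ] + pp$stop)
    path <- integer(Tn)
    path[Tn] <- last
    if (Tn > 1L) for (t in Tn:2L) path[t - 1L] <- bp[t, path[t]]
    out[sq] <- labels[path]
  }
  out
}

# ---- user-facing tagger ----------------------------------------------------

# encode gold tags for a scheme; per_category restricts to one category
.scheme_tags <- function(ad, scheme, category) {
  switch(scheme,
         binary = bio_encode(ad, "binary"),
         per_category = bio_encode(ad, "per_category",
                                   categories = category),
         combined = bio_encode(ad, "per_category"))
}

#' Train a word-level sequence tagger
#'
#' Fits a linear-chain conditional random field over B/I/O/O- tag
#' sequences: binary (any cue), per-category (one category's cues only), or
#' combined multiclass (category-suffixed tags).  Features are the package
#' token template (form, affixes, neighbours, shape flags); optimization is
#' L-BFGS on the penalized log-likelihood with an L2 penalty; training is
#' deterministic (zero initialization).
#'
#' @param docs list of \code{\link{soi_annotated}} training documents (or a
#'   \code{soi_corpus}).
#' @param scheme \code{"binary"}, \code{"per_category"} or
#'   \code{"combined"}.
#' @param category narrow category id (required for
#'   \code{scheme = "per_category"}).
#' @param l2 L2 penalty weight.
#' @param maxit optimizer iteration cap.
#' @param seed recorded for provenance; the fit itself is
#'   deterministic.
#' @return object of class \code{tagger_model} (kind
#'   \code{"linear_chain_crf"}); alternative taggers can be plugged in by
#'   providing the same class contract (fields \code{labels},
#'   \code{predict_tags} method).
#' @export
train_tagger <- function(docs, scheme = c("binary", "per_category",
                                          "combined"),
                         category = NULL, l2 = 1.0, maxit = 80L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (inherits(docs, "soi_corpus")) docs <- docs$docs
  if (!length(docs)) stop("empty training set")
  if (scheme == "per_category" && is.null(category))
    stop("per_category scheme needs a category")
  featmap <- new.env(parent = emptyenv(), hash = TRUE)
  feat_idx <- list(); y_chr <- character(); seqs <- list()
  offset <- 0L
  for (ad in docs) {
    doc <- ad$document
    if (!nrow(doc$tokens)) next
    tags <- .scheme_tags(ad, scheme, category)$tags
    fl <- token_features(doc$tokens$text, doc$tokens$sentence)
    feat_idx <- c(feat_idx, index_features(fl, featmap))
    y_chr <- c(y_chr, tags)
    for (si in unique(doc$tokens$sentence)) {
      seqs[[length(seqs) + 1L]] <- offset + which(doc$tokens$sentence == si)
    }
    offset <- offset + nrow(doc$tokens)
  }
  labels <- sort(unique(y_chr))
  if (scheme == "binary") labels <- union(labels, c("O", "B", "I", "O-"))
  labels <- sort(labels)
  y <- match(y_chr, labels)
  X <- feature_matrix(feat_idx, n_feat(featmap))
  par <- crf_fit(X, y, seqs, length(labels), l2 = l2, maxit = maxit)
  structure(list(kind = "linear_chain_crf", scheme = scheme,
                 category = category, labels = labels, featmap = featmap,
                 n_features = n_feat(featmap), par = par,
                 l2 = l2, maxit = maxit, seed = seed),
            class = "tagger_model")
}

#' @export
print.tagger_model <- function(x, ...) {
  cat("<tagger_model> ", x$kind, " (", x$scheme,
      if (!is.null(x$category)) paste0(":", x$category), "), ",
      length(x$labels), " labels, ", x$n_features, " features\n", sep = "")
  invisible(x)
}

#' Predict B/I/O/O- tags for a document
#'
#' @param model a \code{\link{train_tagger}} model.
#' @param doc a \code{\link{soi_document}}.
#' @return a \code{soi_tags}.
#' @export
predict_tags <- function(model, doc) {
  stopifnot(inherits(model, "tagger_model"), inherits(doc, "soi_document"))
  n <- nrow(doc$tokens)
  scheme_name <- if (model$scheme == "binary") "binary" else "per_category"
  if (!n) return(structure(list(doc_id = doc$doc_id, tags = character(),
                                scheme = scheme_name), class = "soi_tags"))
  fl <- token_features(doc$tokens$text, doc$tokens$sentence)
  fi <- index_features(fl, model$featmap, frozen = TRUE)
  X <- feature_matrix(fi, model$n_features)
  pp <- crf_unpack(model$par, length(model$labels), model$n_features)
  E <- as.matrix(X %*% t(pp$W))
  seqs <- lapply(unique(doc$tokens$sentence), function(si)
    which(doc$tokens$sentence == si))
  tags <- crf_viterbi(pp, E, seqs, model$labels)
  structure(list(doc_id = doc$doc_id, tags = tags, scheme = scheme_name),
            class = "soi_tags")
}

#' Predict cue annotations for a document
#'
#' Tags from the model are re-assembled into lexical cues with
#' \code{\link{bio_decode}} (repairs logged); annotations carry provenance
#' \code{"predicted"}.
#'
#' @param model a \code{\link{train_tagger}} model.
#' @param doc a \code{\link{soi_document}}.
#' @return list with \code{cues}, \code{n_repairs}, \code{repairs}.
#' @export
predict_cues <- function(model, doc) {
  tags <- predict_tags(model, doc)
  bio_decode(doc, tags, provenance = "predicted")
}

#' Exact span-level F1 between predicted and gold cue annotations
#'
#' A predicted cue is a true positive iff its full span list equals a gold
#' cue's span list (and its category, when \code{by_category}).
#'
#' @param predicted,gold lists of \code{\link{soi_cue}} for the same
#'   document set.
#' @param by_category also require category identity?
#' @return list with \code{precision}, \code{recall}, \code{f1}.
#' @export
span_f1 <- function(predicted, gold, by_category = FALSE) {
  key <- function(cu) paste(cu$doc_id,
                            paste(cu$starts, cu$ends, collapse = ";"),
                            if (by_category) cu$category else "")
  pk <- vapply(predicted, key, "")
  gk <- vapply(gold, key, "")
  tp <- 0L
  avail <- gk
  for (k in pk) {
    hit <- match(k, avail)
    if (!is.na(hit)) { tp <- tp + 1L; avail <- avail[-hit] }
  }
  prf(tp, length(pk) - tp, length(gk) - tp)
}

#' Compare predicted cues to the dictionary: novel-cue discovery
#'
#' A predicted cue is novel iff its fragment token sequence
#' (case-insensitive) is absent from the taxonomy's dictionary.  The
#' fraction counts cue instances; cues that become dictionary entries after
#' stripping a plural \code{-s} are additionally reported as variants.
#'
#' @param predicted list of \code{\link{soi_cue}}.
#' @param tax an \code{ignorance_taxonomy}.
#' @param texts named character vector (or list) of document texts keyed by
#'   doc id, used to recover surfaces.
#' @return list with \code{n_total}, \code{n_novel}, \code{fraction},
#'   \code{novel_surfaces}, \code{n_variant} (novel cues that are plural
#'   variants of dictionary cues).
#' @export
discover_novel_cues <- function(predicted, tax, texts) {
  n_total <- length(predicted)
  novel <- character()
  n_novel <- 0L
  n_variant <- 0L
  for (cu in predicted) {
    text <- texts[[cu$doc_id]]
    surf <- cue_surface(cu, text)
    k <- cue_key(surf)
    if (nzchar(k) && exists(k, envir = tax$cue_index)) next
    n_novel <- n_novel + 1L
    novel <- c(novel, k)
    depl <- cue_key(gsub("s\\b", "", surf))
    if (nzchar(depl) && exists(depl, envir = tax$cue_index))
      n_variant <- n_variant + 1L
  }
  list(n_total = n_total, n_novel = n_novel,
       fraction = if (n_total == 0L) 0 else n_novel / n_total,
       novel_surfaces = unique(novel), n_variant = n_variant)
}
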