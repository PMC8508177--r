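#' Build a token-count vocabulary from training sentences
#'
#' Tokens are lowercased and punctuation-run tokens are removed; indices are
#' dense in order of first appearance and frozen after fit.
#'
#' @param sentences character vector of sentence texts.
#' @return named integer vector mapping token to column index.
#' @export
build_vocabulary <- function(sentences) {
  toks <- unlist(lapply(sentences, tokenize, lower = TRUE))
  toks <- toks[grepl("[a-z0-9]", toks)]
  toks <- unique(toks)
  stats::setNames(seq_along(toks), toks)
}

#' Count-vector features over a frozen vocabulary
#'
#' Out-of-vocabulary tokens are dropped.
#'
#' @param sentences character vector.
#' @param vocab a \code{\link{build_vocabulary}} result.
#' @return sparse \code{\link[Matrix]{Matrix}} (sentences x vocabulary).
#' @export
count_features <- function(sentences, vocab) {
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (s in seq_along(sentences)) {
    toks <- tokenize(sentences[s], lower = TRUE)
    idx <- vocab[toks]
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    tab <- table(idx)
    ii <- c(ii, rep(s, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(sentences), length(vocab)),
                       dimnames = list(NULL, names(vocab)))
}

#' Gold sentence labels from annotated documents
#'
#' A sentence is a positive statement of ignorance iff it carries a subject
#' annotation; its category labels are the union of its cues' assigned
#' narrow categories.
#'
#' @param docs a \code{soi_annotated}, list of them, or \code{soi_corpus}.
#' @return data.frame with \code{doc_id}, \code{sentence} (index),
#'   \code{text}, \code{label} (0/1) and \code{categories}
#'   (comma-separated).
#' @export
sentence_dataset <- function(docs) {
  if (inherits(docs, "soi_corpus")) docs <- docs$docs
  if (inherits(docs, "soi_annotated")) docs <- list(docs)
  rows <- lapply(docs, function(ad) {
    doc <- ad$document
    n <- nrow(doc$sentences)
    if (!n) return(NULL)
    pos <- rep(FALSE, n)
    for (s in ad$subjects) {
      i <- sentence_at(doc, s$start)
      if (!is.na(i)) pos[i] <- TRUE
    }
    cats <- rep("", n)
    for (cu in ad$cues) {
      i <- sentence_at(doc, cu$starts[1])
      if (is.na(i) || is.na(cu$category)) next
      have <- strsplit(cats[i], ",", fixed = TRUE)[[1]]
      cats[i] <- paste(unique(c(have, cu$category)), collapse = ",")
    }
    data.frame(doc_id = doc$doc_id, sentence = seq_len(n),
               text = span_text(doc$text, doc$sentences$start,
                                doc$sentences$end),
               label = as.integer(pos), categories = cats,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Per-class counts are preserved within one example of the exact ratio;
#' the split is deterministic given the seed.
#'
#' @param labels class label vector.
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_corpus <- function(labels, ratio = 0.9, seed = 1L) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be strictly inside (0, 1)")
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every class needs at least 2 examples; offending class: ",
         names(tab)[which(tab < 2L)[1]])
  set.seed(seed)
  train <- integer()
  for (cls in names(tab)) {
    idx <- which(labels == cls)
    idx <- sample(idx)
    n_train <- min(max(floor(length(idx) * ratio + 0.5), 1L),
                   length(idx) - 1L)
    train <- c(train, idx[seq_len(n_train)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Downsample the majority class to the minority size
#'
#' Sampling is without replacement and deterministic given the seed; the
#' minority class is kept intact.
#'
#' @param labels binary label vector (two classes present).
#' @param seed RNG seed.
#' @return integer indices of the balanced subset, in ascending order.
#' @export
balance_classes <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) != 2L || any(tab == 0L))
    stop("balancing needs exactly two non-empty classes")
  set.seed(seed)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  keep_min <- which(labels == minority)
  maj <- which(labels == majority)
  keep_maj <- sort(sample(maj, min(tab)))
  sort(c(keep_min, keep_maj))
}

#' Training configuration for sentence models
#'
#' @param hidden_width hidden-layer neuron count.
#' @param epochs training-length control in [6, 12] by convention (default
#'   8, the midpoint); scales the optimizer's iteration cap.
#' @param batch_size recorded for interface compatibility; the quasi-Newton
#'   optimizer used here is full-batch.
#' @param split_ratio train fraction for \code{\link{split_corpus}}.
#' @param seed RNG seed for splitting, balancing and weight init.
#' @param balance downsample the majority class before fitting?
#' @param model \code{"feedforward_1hidden"} (one ReLU-free nnet hidden
#'   layer, sigmoid output) or \code{"logistic"} (no hidden layer).
#' @param threshold decision threshold on the sigmoid output.
#' @return list of class \code{soi_training_config}.
#' @export
training_config <- function(hidden_width = 50L, epochs = 8L,
                            batch_size = 16L, split_ratio = 0.9,
                            seed = 1L, balance = TRUE,
                            model = c("feedforward_1hidden", "logistic"),
                            threshold = 0.5) {
  model <- match.arg(model)
  stopifnot(epochs >= 1L, split_ratio > 0, split_ratio < 1,
            hidden_width >= 1L)
  structure(list(hidden_width = as.integer(hidden_width),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_ratio = split_ratio, seed = as.integer(seed),
                 balance = isTRUE(balance), model = model,
                 threshold = threshold),
            class = "soi_training_config")
}

# minibatch Adam for a 1-hidden-layer sigmoid-output network (ReLU hidden,
# cross-entropy loss); hidden_width = 0 gives plain logistic regression.
# Full-batch quasi-Newton fitters scale quadratically in the weight count,
# which a width-50 layer over a count vocabulary rules out, hence the
# stochastic trainer; determinism comes from the seed (init + shuffling).
fit_ffnn <- function(x, y, hidden_width, epochs, batch_size, seed,
                     lr = 0.05, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  set.seed(seed)
  V <- ncol(x)
  H <- hidden_width
  # hidden weights small random (symmetry breaking); output layer zero so
  # tokens never seen in training contribute nothing to the initial logit
  # and the model starts at p = 0.5
  par <- list(
    W1 = if (H > 0L) matrix(stats::rnorm(V * H, sd = 0.01), V, H) else NULL,
    b1 = if (H > 0L) numeric(H) else NULL,
    w2 = matrix(0, nrow = if (H > 0L) H else V, ncol = 1L),
    b2 = 0)
  mom <- lapply(par, function(p) if (is.null(p)) NULL else p * 0)
  vel <- mom
  step <- 0L
  n <- nrow(x)
  sigmoid <- function(z) 1 / (1 + exp(-z))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      xb <- as.matrix(x[idx, , drop = FALSE])
      yb <- y[idx]
      if (H > 0L) {
        a1 <- xb %*% par$W1
        a1 <- sweep(a1, 2L, par$b1, `+`)
        h <- pmax(a1, 0)
        p <- sigmoid(as.numeric(h %*% par$w2) + par$b2)
        d2 <- (p - yb) / length(yb)
        g <- list(W1 = NULL, b1 = NULL,
                  w2 = crossprod(h, d2), b2 = sum(d2))
        dh <- outer(d2, as.numeric(par$w2)) * (a1 > 0)
        g$W1 <- crossprod(xb, dh)
        g$b1 <- colSums(dh)
      } else {
        p <- sigmoid(as.numeric(xb %*% par$w2) + par$b2)
        d2 <- (p - yb) / length(yb)
        g <- list(W1 = NULL, b1 = NULL, w2 = crossprod(xb, d2),
                  b2 = sum(d2))
      }
      step <- step + 1L
      for (nm in names(par)) {
        if (is.null(par[[nm]])) next
        gn <- g[[nm]]
        if (is.null(dim(par[[nm]])) && !is.null(dim(gn)))
          gn <- as.numeric(gn)
        pn <- par[[nm]]
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gn
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gn^2
        mh <- mom[[nm]] / (1 - beta1^step)
        vh <- vel[[nm]] / (1 - beta2^step)
        par[[nm]] <- pn - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  par
}

ffnn_prob <- function(par, x) {
  sigmoid <- function(z) 1 / (1 + exp(-z))
  if (!is.null(par$W1)) {
    h <- pmax(sweep(as.matrix(x %*% par$W1), 2L, par$b1, `+`), 0)
    sigmoid(as.numeric(h %*% par$w2) + par$b2)
  } else {
    sigmoid(as.numeric(as.matrix(x %*% par$w2)) + par$b2)
  }
}

#' Fit a sentence-level classifier
#'
#' Count-vector features over a vocabulary built from the training
#' sentences only; a single-hidden-layer network (width
#' \code{hidden_width}, rectified-linear hidden units, sigmoid output,
#' cross-entropy loss) trained by minibatch gradient descent (Adam) with
#' the configured epochs and batch size, or a logistic baseline (no hidden
#' layer) fitted to convergence by ridge-penalized maximum likelihood.
#' Training is deterministic given the config seed.
#'
#' @param sentences character vector of training sentence texts.
#' @param labels 0/1 vector (1 = statement of ignorance, or category
#'   membership for one-vs-rest models).
#' @param config a \code{\link{training_config}}.
#' @param target label for what the model predicts (\code{"binary"} or a
#'   narrow category id).
#' @return object of class \code{sentence_model}.
#' @export
train_sentence <- function(sentences, labels, config = training_config(),
                           target = "binary") {
  stopifnot(length(sentences) == length(labels))
  if (!length(sentences)) stop("empty training set")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("degenerate single-class training set")
  if (config$balance) {
    keep <- balance_classes(labels, seed = config$seed)
    sentences <- sentences[keep]
    labels <- labels[keep]
  }
  vocab <- build_vocabulary(sentences)
  x <- count_features(sentences, vocab)
  if (config$model == "logistic") {
    # convex problem: fit to convergence with a small ridge penalty
    fit <- glmnet::glmnet(x, labels, family = "binomial", alpha = 0,
                          lambda = 1e-4, standardize = FALSE, maxit = 1e6)
    par <- list(W1 = NULL, b1 = NULL,
                w2 = matrix(as.numeric(stats::coef(fit))[-1], ncol = 1L),
                b2 = as.numeric(stats::coef(fit))[1])
  } else {
    par <- fit_ffnn(x, labels, config$hidden_width, config$epochs,
                    config$batch_size, config$seed)
  }
  structure(list(vocab = vocab, fit = par, config = config,
                 target = target),
            class = "sentence_model")
}

#' @export
print.sentence_model <- function(x, ...) {
  cat("<sentence_model> target=", x$target, ", ", x$config$model,
      " (hidden ", if (x$config$model == "logistic") 0 else
        x$config$hidden_width,
      "), vocabulary ", length(x$vocab), "\n", sep = "")
  invisible(x)
}

#' Predict with a sentence model
#'
#' @param object a \code{\link{train_sentence}} model.
#' @param newdata character vector of sentences.
#' @param type \code{"class"} (0/1 at the configured threshold) or
#'   \code{"prob"}.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.sentence_model <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  x <- count_features(newdata, object$vocab)
  p <- ffnn_prob(object$fit, x)
  if (type == "prob") p else as.integer(p >= object$config$threshold)
}

#' One-vs-rest multi-label sentence prediction
#'
#' Runs every per-category model over the sentences and unions the positive
#' decisions; a sentence may receive several categories, or none.
#'
#' @param models named list of \code{sentence_model}s, one per narrow
#'   category (names are category ids; models' \code{target}s are used when
#'   names are absent).
#' @param sentences character vector.
#' @return list (one element per sentence) of character vectors of category
#'   ids.
#' @export
predict_multilabel <- function(models, sentences) {
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "target")
  out <- vector("list", length(sentences))
  for (i in seq_along(out)) out[[i]] <- character()
  for (cat in names(models)) {
    hit <- predict(models[[cat]], sentences, type = "class") == 1L
    for (i in which(hit)) out[[i]] <- c(out[[i]], cat)
  }
  out
}

#' Precision, recall and F1 for binary labels
#'
#' F1 is the harmonic mean of precision and recall, defined as 0 when
#' precision + recall is 0.
#'
#' @param predicted,gold equal-length 0/1 (or logical) vectors.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{tp}, \code{fp}, \code{fn}.
#' @export
evaluate_f1 <- function(predicted, gold) {
  if (length(predicted) != length(gold))
    stop("length mismatch: ", length(predicted), " vs ", length(gold))
  predicted <- as.integer(as.logical(predicted))
  gold <- as.integer(as.logical(gold))
  tp <- sum(predicted == 1L & gold == 1L)
  fp <- sum(predicted == 1L & gold == 0L)
  fn <- sum(predicted == 0L & gold == 1L)
  prf(tp, fp, fn)
}

# shared precision/recall/F1 arithmetic
prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Train the 13 one-vs-rest category models
#'
#' For each narrow category, sentences are split with per-category
#' stratification, the training side balanced, and a binary model fitted;
#' returns models plus held-out F1 per category.
#'
#' The default configuration uses the converged logistic model with a
#' decision threshold of 0.8: balanced training inflates the positive
#' prior to one half, while each one-vs-rest model is applied at a
#' prevalence far below that, so the threshold is shifted up to undo part
#' of the prior distortion (exact prior correction at a typical 5-10
#' percent prevalence would push it above 0.9; 0.8 is a milder default and
#' it remains configurable).
#'
#' @param dataset a \code{\link{sentence_dataset}} result.
#' @param tax an \code{ignorance_taxonomy}.
#' @param config a \code{\link{training_config}}.
#' @return list with \code{models} (named list) and \code{scores}
#'   (data.frame of category, f1, support).
#' @export
train_category_models <- function(dataset, tax,
                                  config = training_config(
                                    model = "logistic",
                                    threshold = 0.8)) {
  cats <- narrow_categories(tax)
  models <- list()
  scores <- list()
  cat_sets <- strsplit(dataset$categories, ",", fixed = TRUE)
  for (cat in cats) {
    y <- vapply(cat_sets, function(cs) cat %in% cs, logical(1))
    if (sum(y) < 2L || sum(!y) < 2L) next
    sp <- split_corpus(as.integer(y), ratio = config$split_ratio,
                       seed = config$seed)
    m <- train_sentence(dataset$text[sp$train], as.integer(y[sp$train]),
                        config = config, target = cat)
    pred <- predict(m, dataset$text[sp$test], type = "class")
    sc <- evaluate_f1(pred, y[sp$test])
    models[[cat]] <- m
    scores[[cat]] <- data.frame(category = cat, f1 = sc$f1,
                                support = sum(y[sp$test]),
                                stringsAsFactors = FALSE)
  }
  list(models = models, scores = do.call(rbind, scores))
}
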