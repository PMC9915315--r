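#' Build a TF-IDF vocabulary model from tokenized documents
#'
#' The vocabulary holds every unigram whose total occurrence count across the
#' training corpus reaches `min_term_freq` (default 3), together with each
#' term's document frequency and the corpus size `|D|`. Frequency is read as
#' total occurrences, not document count.
#'
#' @param docs list of character vectors: tokenized, stop-word-filtered
#'   training documents.
#' @param min_term_freq minimum total occurrence count for a term to enter
#'   the vocabulary.
#' @param nonneg_idf clamp negative idf values (for terms present in more
#'   than `|D|/10 - 1` documents under the +1-smoothed base-10 formula) to
#'   zero. Off by default: the printed formula is applied literally.
#' @return A `tfidf_model`: list with `vocabulary` (term -> column index),
#'   `doc_freq`, `corpus_size`, `min_term_freq`, `nonneg_idf`.
#' @export
build_vocabulary <- function(docs, min_term_freq = 3, nonneg_idf = FALSE) {
  stopifnot(is.list(docs))
  if (length(docs) == 0) stop("empty corpus", call. = FALSE)
  total <- table(unlist(docs, use.names = FALSE))
  terms <- names(total)[total >= min_term_freq]
  if (length(terms) == 0) {
    stop("no term reaches min_term_freq = ", min_term_freq,
         "; lower the threshold", call. = FALSE)
  }
  terms <- sort(terms)
  df <- table(factor(unlist(lapply(docs, unique), use.names = FALSE),
                     levels = terms))
  structure(list(
    vocabulary = stats::setNames(seq_along(terms), terms),
    doc_freq = stats::setNames(as.integer(df), terms),
    corpus_size = length(docs),
    min_term_freq = min_term_freq,
    nonneg_idf = isTRUE(nonneg_idf)
  ), class = "tfidf_model")
}

#' Inverse document frequency of terms
#'
#' `idf(t) = log10(|D| / (1 + df(t)))`, the +1-smoothed base-10 form. Terms
#' unseen in training have `df = 0` and hence `idf = log10(|D|)`; terms in
#' every document get a slightly negative idf -- both are consequences of
#' the formula and are kept unless `nonneg_idf` was set on the model.
#'
#' @param model a `tfidf_model`.
#' @param terms character vector of terms.
#' @return Numeric vector of idf values.
#' @export
idf_weight <- function(model, terms) {
  df <- model$doc_freq[terms]
  df[is.na(df)] <- 0L
  v <- log10(model$corpus_size / (1 + df))
  if (model$nonneg_idf) v <- pmax(v, 0)
  unname(v)
}

#' TF-IDF weight of a term in a document
#'
#' `tf` is the term's occurrence count divided by the total token count of
#' the document -- all tokens, including out-of-vocabulary ones, count in
#' the denominator. The weight is `tf * idf`. An empty document has no
#' defined `tf` and scores 0 by convention.
#'
#' @param term a single term.
#' @param doc_tokens character vector: the document's tokens.
#' @param model a `tfidf_model`.
#' @return A single numeric weight.
#' @examples
#' m <- build_vocabulary(rep(list(c("a", "b")), 10), min_term_freq = 1)
#' tfidf_weight("a", c("a", "a", "b", "c"), m)
#' @export
tfidf_weight <- function(term, doc_tokens, model) {
  if (length(doc_tokens) == 0) return(0)
  tf <- sum(doc_tokens == term) / length(doc_tokens)
  tf * idf_weight(model, term)
}

#' Vectorize documents against a TF-IDF model
#'
#' One sparse row per document with an entry for every vocabulary term the
#' document contains; out-of-vocabulary tokens are ignored as features but
#' still count in the `tf` denominator.
#'
#' @param docs list of character vectors (tokenized documents).
#' @param model a `tfidf_model`.
#' @return A `dgCMatrix` of dimension `length(docs)` x vocabulary size.
#' @export
vectorize <- function(docs, model) {
  stopifnot(inherits(model, "tfidf_model"))
  nv <- length(model$vocabulary)
  lens <- vapply(docs, length, integer(1))
  tok <- unlist(docs, use.names = FALSE)
  di <- rep.int(seq_along(docs), lens)
  ji <- model$vocabulary[tok]
  keep <- !is.na(ji)
  x <- Matrix::sparseMatrix(
    i = di[keep], j = unname(ji[keep]),
    x = 1 / lens[di[keep]],
    dims = c(length(docs), nv))
  all_idf <- idf_weight(model, names(model$vocabulary))
  x %*% Matrix::Diagonal(nv, all_idf)
}

#' Train the text classifier
#'
#' Builds the TF-IDF model on the supplied training documents only, then
#' fits a linear maximum-margin classifier (a support vector machine with a
#' linear kernel, unit cost by default) on the TF-IDF vectors. No length
#' normalization is applied to the vectors. The fitted hyperplane is also
#' extracted as an explicit weight vector and intercept, which makes
#' predictions fast and the model serializable as plain text.
#'
#' A different learning engine (e.g. naive Bayes or a decision tree) can be
#' plugged in as `engine = list(fit = function(x, y) m, predict =
#' function(m, x) labels)` operating on the sparse TF-IDF matrix; the
#' surrounding TF-IDF and scoring contract is unchanged.
#'
#' @param docs list of character vectors: tokenized, stop-word-filtered
#'   labelled documents.
#' @param labels integer vector of 0/1 gold labels (1 = useful).
#' @param min_term_freq,nonneg_idf passed to [build_vocabulary()].
#' @param cost margin softness of the SVM (conventional unit default).
#' @param engine optional plug-in engine (see Details).
#' @return A `text_classifier`: list with `tfidf`, `fit`, `weights`,
#'   `intercept`, `engine_name`.
#' @export
train_text_classifier <- function(docs, labels, min_term_freq = 3,
                                  cost = 1, nonneg_idf = FALSE,
                                  engine = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(docs) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  tfidf <- build_vocabulary(docs, min_term_freq, nonneg_idf)
  x <- vectorize(docs, tfidf)
  if (!is.null(engine)) {
    fit <- engine$fit(x, labels)
    return(structure(list(tfidf = tfidf, fit = fit, engine = engine,
                          weights = NULL, intercept = NULL,
                          engine_name = "plugin"),
                     class = "text_classifier"))
  }
  y <- factor(labels, levels = c(0L, 1L))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  hp <- linear_hyperplane(fit, ncol(x))
  structure(list(tfidf = tfidf, fit = fit, engine = NULL,
                 weights = hp$w, intercept = hp$b,
                 engine_name = "linear_svm"),
            class = "text_classifier")
}

# Recover (w, b) of the separating hyperplane such that the post is labelled
# useful when w.x + b > 0. Probes the fitted decision function on the zero
# vector and the coordinate unit vectors, which is exact for a linear kernel
# and independent of the library's internal support-vector storage.
linear_hyperplane <- function(fit, nv) {
  probe <- rbind(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                      x = numeric(0), dims = c(1, nv)),
                 Matrix::Diagonal(nv))
  dv <- attr(predict(fit, probe, decision.values = TRUE),
             "decision.values")
  d <- dv[, 1]
  b0 <- d[1]
  w <- d[-1] - b0
  # the decision value is oriented toward the class named first in the
  # column label ("first/second"); flip if that class is "0" so that a
  # positive value always means useful
  first_class <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- if (identical(first_class, "1")) 1 else -1
  list(w = s * unname(w), b = s * unname(b0))
}

#' Classify documents
#'
#' Hard 0/1 labels from the trained decision rule, plus the fixed score used
#' by the weighted integration: 100 for a useful verdict, 0 otherwise.
#'
#' @param clf a `text_classifier`.
#' @param docs list of character vectors (tokenized documents).
#' @return A tibble with columns `svm_label` (0/1) and `svm_score` (0/100).
#' @export
classify <- function(clf, docs) {
  stopifnot(inherits(clf, "text_classifier"))
  x <- vectorize(docs, clf$tfidf)
  lab <- if (!is.null(clf$engine)) {
    as.integer(clf$engine$predict(clf$fit, x))
  } else {
    as.integer(as.numeric(x %*% clf$weights) + clf$intercept > 0)
  }
  tibble::tibble(svm_label = lab, svm_score = 100 * lab)
}

#' Stratified k-fold cross-validation of the text classifier
#'
#' Splits the labelled corpus into `k` stratified folds, rebuilding the
#' vocabulary and document frequencies inside each training fold so no
#' information leaks from held-out documents, and pools the out-of-fold
#' confusion counts. The fold assignment is deterministic given `seed`.
#'
#' @inheritParams train_text_classifier
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return A list with `folds` (per-fold confusion counts), `pooled`
#'   (precision/recall/F over pooled counts), and `predictions` (a tibble
#'   aligned with the input order: `fold`, `svm_label`, `svm_score`).
#' @export
cross_validate <- function(docs, labels, k = 10, seed = 1,
                           min_term_freq = 3, cost = 1,
                           nonneg_idf = FALSE, engine = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(docs) == length(labels), all(labels %in% 0:1), k >= 2)
  if (min(table(factor(labels, levels = 0:1))) < k) {
    stop("each class must have at least k members for stratified folds",
         call. = FALSE)
  }
  fold <- stratified_folds(labels, k, seed)
  n <- length(docs)
  pred <- integer(n)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    clf <- train_text_classifier(docs[tr], labels[tr],
                                 min_term_freq = min_term_freq,
                                 cost = cost, nonneg_idf = nonneg_idf,
                                 engine = engine)
    pred[!tr] <- classify(clf, docs[!tr])$svm_label
    cm <- confusion(labels[!tr], pred[!tr])
    rows[[f]] <- tibble::tibble(fold = f, n = sum(!tr), tp = cm$tp,
                                fp = cm$fp, fn = cm$fn, tn = cm$tn)
  }
  folds <- do.call(rbind, rows)
  pooled_cm <- list(tp = sum(folds$tp), fp = sum(folds$fp),
                    fn = sum(folds$fn), tn = sum(folds$tn))
  list(folds = folds,
       pooled = precision_recall_f(pooled_cm),
       predictions = tibble::tibble(fold = fold, svm_label = pred,
                                    svm_score = 100L * pred))
}

# balanced stratified assignment; remainders of the two classes are spread
# from opposite ends so combined fold sizes differ by at most one when
# r0 + r1 <= k
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  idx0 <- sample(which(labels == 0L))
  idx1 <- sample(which(labels == 1L))
  fold[idx0] <- rep_len(seq_len(k), length(idx0))
  fold[idx1] <- rep_len(rev(seq_len(k)), length(idx1))
  fold
}

#' Persist a trained text classifier as plain text
#'
#' Writes (and reads back) the vocabulary, document frequencies, corpus
#' size, hyperplane weights and intercept as a self-describing JSON file.
#' Only the default linear engine is serializable.
#'
#' @param clf a `text_classifier` trained with the default engine.
#' @param path file path.
#' @return `read_text_classifier()`: a `text_classifier` (with `fit = NULL`;
#'   predictions use the stored hyperplane). `write_text_classifier()`:
#'   `path`, invisibly.
#' @export
write_text_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "text_classifier"))
  if (is.null(clf$weights)) {
    stop("only the linear engine is serializable", call. = FALSE)
  }
  jsonlite::write_json(list(
    format = "mrim_text_classifier/1",
    terms = names(clf$tfidf$vocabulary),
    doc_freq = unname(clf$tfidf$doc_freq),
    corpus_size = clf$tfidf$corpus_size,
    min_term_freq = clf$tfidf$min_term_freq,
    nonneg_idf = clf$tfidf$nonneg_idf,
    weights = clf$weights,
    intercept = clf$intercept
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_text_classifier
#' @export
read_text_classifier <- function(path) {
  x <- jsonlite::fromJSON(path)
  stopifnot(identical(x$format, "mrim_text_classifier/1"))
  tfidf <- structure(list(
    vocabulary = stats::setNames(seq_along(x$terms), x$terms),
    doc_freq = stats::setNames(as.integer(x$doc_freq), x$terms),
    corpus_size = x$corpus_size,
    min_term_freq = x$min_term_freq,
    nonneg_idf = isTRUE(x$nonneg_idf)
  ), class = "tfidf_model")
  structure(list(tfidf = tfidf, fit = NULL, engine = NULL,
                 weights = as.numeric(x$weights),
                 intercept = as.numeric(x$intercept),
                 engine_name = "linear_svm"),
            class = "text_classifier")
}
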