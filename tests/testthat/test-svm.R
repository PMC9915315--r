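test_that("vocabulary building counts total and document frequencies", {
  m <- build_vocabulary(list(c("a", "a", "a"), "b"), min_term_freq = 3)
  expect_identical(names(m$vocabulary), "a")
  expect_identical(unname(m$doc_freq["a"]), 1L)
  expect_identical(m$corpus_size, 2L)
  m2 <- build_vocabulary(list(c("a", "a", "a"), "b"), min_term_freq = 1)
  expect_setequal(names(m2$vocabulary), c("a", "b"))
  m3 <- build_vocabulary(rep(list("flood"), 10), min_term_freq = 1)
  expect_identical(unname(m3$doc_freq["flood"]), 10L)
  expect_identical(m3$corpus_size, 10L)
  expect_error(build_vocabulary(list()), "empty corpus")
  expect_error(build_vocabulary(list("a", "b"), min_term_freq = 3),
               "threshold")
})

test_that("tf-idf weights reproduce the printed formula exactly", {
  # ten documents; "t" appears in four of them
  docs <- c(rep(list(c("t", "x", "x", "x")), 4),
            rep(list(c("x", "x")), 6))
  m <- build_vocabulary(docs, min_term_freq = 1)
  expect_equal(idf_weight(m, "t"), log10(10 / 5), tolerance = 1e-12)
  # a document of 8 tokens containing the term twice
  doc <- c("t", "t", "x", "x", "x", "x", "x", "x")
  expect_equal(tfidf_weight("t", doc, m), 0.25 * log10(2),
               tolerance = 1e-12)
  # ubiquitous term: negative idf under the literal formula
  expect_equal(idf_weight(m, "x"), log10(10 / 11), tolerance = 1e-12)
  expect_lt(idf_weight(m, "x"), 0)
  # unseen term: df = 0, idf = 1
  expect_equal(idf_weight(m, "zz"), 1, tolerance = 1e-12)
  # empty document scores zero by convention
  expect_equal(tfidf_weight("t", character(), m), 0)
  # the optional clamp removes negative idf only
  mnn <- build_vocabulary(docs, min_term_freq = 1, nonneg_idf = TRUE)
  expect_equal(idf_weight(mnn, "x"), 0)
  expect_equal(idf_weight(mnn, "t"), log10(2), tolerance = 1e-12)
})

test_that("vectorize agrees with element-wise tfidf_weight calls", {
  set.seed(21)
  vocabulary_pool <- c(letters, "oov1", "oov2")
  docs <- lapply(1:60, function(i) {
    sample(vocabulary_pool, sample(2:12, 1), replace = TRUE)
  })
  m <- build_vocabulary(docs, min_term_freq = 3)
  x <- vectorize(docs, m)
  for (i in sample(60, 10)) {
    for (term in unique(docs[[i]])) {
      j <- m$vocabulary[term]
      if (is.na(j)) next
      expect_equal(x[i, j], tfidf_weight(term, docs[[i]], m),
                   tolerance = 1e-12)
    }
  }
  # out-of-vocabulary-only document gives an all-zero row
  mv <- build_vocabulary(list(c("a", "a", "a"), "b"), min_term_freq = 3)
  xr <- vectorize(list(c("zz", "qq")), mv)
  expect_equal(sum(xr != 0), 0)
  # single-term document: tf = 1
  x1 <- vectorize(list("a"), mv)
  expect_equal(x1[1, 1], 1 * idf_weight(mv, "a"), tolerance = 1e-12)
})

test_that("a separable corpus is learned perfectly", {
  docs <- c(rep(list(c("pos", "pos", "filler")), 20),
            rep(list(c("negg", "negg", "filler")), 20))
  labels <- rep(c(1L, 0L), each = 20)
  clf <- train_text_classifier(docs, labels, min_term_freq = 1)
  pr <- classify(clf, docs)
  expect_identical(pr$svm_label, labels)
  expect_identical(pr$svm_score, 100 * labels)
  expect_error(train_text_classifier(docs, rep(1L, 40), min_term_freq = 1),
               "both classes")
})

test_that("the extracted hyperplane matches the fitted decision rule", {
  g <- small_corpus(n = 250, seed = 17)
  feats <- extract_features(g$corpus, test_resources())
  clf <- train_text_classifier(feats$tokens, g$corpus$label)
  x <- vectorize(feats$tokens, clf$tfidf)
  via_fit <- as.integer(as.character(predict(clf$fit, x)))
  via_plane <- classify(clf, feats$tokens)$svm_label
  expect_identical(via_plane, via_fit)
})

test_that("classification is deterministic and persistence is lossless", {
  g <- small_corpus(n = 200, seed = 18)
  feats <- extract_features(g$corpus, test_resources())
  clf <- train_text_classifier(feats$tokens, g$corpus$label)
  p1 <- classify(clf, feats$tokens)
  p2 <- classify(clf, feats$tokens)
  expect_identical(p1, p2)
  path <- withr::local_tempfile(fileext = ".json")
  write_text_classifier(clf, path)
  back <- read_text_classifier(path)
  expect_identical(classify(back, feats$tokens), p1)
})

test_that("stratified folds partition the corpus with balanced sizes", {
  labels <- rep(c(1L, 0L), c(1936, 6043))
  fold <- mrim:::stratified_folds(labels, 10, seed = 3)
  expect_identical(sort(unique(fold)), 1:10)
  sizes <- as.integer(table(fold))
  expect_true(all(sizes %in% c(797L, 798L)))
  expect_equal(sum(sizes), 7979)
  # stratification: every fold holds both classes
  expect_true(all(tapply(labels, fold, function(l) length(unique(l))) == 2))
})

test_that("cross-validation refuses folds that cannot be stratified", {
  docs <- rep(list("a"), 12)
  labels <- c(rep(1L, 3), rep(0L, 9))
  expect_error(cross_validate(docs, labels, k = 5, seed = 1), "at least k")
})

test_that("cross-validation is deterministic and leak-free", {
  g <- small_corpus(n = 200, seed = 19)
  feats <- extract_features(g$corpus, test_resources())
  cv1 <- cross_validate(feats$tokens, g$corpus$label, k = 4, seed = 7)
  cv2 <- cross_validate(feats$tokens, g$corpus$label, k = 4, seed = 7)
  expect_identical(cv1$predictions, cv2$predictions)
  # fold test sets partition the corpus
  expect_equal(sum(cv1$folds$n), 200)
  expect_equal(sum(cv1$folds$tp + cv1$folds$fp + cv1$folds$fn +
                     cv1$folds$tn), 200)
  # no leakage: the model of a training split ignores held-out labels
  fold <- mrim:::stratified_folds(g$corpus$label, 4, seed = 7)
  tr <- fold != 1
  m1 <- train_text_classifier(feats$tokens[tr], g$corpus$label[tr])
  m2 <- train_text_classifier(feats$tokens[tr], g$corpus$label[tr])
  expect_identical(m1$weights, m2$weights)
})

test_that("permuted labels drive cross-validated F to chance", {
  g <- small_corpus(n = 300, seed = 23)
  feats <- extract_features(g$corpus, test_resources())
  set.seed(1)
  shuffled <- sample(g$corpus$label)
  cv <- cross_validate(feats$tokens, shuffled, k = 5, seed = 2)
  p <- mean(shuffled)
  r <- mean(cv$predictions$svm_label)
  expect_lt(abs(cv$pooled$f_measure - chance_f(p, r)), 0.1)
})

test_that("a strongly signalled corpus is learned well", {
  g <- generate_corpus(generator_spec(n = 1600, token_signal = 1,
                                      seed = 29))
  feats <- extract_features(g$corpus, test_resources())
  cv <- cross_validate(feats$tokens, g$corpus$label, k = 5, seed = 3)
  expect_gt(cv$pooled$f_measure, 0.5)
})

test_that("a plug-in engine slots behind the same contract", {
  # nearest-centroid stand-in engine
  engine <- list(
    fit = function(x, y) {
      list(mu1 = Matrix::colMeans(x[y == 1, , drop = FALSE]),
           mu0 = Matrix::colMeans(x[y == 0, , drop = FALSE]))
    },
    predict = function(m, x) {
      d1 <- as.numeric(x %*% m$mu1) - sum(m$mu1^2) / 2
      d0 <- as.numeric(x %*% m$mu0) - sum(m$mu0^2) / 2
      as.integer(d1 > d0)
    })
  docs <- c(rep(list(c("pos", "pos")), 15), rep(list(c("negg", "negg")), 15))
  labels <- rep(c(1L, 0L), each = 15)
  clf <- train_text_classifier(docs, labels, min_term_freq = 1,
                               engine = engine)
  expect_identical(classify(clf, docs)$svm_label, labels)
})
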