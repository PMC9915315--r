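test_that("confusion counts the four outcomes", {
  cm <- confusion(c(1, 1, 0), c(1, 0, 0))
  expect_equal(cm, list(tp = 1L, fp = 0L, fn = 1L, tn = 1L))
  cm2 <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cm2$fp + cm2$fn, 0)
  # brute tally oracle on a large random pair
  set.seed(60)
  gold <- rbinom(1000, 1, 0.3)
  pred <- rbinom(1000, 1, 0.5)
  cm3 <- confusion(gold, pred)
  tally <- table(gold = gold, pred = pred)
  expect_equal(cm3$tp, unname(tally["1", "1"]))
  expect_equal(cm3$fp, unname(tally["0", "1"]))
  expect_equal(cm3$fn, unname(tally["1", "0"]))
  expect_equal(cm3$tn, unname(tally["0", "0"]))
  expect_equal(cm3$tp + cm3$fp + cm3$fn + cm3$tn, 1000)
})

test_that("precision, recall and F follow their definitions", {
  m <- precision_recall_f(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_measure, 2 * 0.75 * 0.6 / 1.35)
  perfect <- precision_recall_f(confusion(rep(1, 5), rep(1, 5)))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1,
                                  f_measure = 1))
  none <- precision_recall_f(list(tp = 0, fp = 0, fn = 3))
  expect_equal(unlist(none), c(precision = 0, recall = 0, f_measure = 0))
})

test_that("F lies between precision and recall (harmonic-mean property)", {
  set.seed(61)
  for (i in 1:200) {
    m <- precision_recall_f(list(tp = sample(0:50, 1), fp = sample(0:50, 1),
                                 fn = sample(0:50, 1)))
    expect_gte(m$precision, 0); expect_lte(m$precision, 1)
    expect_gte(m$recall, 0); expect_lte(m$recall, 1)
    expect_gte(m$f_measure, 0); expect_lte(m$f_measure, 1)
    if (m$precision > 0 && m$recall > 0) {
      expect_lte(m$f_measure, max(m$precision, m$recall) + 1e-12)
      expect_gte(m$f_measure, min(m$precision, m$recall) - 1e-12)
    }
  }
})

test_that("rank deciles split 7979 records as 797 then nine of 798", {
  expect_equal(mrim:::decile_sizes(7979), c(797, rep(798, 9)))
  expect_equal(mrim:::decile_sizes(20), rep(2, 10))
  feats <- tibble::tibble(id = sprintf("p%04d", 1:7979),
                          word_count = rpois(7979, 30))
  g <- group_by_word_count_deciles(feats)
  expect_equal(attr(g, "summary")$size, c(797L, rep(798L, 9)))
  # deciles are ordered by the key
  expect_true(all(diff(attr(g, "summary")$mean_key) >= 0))
})

test_that("deciles with constant keys fall back to the id tie-break", {
  feats <- tibble::tibble(id = sprintf("p%03d", 1:20),
                          word_count = rep(7L, 20))
  g1 <- group_by_word_count_deciles(feats)
  g2 <- group_by_word_count_deciles(feats)
  expect_identical(g1$group, g2$group)
  expect_equal(as.integer(table(g1$group)), rep(2L, 10))
  # ids sort into groups in order
  expect_identical(g1$group, rep(1:10, each = 2))
  expect_error(group_by_word_count_deciles(feats[1:5, ]), "at least")
})

test_that("address/contact grouping is the stated partition", {
  feats <- tibble::tibble(id = as.character(1:4),
                          has_exact_address = c(1L, 0L, 1L, 0L),
                          has_contact = c(1L, 1L, 0L, 0L))
  g <- group_by_address_contact(feats)
  expect_identical(g$group, 1:4)
  expect_equal(sum(attr(g, "summary")$size), 4)
})

test_that("attention deciles key on likes + comments + shares", {
  corpus <- small_corpus(n = 60, seed = 62)$corpus
  g <- group_by_attention_deciles(corpus)
  key <- corpus$likes + corpus$comments + corpus$shares
  expect_equal(sum(attr(g, "summary")$size), 60)
  # group means are non-decreasing in the key
  expect_true(all(diff(attr(g, "summary")$mean_key) >= 0))
  one <- corpus[1, ]
  expect_equal(one$likes + one$comments + one$shares, key[1])
})

test_that("grouped evaluation aggregates consistently", {
  g <- small_corpus(n = 200, seed = 63)
  feats <- extract_features(g$corpus, test_resources())
  gold <- g$corpus$label
  set.seed(1)
  pred <- rbinom(200, 1, 0.4)
  groups <- group_by_word_count_deciles(feats)
  rep_tbl <- grouped_evaluation(groups, gold, list(m = pred))
  # one group covering everything equals the ungrouped metrics
  whole <- grouped_evaluation(tibble::tibble(id = feats$id,
                                             group = rep(1L, 200)),
                              gold, list(m = pred))
  expect_equal(whole$f_measure,
               precision_recall_f(confusion(gold, pred))$f_measure)
  # a perfect method scores F = 1 in every non-empty group
  perfect <- grouped_evaluation(groups, gold, list(m = gold))
  expect_true(all(perfect$f_measure[perfect$size > 0] == 1))
  # pooled confusion equals the sum over the partition
  tots <- vapply(1:10, function(k) {
    sel <- groups$group == k
    cm <- confusion(gold[sel], pred[sel])
    c(cm$tp, cm$fp, cm$fn, cm$tn)
  }, numeric(4))
  cm_all <- confusion(gold, pred)
  expect_equal(rowSums(tots),
               c(cm_all$tp, cm_all$fp, cm_all$fn, cm_all$tn))
})
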