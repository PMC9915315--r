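#' Confusion counts
#'
#' Counts of the four prediction outcomes with useful (1) as the positive
#' class.
#'
#' @param gold,pred aligned integer vectors of 0/1 labels.
#' @return A list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(gold, pred) {
  stopifnot(length(gold) == length(pred))
  gold <- as.integer(gold)
  pred <- as.integer(pred)
  stopifnot(all(gold %in% 0:1), all(pred %in% 0:1))
  list(tp = sum(gold == 1L & pred == 1L),
       fp = sum(gold == 0L & pred == 1L),
       fn = sum(gold == 1L & pred == 0L),
       tn = sum(gold == 0L & pred == 0L))
}

#' Precision, recall and F-measure
#'
#' Precision is the proportion of correct positive predictions among all
#' positive predictions, recall the proportion of actual positives that were
#' predicted positive, and the F-measure their harmonic mean (F1). Degenerate
#' denominators score 0 by convention.
#'
#' @param counts a list with `tp`, `fp`, `fn` (as from [confusion()]).
#' @return A tibble with columns `precision`, `recall`, `f_measure`.
#' @examples
#' precision_recall_f(list(tp = 3, fp = 1, fn = 2))
#' @export
precision_recall_f <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(precision = p, recall = r, f_measure = f)
}

# sizes of m rank-based groups of n records, smaller groups first
decile_sizes <- function(n, m = 10) {
  base <- n %/% m
  extra <- n %% m
  c(rep(base, m - extra), rep(base + 1, extra))
}

rank_groups <- function(key, ids, m = 10) {
  n <- length(key)
  if (n < m) stop("need at least ", m, " records", call. = FALSE)
  ord <- order(key, ids)                       # stable, id tie-break
  g <- integer(n)
  g[ord] <- rep.int(seq_len(m), decile_sizes(n, m))
  g
}

#' Group records into word-count deciles
#'
#' Sorts ascending by word count (ties broken by id for determinism) and
#' splits into ten contiguous rank-based groups; when the corpus size is not
#' divisible by ten the smaller groups come first, so 7979 records split as
#' 797 + nine groups of 798.
#'
#' @param features feature tibble with `id` and `word_count`.
#' @return A tibble with `id`, `group` (1 = fewest words), and the group
#'   attribute table `summary` (size and mean word count per group).
#' @export
group_by_word_count_deciles <- function(features) {
  g <- rank_groups(features$word_count, features$id)
  out <- tibble::tibble(id = features$id, group = g)
  attr(out, "summary") <- tibble::tibble(
    group = 1:10,
    size = as.integer(table(factor(g, levels = 1:10))),
    mean_key = as.numeric(tapply(features$word_count, g, mean)))
  out
}

#' Group records into four address/contact groups
#'
#' Group 1: both an exact address and contact information; group 2: contact
#' only; group 3: address only; group 4: neither. The groups partition the
#' corpus.
#'
#' @param features feature tibble with `id`, `has_exact_address`,
#'   `has_contact`.
#' @return A tibble with `id` and `group` (1--4, order as above).
#' @export
group_by_address_contact <- function(features) {
  a <- features$has_exact_address
  c_ <- features$has_contact
  g <- ifelse(a == 1 & c_ == 1, 1L,
              ifelse(c_ == 1, 2L, ifelse(a == 1, 3L, 4L)))
  out <- tibble::tibble(id = features$id, group = g)
  attr(out, "summary") <- tibble::tibble(
    group = 1:4,
    label = c("both", "contact_only", "address_only", "neither"),
    size = as.integer(table(factor(g, levels = 1:4))))
  out
}

#' Group records into attention deciles
#'
#' Attention is the sum of likes, comments and shares. Decile mechanics are
#' identical to the word-count grouping (rank-based, id tie-break, smaller
#' groups first).
#'
#' @param posts a [microblog_corpus()].
#' @return A tibble with `id`, `group` (1 = least attention), and a
#'   `summary` attribute.
#' @export
group_by_attention_deciles <- function(posts) {
  key <- posts$likes + posts$comments + posts$shares
  g <- rank_groups(key, posts$id)
  out <- tibble::tibble(id = posts$id, group = g)
  attr(out, "summary") <- tibble::tibble(
    group = 1:10,
    size = as.integer(table(factor(g, levels = 1:10))),
    mean_key = as.numeric(tapply(key, g, mean)))
  out
}

#' Per-group evaluation of one or more methods
#'
#' Computes precision/recall/F per group and per method from globally
#' produced predictions (models are not retrained per group). Empty groups
#' are reported with `NA` metrics rather than zeros.
#'
#' @param groups grouping tibble from one of the `group_by_*` functions.
#' @param gold integer vector of 0/1 gold labels aligned with `groups`.
#' @param predictions named list of aligned 0/1 prediction vectors, one per
#'   method.
#' @return A tibble with columns `group`, `size`, `method`, `precision`,
#'   `recall`, `f_measure`.
#' @export
grouped_evaluation <- function(groups, gold, predictions) {
  stopifnot(is.list(predictions), length(names(predictions)) ==
              length(predictions))
  stopifnot(length(gold) == nrow(groups))
  lv <- sort(unique(groups$group))
  rows <- list()
  for (g in lv) {
    sel <- groups$group == g
    for (m in names(predictions)) {
      stopifnot(length(predictions[[m]]) == nrow(groups))
      if (!any(sel)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, size = 0L, method = m, precision = NA_real_,
          recall = NA_real_, f_measure = NA_real_)
      } else {
        met <- precision_recall_f(confusion(gold[sel],
                                            predictions[[m]][sel]))
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, size = sum(sel), method = m, met)
      }
    }
  }
  do.call(rbind, rows)
}
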