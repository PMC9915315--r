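#' Union integration of the two classifier arms
#'
#' The recall-oriented integration strategy: a post is classed useless only
#' when both the text classifier and the rule scorer class it as useless --
#' equivalently, the integrated label is the logical OR of the two labels.
#' The rationale is asymmetry of cost during rescue operations: extracting a
#' useless post is cheap, missing a truly useful one is not.
#'
#' @param svm_label,rule_label integer vectors of 0/1 labels.
#' @return Integer vector of 0/1 integrated labels.
#' @examples
#' integrate_union(c(1, 0, 0), c(0, 0, 1))
#' @export
integrate_union <- function(svm_label, rule_label) {
  stopifnot(all(svm_label %in% 0:1), all(rule_label %in% 0:1),
            length(svm_label) == length(rule_label))
  as.integer(svm_label | rule_label)
}

#' Weighted-score integration
#'
#' The alternative blend: `integrated = (1 - w) * svm_score + w *
#' rule_score`, classed useful when the integrated score reaches the
#' threshold (inclusive). At `w = 0` the decisions coincide with the text
#' classifier alone, at `w = 1` with the rule scorer alone.
#'
#' @param svm_score numeric vector of 0/100 text-classifier scores.
#' @param rule_score numeric vector of rule-based usefulness scores.
#' @param w blending weight in `[0, 1]`.
#' @param threshold decision threshold (default 40).
#' @return A tibble with columns `integrated_score` and `label` (0/1).
#' @examples
#' integrate_weighted(100, 30, w = 0.51)  # 64.3, useful
#' @export
integrate_weighted <- function(svm_score, rule_score, w, threshold = 40) {
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || w < 0 || w > 1) {
    stop("w must be a single number in [0, 1]", call. = FALSE)
  }
  stopifnot(all(svm_score %in% c(0, 100)), all(rule_score >= 0))
  s <- (1 - w) * svm_score + w * rule_score
  tibble::tibble(integrated_score = s,
                 label = as.integer(s >= threshold))
}

#' Sweep the integration weight
#'
#' Evaluates the weighted integration over a grid of `w` values against gold
#' labels, recording precision, recall and F at each grid point and the
#' argmax-F weight. The default grid steps by 0.01 over `[0, 1]`.
#'
#' @param gold integer vector of 0/1 gold labels.
#' @param svm_score,rule_score per-record component scores.
#' @param grid numeric vector of `w` values.
#' @param threshold decision threshold.
#' @return A tibble with one row per grid point (`w`, `precision`, `recall`,
#'   `f_measure`) carrying the attribute `best_w` (smallest argmax-F `w`).
#' @export
sweep_weight <- function(gold, svm_score, rule_score,
                         grid = seq(0, 1, by = 0.01), threshold = 40) {
  if (length(grid) == 0) stop("empty weight grid", call. = FALSE)
  stopifnot(all(gold %in% 0:1))
  rows <- lapply(grid, function(w) {
    lab <- integrate_weighted(svm_score, rule_score, w, threshold)$label
    m <- precision_recall_f(confusion(gold, lab))
    tibble::tibble(w = w, precision = m$precision, recall = m$recall,
                   f_measure = m$f_measure)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_w") <- out$w[which.max(out$f_measure)]
  out
}
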