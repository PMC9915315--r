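#' Configuration of the expert-rule usefulness scorer
#'
#' The scorer rates each post on six judgment dimensions drawn from three
#' aspects of a microblog -- communication characteristics (A1 attention),
#' user characteristics (A2 author history), and content characteristics
#' (A3 sentiment, A4 word count, A5 exact address, A6 contact). Each raw
#' parameter is scaled by a divisor and truncated at a cap so extreme values
#' cannot dominate; the dimension weights came from an expert elicitation and
#' are configuration here, summing to 1. A post whose weighted total reaches
#' the boundary score is classed useful.
#'
#' Default weights are 0.20 (attention), 0.10 (user), 0.05 (sentiment),
#' 0.05 (words), 0.20 (address), 0.40 (contact); divisors are 10 for the
#' three attention counts and 100 for the three user counts; caps are 33.3
#' per count parameter (so each three-parameter dimension tops out at 99.9)
#' and 100 for the content dimensions; the boundary score is 40, compared
#' inclusively.
#'
#' @param weights named numeric: `a1_attention`, `a2_user`, `a3_emotion`,
#'   `a4_words`, `a5_address`, `a6_contact`; must sum to 1.
#' @param divisors named numeric divisors for the six count parameters.
#' @param caps named numeric caps: the six count parameters plus `emotion`
#'   and `words`.
#' @param threshold boundary score (default 40).
#' @param emotion_use_magnitude if `TRUE` (default) the sentiment dimension
#'   scores `|sentiment_value|` -- both strong positive and strong negative
#'   emotion count; if `FALSE`, only positive values score.
#' @return A `rule_config` object.
#' @export
rule_config <- function(weights = c(a1_attention = 0.20, a2_user = 0.10,
                                    a3_emotion = 0.05, a4_words = 0.05,
                                    a5_address = 0.20, a6_contact = 0.40),
                        divisors = c(likes = 10, comments = 10, shares = 10,
                                     prior_posts = 100, followers = 100,
                                     fans = 100),
                        caps = c(likes = 33.3, comments = 33.3,
                                 shares = 33.3, prior_posts = 33.3,
                                 followers = 33.3, fans = 33.3,
                                 emotion = 100, words = 100),
                        threshold = 40,
                        emotion_use_magnitude = TRUE) {
  dim_names <- c("a1_attention", "a2_user", "a3_emotion", "a4_words",
                 "a5_address", "a6_contact")
  stopifnot(setequal(names(weights), dim_names))
  weights <- weights[dim_names]
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("dimension weights must sum to 1", call. = FALSE)
  }
  stopifnot(all(weights >= 0), all(weights <= 1))
  stopifnot(setequal(names(divisors), count_columns()), all(divisors > 0))
  stopifnot(all(c(count_columns(), "emotion", "words") %in% names(caps)),
            all(caps > 0))
  stopifnot(is.numeric(threshold), threshold >= 0)
  structure(list(weights = weights, divisors = divisors[count_columns()],
                 caps = caps, threshold = threshold,
                 emotion_use_magnitude = isTRUE(emotion_use_magnitude)),
            class = "rule_config")
}

#' Capped parameter score
#'
#' The score of one raw count parameter: `min(raw / divisor, cap)`.
#'
#' @param raw non-negative numeric vector of raw parameter values.
#' @param divisor positive scale divisor.
#' @param cap positive truncation cap.
#' @return Numeric vector of scores in `[0, cap]`.
#' @examples
#' parameter_score(10000, 10, 33.3)  # 33.3
#' parameter_score(100, 10, 33.3)    # 10
#' @export
parameter_score <- function(raw, divisor, cap) {
  if (any(is.na(raw)) || any(raw < 0)) {
    stop("raw parameter values must be non-negative", call. = FALSE)
  }
  stopifnot(divisor > 0, cap > 0)
  pmin(raw / divisor, cap)
}

#' Score the six judgment dimensions
#'
#' A1 is the sum of the three capped attention parameter scores
#' (likes, comments, shares), A2 the sum of the three capped user parameter
#' scores (prior posts, followers, fans), A3 the sentiment magnitude capped
#' at its maximum, A4 the word count capped at its maximum, and A5/A6 are
#' 100 times the address/contact flags.
#'
#' @param features feature tibble from [extract_features()] (or any frame
#'   with `word_count`, `sentiment_value`, `has_exact_address`,
#'   `has_contact`).
#' @param posts a [microblog_corpus()] aligned row-by-row with `features`.
#' @param config a [rule_config()].
#' @return A tibble of columns `a1_attention` ... `a6_contact` and `total`,
#'   where `total` is the weighted sum of the six dimensions.
#' @export
dimension_scores <- function(features, posts, config = rule_config()) {
  stopifnot(nrow(features) == nrow(posts))
  if (!is.null(features$id) && !is.null(posts$id) &&
      !all(features$id == posts$id)) {
    stop("features and posts are not aligned by id", call. = FALSE)
  }
  dv <- config$divisors
  cp <- config$caps
  a1 <- parameter_score(posts$likes, dv["likes"], cp["likes"]) +
    parameter_score(posts$comments, dv["comments"], cp["comments"]) +
    parameter_score(posts$shares, dv["shares"], cp["shares"])
  a2 <- parameter_score(posts$prior_posts, dv["prior_posts"],
                        cp["prior_posts"]) +
    parameter_score(posts$followers, dv["followers"], cp["followers"]) +
    parameter_score(posts$fans, dv["fans"], cp["fans"])
  emo <- if (config$emotion_use_magnitude) {
    abs(features$sentiment_value)
  } else {
    pmax(features$sentiment_value, 0)
  }
  a3 <- pmin(emo, cp["emotion"])
  a4 <- pmin(features$word_count, cp["words"])
  a5 <- 100 * features$has_exact_address
  a6 <- 100 * features$has_contact
  dims <- tibble::tibble(a1_attention = unname(a1), a2_user = unname(a2),
                         a3_emotion = unname(a3), a4_words = unname(a4),
                         a5_address = unname(a5), a6_contact = unname(a6))
  dims$total <- usefulness_score(dims, config)
  dims
}

#' Weighted usefulness score
#'
#' The total usefulness score is the weighted sum of the six dimension
#' scores; under default weights
#' `0.20 a1 + 0.10 a2 + 0.05 a3 + 0.05 a4 + 0.20 a5 + 0.40 a6`.
#'
#' @param dims tibble or data frame with the six dimension columns.
#' @param config a [rule_config()].
#' @return Numeric vector of total scores.
#' @examples
#' d <- tibble::tibble(a1_attention = 17, a2_user = 17, a3_emotion = 3,
#'                     a4_words = 40, a5_address = 100, a6_contact = 100)
#' usefulness_score(d)  # 67.25
#' @export
usefulness_score <- function(dims, config = rule_config()) {
  w <- config$weights
  as.numeric(
    w["a1_attention"] * dims$a1_attention +
    w["a2_user"]      * dims$a2_user +
    w["a3_emotion"]   * dims$a3_emotion +
    w["a4_words"]     * dims$a4_words +
    w["a5_address"]   * dims$a5_address +
    w["a6_contact"]   * dims$a6_contact)
}

#' Classify by boundary score
#'
#' A post is useful when its score reaches the boundary (inclusive
#' comparison, `score >= threshold`). The score itself is passed through
#' unchanged as the rule-based score used by the weighted integration.
#'
#' @param score numeric vector of usefulness scores.
#' @param threshold boundary score.
#' @return A tibble with columns `rule_label` (0/1) and `rule_score`.
#' @export
rule_classify <- function(score, threshold = 40) {
  tibble::tibble(rule_label = as.integer(score >= threshold),
                 rule_score = as.numeric(score))
}

#' Rule-score a whole corpus
#'
#' Convenience wrapper: dimension scores, total, and boundary decision for
#' every post.
#'
#' @inheritParams dimension_scores
#' @return A tibble keyed by `id` with the six dimension scores, `total`,
#'   `rule_label`, and `rule_score`.
#' @export
rule_score_corpus <- function(posts, features, config = rule_config()) {
  dims <- dimension_scores(features, posts, config)
  cls <- rule_classify(dims$total, config$threshold)
  tibble::tibble(id = posts$id, dims, cls)
}

#' Recompute caps from a corpus by percentile
#'
#' The shipped caps are fixed defaults; for a new corpus this helper derives
#' caps as the value exceeded by only `1 - q` of the non-zero observations
#' of each parameter (default the 90th percentile), matching the design
#' intent that a cap should exceed most observed values.
#'
#' @param posts a [microblog_corpus()].
#' @param features feature tibble from [extract_features()].
#' @param q percentile in (0, 1), default 0.9.
#' @return Named numeric vector of caps suitable for [rule_config()].
#' @export
percentile_caps <- function(posts, features, q = 0.9) {
  nz_q <- function(x) {
    x <- x[x > 0]
    if (length(x) == 0) return(1)
    as.numeric(quantile(x, q, names = FALSE))
  }
  cfg <- rule_config()
  c(likes = nz_q(posts$likes) / cfg$divisors[["likes"]],
    comments = nz_q(posts$comments) / cfg$divisors[["comments"]],
    shares = nz_q(posts$shares) / cfg$divisors[["shares"]],
    prior_posts = nz_q(posts$prior_posts) / cfg$divisors[["prior_posts"]],
    followers = nz_q(posts$followers) / cfg$divisors[["followers"]],
    fans = nz_q(posts$fans) / cfg$divisors[["fans"]],
    emotion = nz_q(abs(features$sentiment_value)),
    words = nz_q(features$word_count))
}

#' Read or write a rule configuration file
#'
#' The configuration travels as a human-editable JSON object keyed by
#' parameter name (weights, divisors, caps, threshold).
#'
#' @param path file path.
#' @return `read_rule_config()`: a [rule_config()]. `write_rule_config()`:
#'   `path`, invisibly.
#' @export
read_rule_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  rule_config(weights = unlist(x$weights), divisors = unlist(x$divisors),
              caps = unlist(x$caps), threshold = x$threshold,
              emotion_use_magnitude = x$emotion_use_magnitude %||% TRUE)
}

#' @rdname read_rule_config
#' @param config a [rule_config()].
#' @export
write_rule_config <- function(config, path) {
  jsonlite::write_json(
    list(weights = as.list(config$weights),
         divisors = as.list(config$divisors),
         caps = as.list(config$caps),
         threshold = config$threshold,
         emotion_use_magnitude = config$emotion_use_magnitude),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
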