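#' Strip markup and platform artifacts from raw text
#'
#' Removes angle-bracket markup tags (including unclosed trailing tags),
#' embedded hyperlinks, and topic-hashtag delimiters (the `#` fences are
#' dropped, the words inside are kept), preserving the visible text and its
#' order. Cleaning happens here, downstream of the corpus layer, so corpora
#' always store the raw text.
#'
#' @param text character vector of raw texts.
#' @return Character vector of plain texts.
#' @examples
#' strip_markup("<b>help</b> needed")
#' @export
strip_markup <- function(text) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  # closed tags, then an unclosed tag opening at end of string
  text <- gsub("<[^<>]*>", "", text)
  text <- gsub("<[^<>]*$", "", text)
  # embedded hyperlinks
  text <- gsub("https?://[^[:space:]]+", "", text)
  # hashtag fences: keep inner words
  text <- gsub("#", " ", text, fixed = TRUE)
  # normalise whitespace introduced by removals
  text <- gsub("[[:space:]]+", " ", text)
  trimws(text)
}

#' Segment plain text into tokens
#'
#' Splits on whitespace, then segments every whitespace-free chunk by greedy
#' longest-match against the dictionary with single-character fallback -- the
#' standard dictionary strategy for unspaced scripts such as Chinese.
#' Consecutive unmatched ASCII digits are merged into a single numeric token
#' (so a phone number stays whole), and punctuation characters come through
#' as their own tokens. The concatenation of the returned tokens always
#' reproduces the non-whitespace characters of the input, in order.
#'
#' @param text character vector of plain (markup-stripped) texts.
#' @param resources a [tokenizer_resources()] object.
#' @return A list with one character vector of tokens per input text.
#' @examples
#' tokenize("ABC", tokenizer_resources(dictionary = c("AB", "C")))[[1]]
#' @export
tokenize <- function(text, resources = tokenizer_resources()) {
  stopifnot(inherits(resources, "tokenizer_resources"))
  dict <- resources$dictionary
  max_len <- if (length(dict) > 0) max(nchar(dict)) else 1L
  dict_env <- new.env(parent = emptyenv(), size = max(1L, length(dict)))
  for (w in dict) assign(w, TRUE, envir = dict_env)
  lapply(as.character(text), function(tx) {
    if (is.na(tx) || !nzchar(tx)) return(character())
    chunks <- strsplit(tx, "[[:space:]]+")[[1]]
    chunks <- chunks[nzchar(chunks)]
    unlist(lapply(chunks, segment_chunk, dict_env = dict_env,
                  max_len = max_len), use.names = FALSE)
  })
}

segment_chunk <- function(chunk, dict_env, max_len) {
  chars <- strsplit(chunk, "")[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (l in seq(min(max_len, n - i + 1L), 2L)) {
      if (l < 2L) break
      cand <- paste(chars[i:(i + l - 1L)], collapse = "")
      if (exists(cand, envir = dict_env, inherits = FALSE)) {
        out <- c(out, cand)
        i <- i + l
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      # single-character fallback; greedily merge an ASCII digit run
      if (grepl("^[0-9]$", chars[i])) {
        j <- i
        while (j < n && grepl("^[0-9]$", chars[j + 1L])) j <- j + 1L
        out <- c(out, paste(chars[i:j], collapse = ""))
        i <- j + 1L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
  }
  out
}

is_punct_token <- function(tokens) {
  grepl("^[[:punct:]]+$", tokens)
}

#' Count content words in raw text
#'
#' Word count is the number of tokens remaining after markup stripping,
#' segmentation, and removal of stop words and punctuation-only tokens.
#'
#' @inheritParams strip_markup
#' @inheritParams tokenize
#' @return Integer vector of word counts.
#' @export
word_count <- function(text, resources = tokenizer_resources()) {
  toks <- tokenize(strip_markup(text), resources)
  vapply(toks, function(tk) {
    tk <- tk[!is_punct_token(tk)]
    length(setdiff_keep(tk, resources$stop_words))
  }, integer(1))
}

# like setdiff but keeps duplicates of retained elements
setdiff_keep <- function(x, drop) x[!(x %in% drop)]

#' Lexicon-weighted sentiment value of a token list
#'
#' Traverses the tokens left to right. Each emotional word contributes its
#' polarity (+1 or -1) times the product of the degree-adverb multipliers
#' seen since the previous emotional word, times `(-1)^k` where `k` is the
#' number of negation words in that same window; the contributions sum to
#' the sentiment value. Degree and negation words therefore scope over the
#' next emotional word only, the usual convention for lexicon methods.
#'
#' @param tokens character vector of tokens (one document), as produced by
#'   [tokenize()].
#' @param lexicon a [sentiment_lexicon()].
#' @return A single signed real.
#' @examples
#' lex <- sentiment_lexicon(c(safe = 1), c(very = 2), "not")
#' sentiment_value(c("very", "safe"), lex)       # +2
#' sentiment_value(c("not", "very", "safe"), lex) # -2
#' @export
sentiment_value <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  if (length(tokens) == 0) return(0)
  pol <- lexicon$emotional[tokens]          # NA for non-emotional tokens
  deg <- lexicon$degree[tokens]
  neg <- tokens %in% lexicon$negation
  total <- 0
  mult <- 1
  sign <- 1
  for (i in seq_along(tokens)) {
    if (!is.na(pol[i])) {
      total <- total + pol[i] * mult * sign
      mult <- 1
      sign <- 1
    } else if (!is.na(deg[i])) {
      mult <- mult * deg[i]
    } else if (neg[i]) {
      sign <- -sign
    }
  }
  unname(total)
}

#' Sentiment polarity of a value
#'
#' Positive for values above zero, negative below zero, neutral at exactly
#' zero.
#'
#' @param value numeric vector of sentiment values.
#' @return Character vector: `"positive"`, `"negative"`, or `"neutral"`.
#' @export
sentiment_polarity <- function(value) {
  ifelse(value > 0, "positive", ifelse(value < 0, "negative", "neutral"))
}

#' Detect an exact address by feature-word suffix
#'
#' A post contains an exact address when some span ends with a feature-word
#' suffix from any of the five specificity levels and the suffix is preceded
#' by at least `min_prefix` characters that are neither whitespace nor
#' punctuation -- the prefix requirement suppresses bare suffixes ("a road")
#' that name no place, while still admitting numbered units ("building 3"). When several suffixes match, the highest-specificity
#' (largest) level is reported, and within a level the longest suffix wins.
#' Named-entity recognition can be plugged in via `ner_hook`, a function
#' `(text) -> logical`; a post is then also flagged when the hook fires.
#' The hook is disabled by default.
#'
#' @param text character vector of plain texts.
#' @param lexicon an [address_lexicon()].
#' @param min_prefix minimum number of name characters required before the
#'   suffix (default 2).
#' @param ner_hook optional function mapping a character vector of texts to a
#'   logical vector; `NULL` disables it.
#' @return A tibble with columns `has_exact_address` (0/1),
#'   `matched_address_level` (integer or `NA`), `matched_address_span`
#'   (character or `NA`).
#' @export
detect_exact_address <- function(text, lexicon = default_address_lexicon(),
                                 min_prefix = 2, ner_hook = NULL) {
  stopifnot(inherits(lexicon, "address_lexicon"))
  text <- as.character(text)
  n <- length(text)
  flag <- integer(n)
  level <- rep(NA_integer_, n)
  span <- rep(NA_character_, n)
  for (lv in 1:5) {
    for (suf in lexicon$levels[[lv]]) {
      hit <- find_suffix_match(text, suf, min_prefix)
      take <- !is.na(hit) &
        (is.na(level) | lv > level |
           (lv == level & nchar(suf) > nchar(span) - min_prefix))
      flag[take] <- 1L
      level[take] <- lv
      span[take] <- hit[take]
    }
  }
  if (!is.null(ner_hook)) {
    extra <- as.logical(ner_hook(text))
    flag[extra & flag == 0L] <- 1L
    level[extra & is.na(level)] <- 1L
  }
  tibble::tibble(has_exact_address = flag,
                 matched_address_level = level,
                 matched_address_span = span)
}

# returns the matched span (min_prefix name chars + suffix) or NA per text
find_suffix_match <- function(text, suffix, min_prefix) {
  out <- rep(NA_character_, length(text))
  pos <- gregexpr(suffix, text, fixed = TRUE, useBytes = FALSE)
  for (i in seq_along(text)) {
    p <- pos[[i]]
    if (p[1] == -1L) next
    for (st in p) {
      if (st <= min_prefix) next
      prefix <- substr(text[i], st - min_prefix, st - 1L)
      if (grepl("^[^[:space:][:punct:]]+$", prefix)) {
        out[i] <- paste0(prefix, suffix)
        break
      }
    }
  }
  out
}

#' Detect contact information
#'
#' Flags a post when any configured pattern matches: by default an 11-digit
#' mobile number, a landline with area code, or a contact keyword followed
#' by a digit run (see [contact_patterns()]).
#'
#' @param text character vector of plain texts.
#' @param patterns ordered character vector of regular expressions.
#' @return Integer vector of 0/1 flags.
#' @examples
#' detect_contact("call 13812345678 now")
#' @export
detect_contact <- function(text, patterns = contact_patterns()) {
  text <- as.character(text)
  hit <- rep(FALSE, length(text))
  for (p in patterns) {
    hit <- hit | grepl(p, text, perl = TRUE)
  }
  as.integer(hit)
}

#' Extract the four content features of every post
#'
#' Composes the cleaning, segmentation, counting, sentiment, address, and
#' contact steps over a corpus, producing one feature row per post: the word
#' count, the signed sentiment value, and the two binary flags (plus the
#' matched address level/span where present). This is the feature table the
#' rule scorer and the grouped analyses consume.
#'
#' @param corpus a [microblog_corpus()].
#' @param resources list with elements `sentiment`, `address`, `tokenizer`,
#'   and optionally `contact_patterns`, as returned by [generate_lexicons()]
#'   or [read_resources()].
#' @param min_prefix passed to [detect_exact_address()].
#' @param ner_hook passed to [detect_exact_address()].
#' @return A tibble keyed by `id` with columns `word_count`,
#'   `sentiment_value`, `has_exact_address`, `matched_address_level`,
#'   `matched_address_span`, `has_contact`, and `tokens` (list column of
#'   stop-word-filtered tokens, ready for the text classifier).
#' @export
extract_features <- function(corpus, resources, min_prefix = 2,
                             ner_hook = NULL) {
  stopifnot(inherits(corpus, "mrim_corpus"))
  plain <- strip_markup(corpus$text)
  toks <- tokenize(plain, resources$tokenizer)
  stop_words <- resources$tokenizer$stop_words
  content <- lapply(toks, function(tk) {
    setdiff_keep(tk[!is_punct_token(tk)], stop_words)
  })
  wc <- vapply(content, length, integer(1))
  sent <- vapply(toks, sentiment_value, numeric(1),
                 lexicon = resources$sentiment)
  addr <- detect_exact_address(plain, resources$address,
                               min_prefix = min_prefix, ner_hook = ner_hook)
  contact <- detect_contact(
    plain, resources$contact_patterns %||% contact_patterns())
  tibble::tibble(
    id = corpus$id,
    word_count = wc,
    sentiment_value = sent,
    has_exact_address = addr$has_exact_address,
    matched_address_level = addr$matched_address_level,
    matched_address_span = addr$matched_address_span,
    has_contact = contact,
    tokens = content
  )
}
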