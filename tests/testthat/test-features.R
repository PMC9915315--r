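test_that("strip_markup removes tags, links and hashtag fences", {
  expect_identical(strip_markup("<b>help</b> needed"), "help needed")
  expect_identical(strip_markup(""), "")
  # nested / unclosed tags
  expect_identical(strip_markup("<a href=x>call<br"), "call")
  expect_identical(strip_markup("go http://t.cn/abc12 now"), "go now")
  expect_identical(strip_markup("#flood rescue# here"), "flood rescue here")
  # idempotent
  x <- "<b>a</b> #b# http://x.y/z c"
  expect_identical(strip_markup(strip_markup(x)), strip_markup(x))
})

test_that("tokenize uses greedy longest match with single-char fallback", {
  expect_identical(tokenize("ABC", tokenizer_resources(c("AB", "C")))[[1]],
                   c("AB", "C"))
  expect_identical(tokenize("XY", tokenizer_resources())[[1]], c("X", "Y"))
  # digit runs merge into one numeric token
  expect_identical(tokenize("0371-1234567", tokenizer_resources())[[1]],
                   c("0371", "-", "1234567"))
  # dictionary words win over fallback
  res <- tokenizer_resources(c("\u533b\u9662"))
  expect_identical(tokenize("\u674e\u5b85\u533b\u9662", res)[[1]],
                   c("\u674e", "\u5b85", "\u533b\u9662"))
})

test_that("tokenization preserves every non-whitespace character", {
  set.seed(9)
  res <- test_resources()
  alphabet <- c(letters[1:6], "0", "7", strsplit("\u6c34\u6df9\u4e86\u533b\u9662\u8def", "")[[1]], " ")
  for (i in 1:200) {
    s <- paste(sample(alphabet, sample(0:30, 1), replace = TRUE),
               collapse = "")
    toks <- tokenize(s, res$tokenizer)[[1]]
    expect_identical(paste(toks, collapse = ""),
                     gsub("[[:space:]]", "", s))
  }
})

test_that("word_count drops stop words and punctuation", {
  res <- tokenizer_resources(c("the", "flood", "rose"),
                             stop_words = "the")
  expect_identical(word_count("", res), 0L)
  expect_identical(word_count("the flood rose", res), 2L)
  expect_identical(word_count("flood , rose !", res), 2L)
})

test_that("sentiment traversal weights degree adverbs and negation", {
  lex <- sentiment_lexicon(c(safe = 1, trapped = -1),
                           c(very = 2, slightly = 0.5), c("not", "no"))
  expect_equal(sentiment_value(c("x", "y"), lex), 0)
  expect_equal(sentiment_value(c("very", "safe"), lex), 2)
  # double negation restores the sign
  expect_equal(sentiment_value(c("not", "no", "trapped"), lex), -1)
  expect_equal(sentiment_value(c("not", "trapped"), lex), 1)
  # degree and negation combine multiplicatively within the window
  expect_equal(sentiment_value(c("not", "very", "safe"), lex), -2)
  # modifiers scope only up to the next emotional word
  expect_equal(sentiment_value(c("very", "safe", "trapped"), lex), 2 - 1)
})

test_that("sentiment value is additive over windows split at emotional words", {
  set.seed(4)
  lex <- test_resources()$sentiment
  pool <- c(names(lex$emotional), names(lex$degree), lex$negation,
            "tok001", "tok002")
  for (i in 1:50) {
    toks <- sample(pool, sample(5:25, 1), replace = TRUE)
    emo_pos <- which(toks %in% names(lex$emotional))
    if (length(emo_pos) == 0) next
    cut <- emo_pos[sample(length(emo_pos), 1)]
    whole <- sentiment_value(toks, lex)
    parts <- sentiment_value(toks[seq_len(cut)], lex) +
      sentiment_value(toks[-seq_len(cut)], lex)
    expect_equal(whole, parts)
  }
})

test_that("sentiment polarity splits at zero", {
  expect_identical(sentiment_polarity(5.97), "positive")
  expect_identical(sentiment_polarity(0), "neutral")
  expect_identical(sentiment_polarity(-0.5), "negative")
})

test_that("address detection needs a suffix with a real name prefix", {
  lex <- default_address_lexicon()
  # a named hospital: level 3
  hit <- detect_exact_address("\u53bb\u90d1\u5dde\u533b\u9662\u5427", lex)
  expect_identical(hit$has_exact_address, 1L)
  expect_identical(hit$matched_address_level, 3L)
  expect_identical(hit$matched_address_span, "\u90d1\u5dde\u533b\u9662")
  # no suffix at all
  expect_identical(detect_exact_address("tok001 tok002",
                                        lex)$has_exact_address, 0L)
  # bare suffix with no preceding name characters
  expect_identical(detect_exact_address("\u533b\u9662",
                                        lex)$has_exact_address, 0L)
  expect_identical(detect_exact_address(". \u533b\u9662",
                                        lex)$has_exact_address, 0L)
  # the most specific level wins, and numbered units count
  multi <- detect_exact_address(
    "\u90d1\u5dde\u8def \u674e\u5bb6\u5c0f\u533a3\u53f7\u697c", lex)
  expect_identical(multi$matched_address_level, 5L)
})

test_that("address detection agrees with a brute-force substring scan", {
  res <- test_resources()
  g <- small_corpus(n = 250, seed = 31)
  plain <- strip_markup(g$corpus$text)
  fast <- detect_exact_address(plain, res$address)
  # oracle: scan every substring ending for a suffix with a 2-char clean
  # prefix, independent of the package's matcher
  brute_one <- function(tx) {
    for (lv in 5:1) {
      for (suf in res$address$levels[[lv]]) {
        k <- nchar(suf)
        nc <- nchar(tx)
        if (nc < k + 2) next
        for (st in seq_len(nc - k + 1)) {
          if (substr(tx, st, st + k - 1) != suf) next
          if (st <= 2) next
          pre <- substr(tx, st - 2, st - 1)
          if (grepl("^[^[:space:][:punct:]]+$", pre)) return(1L)
        }
      }
    }
    0L
  }
  brute <- vapply(plain, brute_one, integer(1), USE.NAMES = FALSE)
  expect_identical(fast$has_exact_address, brute)
})

test_that("contact detection matches phone shapes only", {
  expect_identical(detect_contact("call 13812345678 now"), 1L)
  expect_identical(detect_contact("13812345678"), 1L)
  expect_identical(detect_contact("0371-1234567"), 1L)
  expect_identical(detect_contact("no digit runs here"), 0L)
  # a 12-digit run is not a mobile number
  expect_identical(detect_contact("138123456789"), 0L)
  expect_identical(detect_contact("tok001 tok002 sos01"), 0L)
})

test_that("extract_features composes the four steps", {
  res <- test_resources()
  empty <- microblog_corpus(tibble::tibble(
    id = "e", text = "", likes = 0L, comments = 0L, shares = 0L,
    prior_posts = 0L, followers = 0L, fans = 0L))
  f <- extract_features(empty, res)
  expect_equal(f$word_count, 0L)
  expect_equal(f$sentiment_value, 0)
  expect_equal(f$has_exact_address, 0L)
  expect_equal(f$has_contact, 0L)
  # contact only: detectors are independent
  one <- microblog_corpus(tibble::tibble(
    id = "c", text = "tok001 13812345678", likes = 0L, comments = 0L,
    shares = 0L, prior_posts = 0L, followers = 0L, fans = 0L))
  f1 <- extract_features(one, res)
  expect_equal(f1$has_contact, 1L)
  expect_equal(f1$has_exact_address, 0L)
  expect_equal(f1$word_count, 2L)
})
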