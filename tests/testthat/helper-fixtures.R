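# shared fixtures: all built in code at test time

test_resources <- function() generate_lexicons(1L)

# a small labelled corpus with known structure
small_corpus <- function(n = 120, seed = 42) {
  generate_corpus(generator_spec(n = n, seed = seed))
}

# hand-built three-post corpus for IO tests
tiny_corpus <- function() {
  microblog_corpus(tibble::tibble(
    id = c("a", "b", "c"),
    text = c("need a boat 13812345678",
             "\u6c34\u6df9\u4e86 <b>help</b>",   # CJK + markup
             "nothing here"),
    likes = c(196L, 0L, 3L), comments = c(5L, 0L, 1L),
    shares = c(2L, 0L, 0L), prior_posts = c(100L, 10L, 0L),
    followers = c(50L, 5L, 1L), fans = c(20L, 2L, 0L),
    label = c(1L, NA_integer_, 0L)))
}

# chance-level F for a classifier predicting positive at rate r,
# independent of gold labels with positive rate p
chance_f <- function(p, r) {
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}
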