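#' Specification of a synthetic microblog corpus
#'
#' The generator emulates the statistical structure of a labelled
#' disaster-relief microblog corpus: the corpus size and useful rate, the
#' joint distribution of exact-address and contact plants over four groups
#' (both / contact only / address only / neither), heavy-tailed word-count,
#' attention and author-history distributions with stated non-zero means,
#' lexicon-driven sentiment plants, and two contamination phenomena observed
#' in real corpora -- non-standard (corrupted) address writing within the
#' address-only group, and long, high-attention media reports that are
#' nevertheless useless for rescue.
#'
#' Two signal strengths control how much information each classifier arm can
#' exploit, and are deliberately routed through partially disjoint channels:
#' `token_signal` feeds rescue-signal tokens into the text (the channel the
#' text classifier sees, concentrated in "vivid" posts and growing with post
#' length), while `feature_signal` tilts the address/contact groups and the
#' attention counts of useful posts (the channel the rule scorer sees). The
#' partial disjointness gives a union integration genuine headroom to raise
#' recall, which is the mechanism the hybrid method relies on. At zero both
#' channels carry no label information.
#'
#' @param n corpus size (>= 10).
#' @param useful_rate probability a post is useful (default 1936/7979).
#' @param quadrant_probs marginal probabilities of (both, contact-only,
#'   address-only, neither); default (5461, 1202, 331, 985)/7979.
#' @param token_signal,feature_signal signal strengths in `[0, 1]`.
#' @param malformed_address_rate probability that an address plant in the
#'   address-only group is corrupted beyond suffix recognition (default
#'   0.40).
#' @param media_report_rate target share of media reports among the useless
#'   posts of the top attention decile (default 0.50).
#' @param sentiment_injection_rate probability a post carries sentiment
#'   plants.
#' @param word_count_meanlog,word_count_sdlog,short_post_prob,short_post_mean
#'   word-count model: a mixture of a short-post component
#'   (`1 + Poisson(short_post_mean)`) and a lognormal body; useful posts and
#'   media reports are longer by the two length multipliers.
#' @param useful_len_mult,media_len_mult length multipliers.
#' @param seed integer seed; every random choice derives from it.
#' @return A `generator_spec` object (a validated list).
#' @seealso [default_study_profile()], [generate_corpus()]
#' @export
generator_spec <- function(n = 7979,
                           useful_rate = 1936 / 7979,
                           quadrant_probs = c(5461, 1202, 331, 985) / 7979,
                           token_signal = 0.35,
                           feature_signal = 0.8,
                           malformed_address_rate = 0.40,
                           media_report_rate = 0.50,
                           sentiment_injection_rate = 0.55,
                           word_count_meanlog = 3.18,
                           word_count_sdlog = 0.80,
                           short_post_prob = 0.10,
                           short_post_mean = 1.6,
                           useful_len_mult = 1.55,
                           media_len_mult = 1.7,
                           seed = 1L) {
  stopifnot(n >= 10)
  stopifnot(length(quadrant_probs) == 4, all(quadrant_probs >= 0),
            abs(sum(quadrant_probs) - 1) < 1e-8)
  rates <- c(useful_rate, token_signal, feature_signal,
             malformed_address_rate, media_report_rate,
             sentiment_injection_rate, short_post_prob)
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (useful_rate <= 0 || useful_rate >= 1) {
    stop("useful_rate must be strictly between 0 and 1: ",
         "a single-class corpus cannot exercise the classifiers",
         call. = FALSE)
  }
  structure(list(
    n = as.integer(n), useful_rate = useful_rate,
    quadrant_probs = quadrant_probs, token_signal = token_signal,
    feature_signal = feature_signal,
    malformed_address_rate = malformed_address_rate,
    media_report_rate = media_report_rate,
    sentiment_injection_rate = sentiment_injection_rate,
    word_count_meanlog = word_count_meanlog,
    word_count_sdlog = word_count_sdlog,
    short_post_prob = short_post_prob,
    short_post_mean = short_post_mean,
    useful_len_mult = useful_len_mult,
    media_len_mult = media_len_mult,
    seed = as.integer(seed)
  ), class = "generator_spec")
}

#' The study-scale generator profile
#'
#' The default spec at full study scale: 7979 posts of which an expected
#' 1936 are useful, address/contact groups in proportion
#' 5461 : 1202 : 331 : 985, word counts averaging about 36, non-zero likes
#' averaging about 196, non-zero author history about 2299, non-zero
#' sentiment magnitude about 6, 40% malformed addresses in the address-only
#' group and about half of the top-attention useless posts being media
#' reports.
#'
#' @param seed integer seed.
#' @return A `generator_spec`.
#' @export
default_study_profile <- function(seed = 1L) {
  generator_spec(seed = seed)
}

# fixed scale constants of the count models; the lognormal means are solved
# so that the expected non-zero mean of likes is ~196 and of prior posts
# ~2299 under the default profile's mixture of useful/media uplifts
attention_params <- function() {
  list(zero_prob = c(likes = 0.35, comments = 0.45, shares = 0.50),
       meanlog = c(likes = 3.700, comments = 2.700, shares = 2.300),
       sdlog = 1.2, useful_uplift_per_signal = 1.25, media_uplift = 25)
}

user_params <- function() {
  list(zero_prob = c(prior_posts = 0.10, followers = 0.20, fans = 0.25),
       meanlog = c(prior_posts = 5.780, followers = 4.280, fans = 3.880),
       sdlog = 1.6, media_uplift = 20)
}

#' Generate fixture lexicon resources
#'
#' Builds a small, self-consistent resource set over a synthetic ASCII
#' vocabulary: 24 emotional words with balanced polarity, 6 degree adverbs,
#' 4 negation words, 12 stop words, 460 background content tokens plus 40
#' designated rescue-signal tokens, and the five-level address suffix
#' inventory of [default_address_lexicon()]. The construction is
#' deterministic; the seed is accepted for interface symmetry with
#' [generate_corpus()].
#'
#' @param seed integer seed (construction is deterministic regardless).
#' @return A resource list with elements `sentiment`, `address`,
#'   `tokenizer`, `contact_patterns`, plus `vocabulary` (background tokens)
#'   and `signal_tokens`.
#' @export
generate_lexicons <- function(seed = 1L) {
  pos <- sprintf("emop%02d", 1:12)
  neg <- sprintf("emon%02d", 1:12)
  emotional <- stats::setNames(rep(c(1, -1), each = 12), c(pos, neg))
  degree <- stats::setNames(c(1.3, 1.6, 1.8, 2.0, 2.5, 3.0),
                            sprintf("deg%02d", 1:6))
  negation <- sprintf("neg%02d", 1:4)
  stop_words <- sprintf("stp%02d", 1:12)
  background <- sprintf("tok%03d", 1:460)
  signal <- sprintf("sos%02d", 1:40)
  sentiment <- sentiment_lexicon(emotional, degree, negation)
  address <- default_address_lexicon()
  dictionary <- c(background, signal, names(emotional), names(degree),
                  negation, stop_words,
                  unlist(address$levels, use.names = FALSE))
  list(sentiment = sentiment,
       address = address,
       tokenizer = tokenizer_resources(dictionary, stop_words),
       contact_patterns = contact_patterns(),
       vocabulary = background,
       signal_tokens = signal)
}

# CJK single characters used as address name prefixes (common surnames;
# disjoint from every suffix character)
address_name_chars <- function() {
  c("\u5f20", "\u738b", "\u674e", "\u8d75", "\u5218", "\u9648",
    "\u6768", "\u9ec4", "\u5468", "\u5434", "\u5f90", "\u5b59",
    "\u9a6c", "\u6731", "\u80e1", "\u90ed", "\u4f55", "\u9ad8")
}

# character used to corrupt a suffix beyond recognition
address_corrupt_char <- function() "\u5047"

#' Generate a labelled synthetic corpus with ground truth
#'
#' Draws gold labels first and conditions every feature channel on them (see
#' [generator_spec()] for the channel design), composes each post's text
#' from the fixture vocabulary -- content tokens, optional sentiment blocks,
#' an optional address phrase (possibly corrupted), an optional contact
#' string, occasional markup wrappers, hyperlinks and hashtag fences -- and
#' draws heavy-tailed attention and author-history counts. The emitted
#' ground truth records, per post, the gold label, group, media-report flag,
#' plus the planted word count, sentiment value, address level, malformation
#' flag, and contact flag; re-running feature extraction on the emitted text
#' recovers the plants exactly, except where malformation was planted.
#'
#' @param spec a [generator_spec()].
#' @param resources optional resource list from [generate_lexicons()]; by
#'   default generated from `spec$seed`.
#' @return A list with `corpus` (a [microblog_corpus()], labelled) and
#'   `truth` (a tibble keyed by `id`).
#' @export
generate_corpus <- function(spec = default_study_profile(),
                            resources = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(resources)) resources <- generate_lexicons(spec$seed)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n
  p <- spec$useful_rate
  s_f <- spec$feature_signal
  s_t <- spec$token_signal
  label <- rbinom(n, 1, p)

  ## quadrants: useful posts tilted toward contact-bearing groups by the
  ## feature signal; useless conditional solved so the marginal matches
  q <- spec$quadrant_probs
  tilt <- c(0.80, 0.08, 0.04, 0.08)
  pu <- (1 - s_f) * q + s_f * tilt
  p0 <- pmax(q - p * pu, 0) / (1 - p)
  p0 <- p0 / sum(p0)
  quadrant <- integer(n)
  quadrant[label == 1] <- sample.int(4, sum(label == 1), TRUE, pu)
  quadrant[label == 0] <- sample.int(4, sum(label == 0), TRUE, p0)
  has_address_plant <- quadrant %in% c(1L, 3L)
  has_contact_plant <- quadrant %in% c(1L, 2L)

  ## media reports: useless, long, high-attention, signal-rich; the count is
  ## sized so that about media_report_rate of the top attention decile's
  ## useless posts are media reports
  media <- integer(n)
  n_media <- min(round(spec$media_report_rate * 0.082 * n),
                 sum(label == 0))
  if (n_media > 0) {
    media[sample(which(label == 0), n_media)] <- 1L
  }

  ## word counts: short-post/lognormal mixture, longer for useful and media
  lenm <- ifelse(label == 1, spec$useful_len_mult, 1) *
    ifelse(media == 1, spec$media_len_mult, 1)
  short <- runif(n) < spec$short_post_prob
  len <- ifelse(short,
                1 + rpois(n, spec$short_post_mean),
                pmax(1, round(rlnorm(n, spec$word_count_meanlog,
                                     spec$word_count_sdlog) * lenm)))

  ## token-signal intensity: vivid posts carry dense rescue vocabulary, and
  ## intensity grows with post length (short posts cannot show many cues)
  leak <- 0.02
  vivid_prob <- pmin(1, s_t * ifelse(
    label == 1, ifelse(has_contact_plant, 0.55, 2.7),
    ifelse(media == 1, 1.4, 0)))
  vivid <- rbinom(n, 1, vivid_prob)
  lenfac <- pmin(1, len / 45)^0.8
  lambda <- pmin(0.9, leak + s_t * lenfac *
                   ifelse(vivid == 1, 1.5,
                          ifelse(label == 1 | media == 1, 0.14, 0)))

  ## sentiment plants
  sent_here <- runif(n) < spec$sentiment_injection_rate
  lam_emo <- 6.1
  n_emo <- ifelse(sent_here, 1 + rpois(n, lam_emo * pmin(1, len / 35)), 0)

  ## plan and render each post
  bg <- resources$vocabulary
  sig <- resources$signal_tokens
  lex <- resources$sentiment
  stop_words <- resources$tokenizer$stop_words
  name_chars <- address_name_chars()
  texts <- character(n)
  truth_wc <- integer(n)
  truth_sent <- numeric(n)
  addr_level <- rep(NA_integer_, n)
  malformed <- integer(n)
  bg_prob <- 1 / seq_along(bg)
  sig_prob <- 1 / seq_along(sig)

  for (i in seq_len(n)) {
    plan <- plan_post(
      len = len[i], lambda = lambda[i], n_emo = n_emo[i],
      plant_address = has_address_plant[i],
      malform = has_address_plant[i] && quadrant[i] == 3L &&
        runif(1) < spec$malformed_address_rate,
      plant_contact = has_contact_plant[i],
      bg = bg, bg_prob = bg_prob, sig = sig, sig_prob = sig_prob,
      lex = lex, addr_levels = resources$address$levels,
      stop_words = stop_words, name_chars = name_chars)
    texts[i] <- plan$text
    truth_wc[i] <- plan$word_count
    truth_sent[i] <- plan$sentiment
    addr_level[i] <- plan$address_level
    malformed[i] <- plan$malformed
  }

  ## attention and author-history counts
  ap <- attention_params()
  att_uplift <- ifelse(label == 1, 1 + ap$useful_uplift_per_signal * s_f,
                       1) * ifelse(media == 1, ap$media_uplift, 1)
  draw_count <- function(zero_prob, meanlog, sdlog, uplift) {
    nz <- runif(n) >= zero_prob
    as.integer(round(ifelse(nz, rlnorm(n, meanlog, sdlog) * uplift, 0)))
  }
  likes <- draw_count(ap$zero_prob["likes"], ap$meanlog["likes"],
                      ap$sdlog, att_uplift)
  comments <- draw_count(ap$zero_prob["comments"], ap$meanlog["comments"],
                         ap$sdlog, att_uplift)
  shares <- draw_count(ap$zero_prob["shares"], ap$meanlog["shares"],
                       ap$sdlog, att_uplift)
  up <- user_params()
  user_uplift <- ifelse(media == 1, up$media_uplift, 1)
  prior_posts <- draw_count(up$zero_prob["prior_posts"],
                            up$meanlog["prior_posts"], up$sdlog,
                            user_uplift)
  followers <- draw_count(up$zero_prob["followers"],
                          up$meanlog["followers"], up$sdlog, user_uplift)
  fans <- draw_count(up$zero_prob["fans"], up$meanlog["fans"], up$sdlog,
                     user_uplift)

  ids <- sprintf("p%05d", seq_len(n))
  corpus <- microblog_corpus(
    tibble::tibble(id = ids, text = texts, likes = likes,
                   comments = comments, shares = shares,
                   prior_posts = prior_posts, followers = followers,
                   fans = fans, label = label),
    provenance = sprintf("synthetic: generator_spec seed=%d n=%d",
                         spec$seed, n))
  truth <- tibble::tibble(
    id = ids, label = label, quadrant = quadrant, media = media,
    vivid = vivid,
    planted_word_count = as.integer(truth_wc),
    planted_sentiment = truth_sent,
    planted_address_level = addr_level,
    address_malformed = malformed,
    planted_contact = as.integer(has_contact_plant))
  list(corpus = corpus, truth = truth)
}

# Compose one post: returns the rendered text plus the planted feature
# values implied by the plan. The planted word count is what the package's
# own tokenizer/stop-word pipeline will recover, computed here from the
# plan's token inventory, not by running the extractor.
plan_post <- function(len, lambda, n_emo, plant_address, malform,
                      plant_contact, bg, bg_prob, sig, sig_prob, lex,
                      addr_levels, stop_words, name_chars) {
  ## content tokens (rescue-signal vs background), minus room for plants
  n_sent_tokens <- 0L
  sent_blocks <- list()
  sentiment <- 0
  if (n_emo > 0) {
    polarity <- sample(c(1, -1), 1)
    for (b in seq_len(n_emo)) {
      emo_pool <- names(lex$emotional)[lex$emotional == polarity]
      block <- sample(emo_pool, 1)
      contrib <- polarity
      if (runif(1) < 0.5) {
        d <- sample(length(lex$degree), 1)
        block <- c(names(lex$degree)[d], block)
        contrib <- contrib * lex$degree[[d]]
      }
      if (runif(1) < 0.15) {
        k <- sample(1:2, 1, prob = c(0.8, 0.2))
        block <- c(sample(lex$negation, k, replace = FALSE), block)
        contrib <- contrib * (-1)^k
      }
      sent_blocks[[b]] <- block
      sentiment <- sentiment + contrib
      n_sent_tokens <- n_sent_tokens + length(block)
    }
  }
  addr_chunk <- NULL
  addr_tokens <- 0L
  addr_level <- NA_integer_
  if (plant_address) {
    addr_level <- sample(1:5, 1)
    suffix <- sample(addr_levels[[addr_level]], 1)
    n_name <- sample(2:3, 1)
    prefix <- paste(sample(name_chars, n_name), collapse = "")
    if (malform) {
      # non-standard writing: the whole suffix degenerates to filler
      # characters, so no feature word (not even an embedded shorter one,
      # as in "<unit> number" words) survives for the detector
      k <- nchar(suffix)
      suffix <- paste(rep(address_corrupt_char(), k), collapse = "")
      addr_tokens <- n_name + k                # shatters to single chars
      addr_level <- NA_integer_
    } else {
      addr_tokens <- n_name + 1L               # name chars + suffix word
    }
    addr_chunk <- paste0(prefix, suffix)
  }
  contact_chunk <- NULL
  contact_tokens <- 0L
  if (plant_contact) {
    if (runif(1) < 0.6) {
      contact_chunk <- paste0("1", sample(3:9, 1),
                              paste(sample(0:9, 9, TRUE), collapse = ""))
      contact_tokens <- 1L
    } else {
      contact_chunk <- paste0("0", paste(sample(0:9, 3, TRUE),
                                         collapse = ""), "-",
                              paste(sample(0:9, 7, TRUE), collapse = ""))
      contact_tokens <- 2L                     # two digit runs; '-' is
    }                                          # punctuation, not counted
  }
  extras <- n_sent_tokens + addr_tokens + contact_tokens
  n_content <- max(0L, len - extras)
  n_sig <- rbinom(1, n_content, lambda)
  content <- c(sample(sig, n_sig, TRUE, sig_prob),
               sample(bg, n_content - n_sig, TRUE, bg_prob))
  content <- sample(content)
  ## a few stop words, counted nowhere
  n_stop <- rpois(1, 2)
  units <- c(as.list(content),
             as.list(sample(stop_words, min(n_stop, length(stop_words)))))
  if (length(units) > 1) units <- sample(units)
  ## insert plants at random positions, keeping each block contiguous
  for (blk in sent_blocks) {
    at <- sample(0:length(units), 1)
    units <- append(units, list(blk), after = at)
  }
  if (!is.null(addr_chunk)) {
    units <- append(units, list(addr_chunk),
                    after = sample(0:length(units), 1))
  }
  if (!is.null(contact_chunk)) {
    units <- append(units, list(contact_chunk),
                    after = sample(0:length(units), 1))
  }
  text <- paste(unlist(units), collapse = " ")
  ## markup, hyperlinks, hashtag fences: removed downstream by
  ## strip_markup, so they must not change the planted counts
  r <- runif(3)
  if (r[1] < 0.25) text <- paste0("<b>", text, "</b>")
  if (r[2] < 0.15) {
    text <- paste(text, paste0("http://t.cn/",
                               paste(sample(letters, 5, TRUE),
                                     collapse = "")))
  }
  if (r[3] < 0.20) text <- paste0("#", text, "#")
  list(text = text,
       word_count = n_content + extras,
       sentiment = as.numeric(sentiment),
       address_level = addr_level,
       malformed = as.integer(malform))
}
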