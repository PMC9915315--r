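#' Sentiment lexicon
#'
#' Holds the three word lists used by the traversal-based sentiment scorer:
#' emotional words with polarity exactly +1 or -1, degree adverbs with a
#' positive real multiplier, and negation words. Emotional words carry no
#' graded strength of their own -- magnitude comes from the degree adverbs.
#'
#' @param emotional named numeric vector, values +1 or -1, names are words.
#' @param degree named numeric vector of positive multipliers.
#' @param negation character vector of negation words.
#' @return A `sentiment_lexicon` object.
#' @examples
#' sentiment_lexicon(c(safe = 1, trapped = -1), c(very = 2), "not")
#' @export
sentiment_lexicon <- function(emotional, degree, negation) {
  stopifnot(is.numeric(emotional), !is.null(names(emotional)),
            all(emotional %in% c(-1, 1)))
  stopifnot(is.numeric(degree), !is.null(names(degree)), all(degree > 0))
  negation <- as.character(negation)
  structure(list(emotional = emotional, degree = degree,
                 negation = negation),
            class = "sentiment_lexicon")
}

#' Address feature-word lexicon
#'
#' Chinese addresses are written as a chain of named units ending in
#' characteristic suffix words ("feature words"): a road, a hospital, a
#' residential compound, a building, a room. The lexicon maps each of five
#' specificity levels (1 = township/street ... 5 = detailed unit) to its
#' suffix inventory; a span ending in any of them counts as an exact address.
#'
#' @param levels list of exactly five non-empty character vectors, one per
#'   level 1--5.
#' @return An `address_lexicon` object.
#' @seealso [default_address_lexicon()]
#' @export
address_lexicon <- function(levels) {
  stopifnot(is.list(levels), length(levels) == 5,
            all(vapply(levels, length, integer(1)) > 0))
  levels <- lapply(levels, as.character)
  names(levels) <- as.character(1:5)
  structure(list(levels = levels), class = "address_lexicon")
}

#' Default five-level address feature-word inventory
#'
#' The standard inventory of Chinese address suffixes by specificity level:
#' township/street units (level 1), road/village units (2), points of
#' interest (3), street-level units (4), and detailed in-building units (5).
#' Words appearing at more than one level in common usage are kept at their
#' most specific level, since detection reports the highest-specificity
#' match.
#'
#' @return An `address_lexicon`.
#' @export
default_address_lexicon <- function() {
  address_lexicon(list(
    # township / street level
    c("\u9547", "\u4e61", "\u529e\u4e8b\u5904", "\u5c45\u59d4\u4f1a",
      "\u793e\u533a", "\u8857\u9053"),
    # road / village level
    c("\u6751", "\u7ec4", "\u961f", "\u91cc", "\u56ed", "\u5e84",
      "\u5f04", "\u5934", "\u6865", "\u53e3", "\u7530", "\u5e97",
      "\u5c9b", "\u8def", "\u8857"),
    # points of interest
    c("\u533b\u9662", "\u996d\u5e97", "\u4e2d\u5fc3", "\u5927\u697c",
      "\u573a", "\u9152\u5e97", "\u5bbe\u9986", "\u5e02\u573a",
      "\u62db\u5f85\u6240", "\u5927\u5b66", "\u5382", "\u5c40",
      "\u5bbf\u820d"),
    # street level
    c("\u5761", "\u5df7", "\u80e1\u540c", "\u6751\u59d4\u4f1a",
      "\u53f7", "\u9986", "\u5c45", "\u5c0f\u533a", "\u516c\u5bd3",
      "\u53f7\u9662", "\u82b1\u56ed", "\u5927\u53a6", "\u5e7f\u573a"),
    # detailed unit level
    c("\u5355\u5143", "\u5c42", "\u5ba4", "\u680b", "\u53f7\u697c",
      "\u5e62", "\u5ea7")
  ))
}

#' Tokenizer resources
#'
#' A dictionary of known multi-character words for longest-match segmentation
#' and a stop-word list removed before word counting.
#'
#' @param dictionary character vector of known words.
#' @param stop_words character vector of stop words.
#' @return A `tokenizer_resources` object.
#' @export
tokenizer_resources <- function(dictionary = character(),
                                stop_words = character()) {
  dictionary <- setdiff(as.character(dictionary), "")
  stop_words <- setdiff(as.character(stop_words), "")
  structure(list(dictionary = dictionary, stop_words = stop_words),
            class = "tokenizer_resources")
}

#' Default contact-information patterns
#'
#' Ordered regular expressions for contact detection, defaulting to mainland
#' Chinese phone shapes: an 11-digit mobile number (1 followed by 3--9 then
#' nine digits), a landline with a 3--4 digit area code, separator, and 7--8
#' digit number, and an explicit contact keyword followed by a digit run.
#'
#' @return Character vector of regular expressions.
#' @export
contact_patterns <- function() {
  c(mobile   = "(?<![0-9])1[3-9][0-9]{9}(?![0-9])",
    landline = "(?<![0-9])0[0-9]{2,3}[- ][0-9]{7,8}(?![0-9])",
    keyword  = paste0("(\u8054\u7cfb|\u7535\u8bdd|contact|tel)",
                      "[^0-9]{0,4}[0-9]{5,}"))
}

#' Read or write lexicon resources as plain text
#'
#' Lexicons ship and load as editable UTF-8 text: two tab-separated columns
#' (word, value) for emotional words and degree adverbs; one word per line
#' for negation and stop words; `level<TAB>suffix` pairs for the address
#' lexicon; one word per line for the dictionary. `read_resources()` expects
#' a directory containing `emotional.tsv`, `degree.tsv`, `negation.txt`,
#' `stopwords.txt`, `address.tsv`, and `dictionary.txt`;
#' `write_resources()` creates it.
#'
#' @param dir directory of lexicon files.
#' @return `read_resources()`: a list with elements `sentiment`, `address`,
#'   `tokenizer`, `contact_patterns`. `write_resources()`: `dir`, invisibly.
#' @export
read_resources <- function(dir) {
  two_col <- function(f) {
    x <- utils::read.table(file.path(dir, f), sep = "\t", quote = "",
                           fileEncoding = "UTF-8",
                           col.names = c("word", "value"),
                           stringsAsFactors = FALSE)
    stats::setNames(as.numeric(x$value), x$word)
  }
  one_col <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(character())
    x <- readLines(p, encoding = "UTF-8", warn = FALSE)
    x[nzchar(x)]
  }
  addr <- utils::read.table(file.path(dir, "address.tsv"), sep = "\t",
                            quote = "", fileEncoding = "UTF-8",
                            col.names = c("level", "suffix"),
                            stringsAsFactors = FALSE)
  list(
    sentiment = sentiment_lexicon(two_col("emotional.tsv"),
                                  two_col("degree.tsv"),
                                  one_col("negation.txt")),
    address = address_lexicon(split(addr$suffix,
                                    factor(addr$level, levels = 1:5))),
    tokenizer = tokenizer_resources(one_col("dictionary.txt"),
                                    one_col("stopwords.txt")),
    contact_patterns = contact_patterns()
  )
}

#' @rdname read_resources
#' @param resources a resource list as returned by [read_resources()] or
#'   [generate_lexicons()].
#' @export
write_resources <- function(resources, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(lines, f) {
    con <- file(file.path(dir, f), open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
  }
  sl <- resources$sentiment
  wr(paste(names(sl$emotional), sl$emotional, sep = "\t"), "emotional.tsv")
  wr(paste(names(sl$degree), sl$degree, sep = "\t"), "degree.tsv")
  wr(sl$negation, "negation.txt")
  wr(resources$tokenizer$stop_words, "stopwords.txt")
  wr(resources$tokenizer$dictionary, "dictionary.txt")
  al <- resources$address
  wr(unlist(lapply(1:5, function(l) {
    paste(l, al$levels[[l]], sep = "\t")
  })), "address.tsv")
  invisible(dir)
}
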