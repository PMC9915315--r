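#' Microblog corpus container
#'
#' A corpus is a tibble with one row per microblog and the fixed column set
#' `id`, `text`, `likes`, `comments`, `shares`, `prior_posts`, `followers`,
#' `fans`, `label`. The six count fields are non-negative integers; `label`
#' is 1 (useful for rescue), 0 (useless), or `NA` for unlabelled posts --
#' an absent label is deliberately distinct from a 0 label so that unlabelled
#' corpora can be classified without fabricating gold labels. Text is stored
#' raw: markup removal is a downstream feature-extraction step, never done at
#' the corpus layer.
#'
#' @param records data frame (or tibble) holding the columns above; `label`
#'   may be omitted entirely.
#' @param provenance free-text metadata (source description, generator seed).
#' @return A `mrim_corpus` tibble.
#' @examples
#' microblog_corpus(data.frame(
#'   id = "m1", text = "need a boat", likes = 3L, comments = 0L,
#'   shares = 1L, prior_posts = 10L, followers = 5L, fans = 2L))
#' @export
microblog_corpus <- function(records, provenance = "unspecified") {
  records <- tibble::as_tibble(records)
  if (!"label" %in% names(records)) records$label <- NA_integer_
  missing_cols <- setdiff(corpus_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[corpus_columns()]
  records$id <- as.character(records$id)
  records$text <- as.character(records$text)
  for (col in count_columns()) records[[col]] <- as.integer(records[[col]])
  records$label <- as.integer(records$label)
  err <- validate_corpus_rows(records)
  if (!is.null(err)) stop(err, call. = FALSE)
  if (anyDuplicated(records$id)) {
    stop("duplicate id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }
  structure(records,
            class = c("mrim_corpus", class(records)),
            provenance = provenance)
}

corpus_columns <- function() {
  c("id", "text", "likes", "comments", "shares",
    "prior_posts", "followers", "fans", "label")
}

count_columns <- function() {
  c("likes", "comments", "shares", "prior_posts", "followers", "fans")
}

# NULL when valid, otherwise a message naming the first offending field/row
validate_corpus_rows <- function(records) {
  for (col in count_columns()) {
    bad <- which(is.na(records[[col]]) | records[[col]] < 0L)
    if (length(bad) > 0) {
      return(sprintf("field '%s' must be a non-negative integer (row %d)",
                     col, bad[1]))
    }
  }
  bad <- which(!is.na(records$label) & !records$label %in% c(0L, 1L))
  if (length(bad) > 0) {
    return(sprintf("field 'label' must be 0, 1 or empty (row %d)", bad[1]))
  }
  bad <- which(is.na(records$text))
  if (length(bad) > 0) {
    return(sprintf("field 'text' is missing (row %d)", bad[1]))
  }
  NULL
}

#' Validate one raw record
#'
#' Coerces a named list (or one-row data frame) of raw fields into a one-row
#' corpus, enforcing the record invariants: six non-negative integer counts, a
#' binary-or-absent label, and non-missing text. Errors name the offending
#' field.
#'
#' @param raw named list or one-row data frame with the microblog fields.
#' @return A one-row `mrim_corpus` tibble.
#' @examples
#' validate_record(list(id = "a", text = "x", likes = 0, comments = 0,
#'                      shares = 0, prior_posts = 0, followers = 0, fans = 0))
#' @export
validate_record <- function(raw) {
  raw <- as.list(raw)
  if (is.null(raw$id)) raw$id <- "1"
  for (col in count_columns()) {
    v <- raw[[col]]
    if (is.null(v)) stop("field '", col, "' is missing", call. = FALSE)
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v) || v %% 1 != 0 || v < 0) {
      stop("field '", col, "' must be a non-negative integer", call. = FALSE)
    }
    raw[[col]] <- as.integer(v)
  }
  if (is.null(raw$text)) stop("field 'text' is missing", call. = FALSE)
  if (!is.null(raw$label) && !is.na(raw$label) &&
      !(raw$label %in% c(0, 1))) {
    stop("field 'label' must be 0, 1 or empty", call. = FALSE)
  }
  microblog_corpus(tibble::as_tibble(raw[!vapply(raw, is.null, logical(1))]))
}

#' Read a corpus from disk
#'
#' Two interchange formats are supported: `"delimited"` (UTF-8 CSV with a
#' header row and a quoted text field) and `"record_per_line"` (one JSON
#' object per line, same field names). Malformed rows are rejected -- never
#' silently dropped: the number of rejected rows is reported via a warning
#' and the `"rejected"` attribute, so `rows_in = rows_kept + rows_rejected`.
#'
#' @param path file to read.
#' @param format `"delimited"` or `"record_per_line"`.
#' @return A `mrim_corpus` tibble with attribute `rejected` (integer count)
#'   and `rejected_rows` (indices of rejected input rows).
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("delimited", "record_per_line")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "delimited") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    missing_cols <- setdiff(setdiff(corpus_columns(), "label"), names(raw))
    if (length(missing_cols) > 0) {
      stop("file is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    rows <- lapply(seq_len(nrow(raw)), function(i) as.list(raw[i, ]))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
  }
  kept <- vector("list", length(rows))
  rejected <- integer(0)
  for (i in seq_along(rows)) {
    rec <- tryCatch(coerce_row(rows[[i]]), error = function(e) NULL)
    if (is.null(rec)) rejected <- c(rejected, i) else kept[[i]] <- rec
  }
  kept <- kept[!vapply(kept, is.null, logical(1))]
  if (length(rejected) > 0) {
    warning(length(rejected), " malformed row(s) rejected (rows ",
            paste(head(rejected, 10), collapse = ", "),
            if (length(rejected) > 10) ", ..." else "", ")", call. = FALSE)
  }
  records <- if (length(kept) > 0) {
    do.call(rbind, lapply(kept, tibble::as_tibble))
  } else {
    empty_corpus_frame()
  }
  corpus <- microblog_corpus(records, provenance = paste0("file:", path))
  attr(corpus, "rejected") <- length(rejected)
  attr(corpus, "rejected_rows") <- rejected
  corpus
}

coerce_row <- function(row) {
  row <- as.list(row)
  out <- list(id = as.character(row$id), text = as.character(row$text))
  if (length(out$id) != 1 || length(out$text) != 1 || is.na(out$id) ||
      is.na(out$text)) {
    stop("bad id/text")
  }
  for (col in count_columns()) {
    v <- suppressWarnings(as.numeric(row[[col]]))
    if (length(v) != 1 || is.na(v) || v %% 1 != 0 || v < 0) {
      stop("field '", col, "' must be a non-negative integer")
    }
    out[[col]] <- as.integer(v)
  }
  lab <- row$label
  if (is.null(lab) || length(lab) != 1 || is.na(lab) ||
      identical(lab, "")) {
    out$label <- NA_integer_
  } else {
    v <- suppressWarnings(as.numeric(lab))
    if (is.na(v) || !v %in% c(0, 1)) stop("field 'label' must be 0 or 1")
    out$label <- as.integer(v)
  }
  out
}

empty_corpus_frame <- function() {
  tibble::tibble(id = character(), text = character(), likes = integer(),
                 comments = integer(), shares = integer(),
                 prior_posts = integer(), followers = integer(),
                 fans = integer(), label = integer())
}

#' Write a corpus to disk
#'
#' Lossless for every field, including absent labels (written as an empty
#' CSV field, or omitted from the JSON object), so that
#' `read_corpus(write_corpus(x))` is the identity.
#'
#' @param corpus a `mrim_corpus`.
#' @param path output file.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path,
                         format = c("delimited", "record_per_line")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "mrim_corpus"))
  df <- tibble::as_tibble(unclass_corpus(corpus))
  if (format == "delimited") {
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      row <- as.list(df[i, ])
      if (is.na(row$label)) row$label <- NULL
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

unclass_corpus <- function(corpus) {
  class(corpus) <- setdiff(class(corpus), "mrim_corpus")
  corpus
}

#' @export
print.mrim_corpus <- function(x, ...) {
  n_lab <- sum(!is.na(x$label))
  cat(sprintf("<mrim_corpus> %d posts (%d labelled, %d useful)\n",
              nrow(x), n_lab, sum(x$label == 1L, na.rm = TRUE)))
  cat("provenance:", attr(x, "provenance") %||% "unspecified", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
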