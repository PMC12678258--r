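# Corpus data model, readers/writers, and preprocessing.

#' Construct a document
#'
#' @param doc_id unique non-empty identifier.
#' @param title article title (may be empty).
#' @param body article text; must be non-empty after whitespace stripping.
#' @param year publication year or `NA`.
#' @param language ISO language code or `NA`.
#' @return an object of class `"document"`.
#' @export
document <- function(doc_id, title = "", body, year = NA_integer_,
                     language = NA_character_) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id))
    stop("doc_id must be a non-empty string")
  if (!is.character(body) || length(body) != 1L || !nzchar(trimws(body)))
    stop("document '", doc_id, "': body is empty")
  structure(list(doc_id = doc_id, title = title, body = body,
                 year = if (is.na(year)) NA_integer_ else as.integer(year),
                 language = language),
            class = "document")
}

#' Construct a corpus from a list of documents
#'
#' @param documents list of [document()] objects, order preserved.
#' @return an object of class `"corpus"` with elements `documents` and `N`.
#' @export
corpus <- function(documents) {
  if (length(documents) < 1L) stop("empty corpus: a corpus needs N >= 1 documents")
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate doc_id: ", paste(dup, collapse = ", "))
  structure(list(documents = documents, N = length(documents)), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus> ", x$N, " documents\n", sep = "")
  invisible(x)
}

#' @export
length.corpus <- function(x) x$N

corpus_ids <- function(x) vapply(x$documents, function(d) d$doc_id, character(1))

#' Read a corpus from JSONL or CSV
#'
#' JSONL: one object per line with keys `doc_id`, `title`, `body` and
#' optionally `year`, `language` (UTF-8). CSV: a header row with the same
#' column names, RFC-4180 quoting. Record order is preserved; duplicate
#' `doc_id`s are a hard error listing the offenders.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return a [corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty corpus file: ", path)
    docs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("record ", i, ": invalid JSON (", conditionMessage(e), ")"))
      for (f in c("doc_id", "body"))
        if (is.null(rec[[f]])) stop("record ", i, ": missing field '", f, "'")
      docs[[i]] <- document(rec$doc_id, rec$title %||% "", rec$body,
                            rec$year %||% NA_integer_,
                            rec$language %||% NA_character_)
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (!nrow(df)) stop("empty corpus file: ", path)
    for (f in c("doc_id", "body"))
      if (is.null(df[[f]])) stop("corpus CSV missing column '", f, "'")
    docs <- lapply(seq_len(nrow(df)), function(i)
      document(as.character(df$doc_id[i]),
               if (is.null(df$title)) "" else as.character(df$title[i]),
               as.character(df$body[i]),
               if (is.null(df$year)) NA_integer_ else df$year[i],
               if (is.null(df$language)) NA_character_ else df$language[i]))
  }
  corpus(docs)
}

#' Write a corpus as JSONL
#'
#' Inverse of [read_corpus()] on the JSONL dialect: `read_corpus` of the
#' written file reproduces the corpus exactly.
#'
#' @param x a [corpus()].
#' @param path output path.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  lines <- vapply(x$documents, function(d) {
    rec <- list(doc_id = d$doc_id, title = d$title, body = d$body)
    if (!is.na(d$year)) rec$year <- d$year
    if (!is.na(d$language)) rec$language <- d$language
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default English stop-word list
#'
#' A packaged static list of common English function words, used so that
#' results do not drift with external library versions. Override by passing
#' your own character vector (or a file read with `readLines`) to
#' [preprocess()].
#'
#' @return character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "if", "then", "else", "when",
    "while", "of", "at", "by", "for", "with", "about", "against", "between",
    "into", "through", "during", "before", "after", "above", "below", "to",
    "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
    "further", "once", "here", "there", "all", "any", "both", "each", "few",
    "more", "most", "other", "some", "such", "no", "nor", "not", "only",
    "own", "same", "so", "than", "too", "very", "can", "will", "just",
    "should", "now", "i", "me", "my", "we", "our", "you", "your", "he",
    "him", "his", "she", "her", "it", "its", "they", "them", "their",
    "what", "which", "who", "whom", "this", "that", "these", "those", "am",
    "is", "are", "was", "were", "be", "been", "being", "have", "has", "had",
    "having", "do", "does", "did", "doing", "would", "could", "ought",
    "as", "until", "because", "where", "why", "how", "also", "may", "might",
    "must", "shall", "upon", "via", "per", "etc", "eg", "ie")
}

# Abbreviations that must not terminate a sentence at a trailing period.
abbrev_guard <- c("e.g", "i.e", "et al", "etc", "fig", "vs", "cf", "dr", "mr",
                  "mrs", "no", "approx")

split_sentences <- function(text) {
  # protect guarded abbreviations, then split on ./?/! runs
  guarded <- text
  for (a in abbrev_guard) {
    guarded <- gsub(paste0("(?i)\\b", gsub("\\.", "\\\\.", a), "\\."),
                    gsub("\\.", "․", paste0(a, ".")), guarded, perl = TRUE)
  }
  parts <- strsplit(guarded, "[.!?]+", perl = TRUE)[[1]]
  parts <- gsub("․", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

tokenize_words <- function(text, token_regex = "[a-z0-9][a-z0-9'-]*") {
  m <- gregexpr(token_regex, tolower(text), perl = TRUE)
  regmatches(tolower(text), m)[[1]]
}

#' Preprocess a document into a token sequence
#'
#' Lowercases, splits sentences (period/question/exclamation with an
#' abbreviation guard), tokenizes words, and removes stop words and pure
#' punctuation. Sentence boundaries are recorded before stop-word removal and
#' re-expressed as spans over the retained tokens; spans partition the token
#' list. A document reduced to zero tokens is returned flagged empty rather
#' than raising an error.
#'
#' @param doc a [document()], or a plain string.
#' @param stopwords character vector of words to drop; default
#'   [default_stopwords()].
#' @param token_regex regex defining a word token (applied to lowercased
#'   text).
#' @return an object of class `"token_seq"`: list with `doc_id`, `tokens`,
#'   `sentences` (list of integer index spans) and `empty` flag.
#' @export
preprocess <- function(doc, stopwords = default_stopwords(),
                       token_regex = "[a-z0-9][a-z0-9'-]*") {
  if (is.character(doc)) doc <- document("doc", body = doc)
  stopifnot(inherits(doc, "document"))
  sents <- split_sentences(paste(doc$title, doc$body))
  tokens <- character(0)
  spans <- list()
  for (s in sents) {
    toks <- tokenize_words(s, token_regex)
    toks <- toks[!(toks %in% stopwords)]
    if (!length(toks)) next
    spans[[length(spans) + 1L]] <- seq.int(length(tokens) + 1L,
                                           length(tokens) + length(toks))
    tokens <- c(tokens, toks)
  }
  structure(list(doc_id = doc$doc_id, tokens = tokens, sentences = spans,
                 empty = length(tokens) == 0L),
            class = "token_seq")
}

#' @export
print.token_seq <- function(x, ...) {
  cat("<token_seq> ", x$doc_id, ": ", length(x$tokens), " tokens, ",
      length(x$sentences), " sentences",
      if (x$empty) " (flagged empty)", "\n", sep = "")
  invisible(x)
}

token_seq_from_tokens <- function(doc_id, tokens, sentences = NULL) {
  if (is.null(sentences))
    sentences <- if (length(tokens)) list(seq_along(tokens)) else list()
  structure(list(doc_id = doc_id, tokens = tokens, sentences = sentences,
                 empty = length(tokens) == 0L),
            class = "token_seq")
}

#' Preprocess every document of a corpus
#'
#' @param x a [corpus()].
#' @inheritParams preprocess
#' @return list of `token_seq`, one per document, in corpus order.
#' @export
preprocess_corpus <- function(x, stopwords = default_stopwords(),
                              token_regex = "[a-z0-9][a-z0-9'-]*") {
  stopifnot(inherits(x, "corpus"))
  lapply(x$documents, preprocess, stopwords = stopwords,
         token_regex = token_regex)
}
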