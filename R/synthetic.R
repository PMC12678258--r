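# Seeded synthetic corpora with planted phrases, a planted topic hierarchy,
# and simulated rater panels. This stands in for a real literature corpus in
# all tests and examples; it controls exactly the statistics the downstream
# stages consume (phrase frequencies, document spread, topic structure).

#' Specify a synthetic corpus
#'
#' @param n_docs number of documents.
#' @param vocab_size size of the Zipf-distributed noise vocabulary.
#' @param planted_phrases data.frame with columns `phrase` (multi-word text,
#'   space-separated tokens), `total_freq`, `doc_freq`, `topic` (topic id).
#' @param topic_hierarchy data.frame with columns `parent`, `child` (topic
#'   ids); must be acyclic.
#' @param noise_rate mean number of noise tokens per planted occurrence slot;
#'   controls how much filler text surrounds the planted material.
#' @param zipf_offset rank offset of the Zipf noise distribution
#'   (probabilities proportional to `(rank + zipf_offset)^-1.1`). The
#'   generator emulates an already-preprocessed corpus: the ultra-frequent
#'   Zipf head of raw text corresponds to stop words that preprocessing
#'   removes, so the default offset (50) truncates it.
#' @param doc_length target number of noise tokens per document (Poisson
#'   mean).
#' @param seed integer seed governing all generation streams.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_docs, vocab_size = 500, planted_phrases,
                           topic_hierarchy = NULL, noise_rate = 0.5,
                           doc_length = 40, zipf_offset = 50, seed = 1L) {
  stopifnot(n_docs >= 1, vocab_size >= 10)
  pp <- as.data.frame(planted_phrases, stringsAsFactors = FALSE)
  req <- c("phrase", "total_freq", "doc_freq", "topic")
  if (!all(req %in% names(pp)))
    stop("planted_phrases needs columns: ", paste(req, collapse = ", "))
  bad <- pp$doc_freq > n_docs
  if (any(bad))
    stop("infeasible spec: doc_freq > n_docs for phrase(s): ",
         paste(pp$phrase[bad], collapse = ", "))
  bad <- pp$total_freq < pp$doc_freq
  if (any(bad))
    stop("infeasible spec: total_freq < doc_freq for phrase(s): ",
         paste(pp$phrase[bad], collapse = ", "))
  if (!is.null(topic_hierarchy)) {
    th <- as.data.frame(topic_hierarchy, stringsAsFactors = FALSE)
    if (!all(c("parent", "child") %in% names(th)))
      stop("topic_hierarchy needs columns parent, child")
    if (has_cycle_edges(th$parent, th$child))
      stop("topic_hierarchy must be acyclic")
  } else th <- data.frame(parent = character(0), child = character(0))
  structure(list(n_docs = as.integer(n_docs),
                 vocab_size = as.integer(vocab_size),
                 planted_phrases = pp, topic_hierarchy = th,
                 noise_rate = noise_rate, doc_length = doc_length,
                 zipf_offset = zipf_offset, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Kahn's algorithm cycle check over an edge list of arbitrary labels.
has_cycle_edges <- function(parent, child) {
  nodes <- unique(c(parent, child))
  if (!length(nodes)) return(FALSE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (c_ in child) indeg[c_] <- indeg[c_] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- child[parent == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(nodes)
}

#' Generate a seeded synthetic corpus with planted phrases
#'
#' Every planted phrase is inserted as a contiguous token run exactly
#' `total_freq` times spread over exactly `doc_freq` distinct documents
#' (chosen by seeded sampling); remaining tokens are drawn from a Zipf(s=1.1)
#' noise vocabulary of made-up word forms. The same seed yields a
#' byte-identical corpus.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `corpus` (a [corpus()]) and `truth` (class
#'   `"ground_truth"`: `phrases` frequency table, `hierarchy` edge list,
#'   `topic_of` named vector phrase -> topic, `doc_topic` topic per
#'   document).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pp <- spec$planted_phrases
  n <- spec$n_docs
  with_seed(derive_seed(spec$seed, 1L), {
    # each document gets a topic (round-robin over the planted topics, in
    # seeded random order) so that documents are topically coherent, the
    # way articles have subjects; a phrase is planted into documents of
    # its own topic whenever that is feasible
    topics <- unique(pp$topic)
    doc_topic <- if (length(topics))
      sample(rep(topics, length.out = n)) else rep(NA_character_, n)
    # per-document buckets of planted phrase occurrences
    slots <- vector("list", n)
    for (i in seq_len(n)) slots[[i]] <- character(0)
    if (nrow(pp)) for (k in seq_len(nrow(pp))) {
      host <- which(doc_topic == pp$topic[k])
      if (length(host) < pp$doc_freq[k]) host <- seq_len(n)
      docs_k <- host[sample.int(length(host), pp$doc_freq[k])]
      extra <- pp$total_freq[k] - pp$doc_freq[k]
      # each chosen doc gets one occurrence; extras spread over chosen docs
      counts <- stats::setNames(rep(1L, length(docs_k)), docs_k)
      if (extra > 0) {
        add <- docs_k[sample.int(length(docs_k), extra, replace = TRUE)]
        for (d in add) counts[as.character(d)] <- counts[as.character(d)] + 1L
      }
      for (d in names(counts))
        slots[[as.integer(d)]] <- c(slots[[as.integer(d)]],
                                    rep(pp$phrase[k], counts[[d]]))
    }
    vocab <- paste0("w", sprintf("%04d", seq_len(spec$vocab_size)))
    zipf_p <- (seq_len(spec$vocab_size) + spec$zipf_offset)^(-1.1)
    zipf_p <- zipf_p / sum(zipf_p)
    docs <- vector("list", n)
    for (i in seq_len(n)) {
      n_noise <- max(3L, stats::rpois(1, spec$doc_length))
      noise <- sample(vocab, n_noise, replace = TRUE, prob = zipf_p)
      occ <- sample(slots[[i]])          # shuffle occurrence order
      # one sentence per planted occurrence (keeps the run contiguous),
      # noise split around them into sentences
      pieces <- character(0)
      cut <- sort(sample.int(n_noise, min(n_noise - 1L, length(occ) + 1L)))
      noise_groups <- split(noise, findInterval(seq_len(n_noise), cut + 1L))
      gi <- 1L
      for (ph in occ) {
        if (gi <= length(noise_groups)) {
          pieces <- c(pieces, paste(noise_groups[[gi]], collapse = " "))
          gi <- gi + 1L
        }
        pieces <- c(pieces, ph)
      }
      while (gi <= length(noise_groups)) {
        pieces <- c(pieces, paste(noise_groups[[gi]], collapse = " "))
        gi <- gi + 1L
      }
      body <- paste0(paste(pieces, collapse = ". "), ".")
      docs[[i]] <- document(sprintf("doc%04d", i), title = "", body = body,
                            year = 2020L)
    }
    truth <- structure(list(
      phrases = data.frame(phrase = pp$phrase, total_freq = pp$total_freq,
                           doc_freq = pp$doc_freq, topic = pp$topic,
                           stringsAsFactors = FALSE),
      hierarchy = spec$topic_hierarchy,
      topic_of = if (nrow(pp)) stats::setNames(pp$topic, pp$phrase)
                 else stats::setNames(character(0), character(0)),
      doc_topic = doc_topic),
      class = "ground_truth")
    list(corpus = corpus(docs), truth = truth)
  })
}

#' Write ground truth tables as CSV
#'
#' @param truth a `"ground_truth"` object from [generate_corpus()].
#' @param phrases_path,hierarchy_path output CSV paths.
#' @export
write_ground_truth <- function(truth, phrases_path, hierarchy_path) {
  utils::write.csv(truth$phrases, phrases_path, row.names = FALSE)
  utils::write.csv(truth$hierarchy, hierarchy_path, row.names = FALSE)
  invisible(NULL)
}

#' Simulate a rater panel
#'
#' Generates an items x raters table of 1-5 Likert scores. Each item has a
#' latent "true" score drawn from `latent_probs`; each rater independently
#' either copies the latent score (with probability `agreement`) or draws
#' uniformly from 1-5. At `agreement = 1` all raters are identical; at
#' `agreement = 0` ratings are independent uniform draws, so
#' chance-corrected agreement is ~0.
#'
#' The default latent distribution is skewed toward 4-5 (mean 4.35),
#' emulating expert panels scoring indicators that earlier screening
#' already vetted.
#'
#' @param n_items number of rated items.
#' @param n_raters number of raters (columns).
#' @param agreement probability in [0, 1] that a rater reports the latent
#'   score.
#' @param seed integer seed.
#' @param groups optional character vector of length `n_raters` assigning
#'   raters to groups (e.g. NPI stringency strata); stored as an attribute.
#' @param latent_probs probabilities of latent scores 1-5.
#' @return integer matrix `n_items` x `n_raters` with class
#'   `"rating_table"`.
#' @export
generate_raters <- function(n_items, n_raters, agreement, seed = 1L,
                            groups = NULL,
                            latent_probs = c(0.01, 0.03, 0.10, 0.32, 0.54)) {
  stopifnot(n_items >= 1, n_raters >= 2, length(latent_probs) == 5)
  if (agreement < 0 || agreement > 1) stop("agreement must be in [0, 1]")
  with_seed(derive_seed(seed, 2L), {
    latent <- sample.int(5L, n_items, replace = TRUE, prob = latent_probs)
    m <- matrix(0L, n_items, n_raters,
                dimnames = list(paste0("item", seq_len(n_items)),
                                paste0("rater", seq_len(n_raters))))
    for (j in seq_len(n_raters)) {
      copy <- stats::runif(n_items) < agreement
      m[, j] <- ifelse(copy, latent, sample.int(5L, n_items, replace = TRUE))
    }
    if (!is.null(groups)) {
      stopifnot(length(groups) == n_raters)
      attr(m, "groups") <- as.character(groups)
    }
    class(m) <- c("rating_table", class(m))
    m
  })
}
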