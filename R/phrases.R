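# Candidate-phrase extraction and the four-phase screening funnel:
#   Phase 1  initial pool by frequency (>= pool_min_freq, optionally the
#            upper quartile Q3 of the pool frequency distribution)
#   Phase 2  frequency and source-breadth thresholds
#   Phase 3  semantic relevance threshold
#   Phase 4  quality filters: length, generic single words, TF-IDF and
#            specificity floors, ambiguity blocklist, reviewer consensus
#            (when ratings are supplied), and near-duplicate merging.

#' Extract contiguous n-grams with exact frequency counts
#'
#' Enumerates all contiguous 1..`max_n`-grams within sentence spans of the
#' preprocessed corpus and counts each candidate's total frequency and
#' document frequency exactly.
#'
#' @param seqs list of `token_seq` (one per document), or a [corpus()]
#'   (preprocessed internally).
#' @param max_n longest n-gram length (default 6).
#' @return a `phrase_pool`: data.frame with columns `phrase`, `n_words`,
#'   `total_freq`, `doc_freq`, sorted by descending `total_freq` then
#'   phrase text.
#' @export
extract_ngrams <- function(seqs, max_n = 6L) {
  if (inherits(seqs, "corpus")) seqs <- preprocess_corpus(seqs)
  counts <- new.env(parent = emptyenv())
  docs <- new.env(parent = emptyenv())
  for (di in seq_along(seqs)) {
    s <- seqs[[di]]
    seen <- character(0)
    for (span in s$sentences) {
      toks <- s$tokens[span]
      L <- length(toks)
      for (n in seq_len(min(max_n, L))) {
        if (L - n + 1L < 1L) next
        for (start in seq_len(L - n + 1L)) {
          g <- paste(toks[start:(start + n - 1L)], collapse = " ")
          counts[[g]] <- (counts[[g]] %||% 0L) + 1L
          if (!(g %in% seen)) {
            docs[[g]] <- (docs[[g]] %||% 0L) + 1L
            seen <- c(seen, g)
          }
        }
      }
    }
  }
  phrases <- ls(counts)
  pool <- data.frame(
    phrase = phrases,
    n_words = lengths(strsplit(phrases, " ", fixed = TRUE)),
    total_freq = vapply(phrases, function(g) counts[[g]], integer(1),
                        USE.NAMES = FALSE),
    doc_freq = vapply(phrases, function(g) docs[[g]], integer(1),
                      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  pool <- pool[order(-pool$total_freq, pool$phrase), ]
  rownames(pool) <- NULL
  class(pool) <- c("phrase_pool", "data.frame")
  pool
}

#' Normalized TF-IDF score for a phrase pool
#'
#' Raw score `total_freq * ln(N / doc_freq)`, normalized into [0, 1] by the
#' pool maximum. A phrase present in every document gets 0; the pool's
#' argmax gets 1. Phrases with `doc_freq = 0` are excluded.
#'
#' @param pool a `phrase_pool`.
#' @param n_docs number of documents `N` in the corpus.
#' @return the pool with a `tfidf_norm` column added.
#' @export
tfidf_norm <- function(pool, n_docs) {
  pool <- pool[pool$doc_freq > 0, ]
  raw <- pool$total_freq * log(n_docs / pool$doc_freq)
  mx <- max(raw, 0)
  pool$tfidf_norm <- if (mx > 0) raw / mx else rep(0, length(raw))
  pool
}

#' Domain centroid embedding
#'
#' Mean encoder embedding of all (non-empty) corpus documents; the anchor
#' against which phrase relevance is scored.
#'
#' @param encoder an encoder.
#' @param seqs list of `token_seq` or a [corpus()].
#' @return numeric vector of length `encoder$d`.
#' @export
domain_centroid <- function(encoder, seqs) {
  if (inherits(seqs, "corpus")) seqs <- preprocess_corpus(seqs)
  seqs <- Filter(function(s) length(s$tokens) > 0, seqs)
  if (!length(seqs)) stop("no non-empty documents")
  colMeans(t(vapply(seqs, function(s) encode(encoder, s),
                    numeric(encoder$d))))
}

#' Semantic relevance of a phrase to the domain centroid
#'
#' `(cosine(phrase embedding, centroid) + 1) / 2`, mapped into [0, 1].
#'
#' @param phrase phrase text (space-separated tokens).
#' @param encoder an encoder.
#' @param centroid the [domain_centroid()] vector.
#' @return scalar in [0, 1].
#' @export
relevance_score <- function(phrase, encoder, centroid) {
  emb <- encode(encoder, strsplit(phrase, " ", fixed = TRUE)[[1]])
  if (all(emb == 0)) stop("zero embedding for phrase: ", phrase)
  (cosine_similarity(emb, centroid) + 1) / 2
}

#' Add relevance scores to a pool
#'
#' @param pool a `phrase_pool`.
#' @inheritParams relevance_score
#' @return the pool with a `relevance` column.
#' @export
add_relevance <- function(pool, encoder, centroid) {
  pool$relevance <- vapply(pool$phrase, relevance_score, numeric(1),
                           encoder = encoder, centroid = centroid,
                           USE.NAMES = FALSE)
  pool
}

#' Specificity index of phrases
#'
#' Mean token IDF (`ln(N / df_token)`) of the phrase's tokens, divided by
#' the corpus's 95th-percentile token IDF (linear-interpolation quantile)
#' and clipped to [0, 1]. Tokens unseen in the corpus are treated as having
#' maximal IDF (`ln N`, a document frequency of 1). Phrases of ubiquitous
#' tokens score 0; phrases of rare tokens score 1.
#'
#' @param pool a `phrase_pool`.
#' @param seqs list of `token_seq` or a [corpus()].
#' @return the pool with a `specificity` column.
#' @export
specificity_index <- function(pool, seqs) {
  if (inherits(seqs, "corpus")) seqs <- preprocess_corpus(seqs)
  N <- length(seqs)
  df_tok <- table(unlist(lapply(seqs, function(s) unique(s$tokens)),
                         use.names = FALSE))
  idf <- log(N / as.numeric(df_tok))
  names(idf) <- names(df_tok)
  denom <- stats::quantile(idf, 0.95, type = 7, names = FALSE)
  pool$specificity <- vapply(pool$phrase, function(p) {
    toks <- strsplit(p, " ", fixed = TRUE)[[1]]
    vals <- idf[toks]
    vals[is.na(vals)] <- log(N)
    if (denom <= 0) return(if (mean(vals) > 0) 1 else 0)
    min(max(mean(vals) / denom, 0), 1)
  }, numeric(1), USE.NAMES = FALSE)
  pool
}

#' Upper-quartile pool frequency threshold
#'
#' Q3 of the pool's total-frequency distribution, by the
#' linear-interpolation (type-7) quantile.
#'
#' @param pool a `phrase_pool` (non-empty).
#' @return scalar threshold.
#' @export
quartile_pool_threshold <- function(pool) {
  if (!nrow(pool)) stop("empty pool")
  stats::quantile(pool$total_freq, 0.75, type = 7, names = FALSE)
}

#' Screening configuration
#'
#' Defaults follow the screening rules used throughout the package: initial
#' pool frequency >= 5; retention requires total frequency >= 7 across the
#' corpus and presence in >= 10 different articles; semantic relevance
#' >= 0.65; quality filters drop phrases longer than 6 words, generic
#' single words, phrases under the 0.45 normalized TF-IDF or 0.50
#' specificity floors, blocklisted (ambiguous) phrases, and merge
#' near-duplicates at cosine >= 0.9 keeping the higher-relevance member.
#'
#' @param pool_min_freq Phase-1 minimum total frequency.
#' @param use_q3_pool_threshold if `TRUE`, Phase 1 instead uses
#'   `max(pool_min_freq, Q3)` where Q3 is [quartile_pool_threshold()].
#' @param min_total_freq,min_doc_freq Phase-2 thresholds.
#' @param min_relevance Phase-3 relevance threshold.
#' @param min_tfidf,min_specificity Phase-4 score floors; set `apply_tfidf`
#'   / `apply_specificity` to `FALSE` to disable.
#' @param apply_tfidf,apply_specificity toggles for the Phase-4 score
#'   floors.
#' @param max_words Phase-4 length cap.
#' @param generic_word_list single words dropped at Phase 4.
#' @param blocklist phrases dropped as ambiguous at Phase 4.
#' @param merge_similarity cosine threshold for near-duplicate merging.
#' @param absorb_nested drop a phrase nested inside a longer candidate
#'   when its residual frequency outside the longer phrase falls below
#'   `pool_min_freq` (retaining the more precise expression).
#' @param consensus_threshold minimum reviewer approval fraction (used only
#'   when ratings are supplied to [screen()]).
#' @return object of class `"screening_config"`.
#' @export
screening_config <- function(pool_min_freq = 5L, use_q3_pool_threshold = FALSE,
                             min_total_freq = 7L, min_doc_freq = 10L,
                             min_relevance = 0.65, min_tfidf = 0.45,
                             min_specificity = 0.50, apply_tfidf = TRUE,
                             apply_specificity = TRUE, max_words = 6L,
                             generic_word_list = c("community", "problem",
                                                   "impact", "system",
                                                   "factor", "approach"),
                             blocklist = character(0),
                             merge_similarity = 0.9,
                             absorb_nested = TRUE,
                             consensus_threshold = 2 / 3) {
  if (pool_min_freq > min_total_freq)
    stop("pool_min_freq must be <= min_total_freq")
  structure(list(pool_min_freq = pool_min_freq,
                 use_q3_pool_threshold = isTRUE(use_q3_pool_threshold),
                 min_total_freq = min_total_freq, min_doc_freq = min_doc_freq,
                 min_relevance = min_relevance, min_tfidf = min_tfidf,
                 min_specificity = min_specificity,
                 apply_tfidf = isTRUE(apply_tfidf),
                 apply_specificity = isTRUE(apply_specificity),
                 max_words = as.integer(max_words),
                 generic_word_list = generic_word_list,
                 blocklist = blocklist,
                 merge_similarity = merge_similarity,
                 absorb_nested = isTRUE(absorb_nested),
                 consensus_threshold = consensus_threshold),
            class = "screening_config")
}

phrase_embedding <- function(encoder, phrase)
  encode(encoder, strsplit(phrase, " ", fixed = TRUE)[[1]])

# is `a` (token vector) a contiguous run inside `b`?
is_sub_run <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na >= nb) return(FALSE)
  for (s in seq_len(nb - na + 1L))
    if (all(b[s:(s + na - 1L)] == a)) return(TRUE)
  FALSE
}

# Nested-phrase absorption: a phrase contained as a contiguous token run in
# a longer candidate is dropped when its frequency outside that candidate
# (total_freq minus the containing phrase's total_freq, maximised over
# containing candidates) falls below min_residual. Keeps the semantically
# more precise (longer) expression.
absorb_nested_phrases <- function(df, min_residual) {
  if (nrow(df) <= 1L) return(df)
  toks <- strsplit(df$phrase, " ", fixed = TRUE)
  drop <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    best_cover <- 0L
    for (j in seq_len(nrow(df))) {
      if (i == j || df$n_words[j] <= df$n_words[i]) next
      if (is_sub_run(toks[[i]], toks[[j]]))
        best_cover <- max(best_cover, df$total_freq[j])
    }
    if (best_cover > 0L && df$total_freq[i] - best_cover < min_residual)
      drop[i] <- TRUE
  }
  df[!drop, ]
}

# Deterministic near-duplicate merge: phrases visited in canonical order
# (descending relevance, then alphabetical); a phrase is kept iff its
# embedding cosine with every already-kept phrase is < merge_similarity.
merge_near_duplicates <- function(df, encoder, merge_similarity) {
  if (nrow(df) <= 1L || is.null(encoder)) return(df)
  ord <- order(-df$relevance, df$phrase)
  df <- df[ord, ]
  emb <- t(vapply(df$phrase, phrase_embedding, numeric(encoder$d),
                  encoder = encoder, USE.NAMES = FALSE))
  keep <- logical(nrow(df))
  kept_rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    dup <- FALSE
    for (j in kept_rows) {
      if (cosine_similarity(emb[i, ], emb[j, ]) >= merge_similarity) {
        dup <- TRUE; break
      }
    }
    if (!dup) { keep[i] <- TRUE; kept_rows <- c(kept_rows, i) }
  }
  df[keep, ]
}

#' Run the four-phase screening funnel
#'
#' Applies Phases 1-4 (see [screening_config()]) to a scored pool and
#' returns an auditable per-phase report. Phase counts are non-increasing
#' and each phase's survivors are a subset of the previous phase's. The
#' result is independent of pool row order (merging uses a deterministic
#' canonical order).
#'
#' @param pool a `phrase_pool` with `total_freq`, `doc_freq`, `relevance`
#'   (and `tfidf_norm` / `specificity` when those floors are enabled).
#' @param cfg a [screening_config()].
#' @param encoder encoder for near-duplicate merging; if `NULL`, merging is
#'   skipped.
#' @param quality_ratings optional named numeric vector of reviewer approval
#'   fractions per phrase; phrases below `cfg$consensus_threshold` are
#'   dropped at Phase 4. When omitted the consensus gate is skipped.
#' @return object of class `"funnel_report"`: list with `counts` (named
#'   vector pool/phase1..phase4), `retained` (list of per-phase phrase
#'   character vectors), `pool4` (data.frame of final survivors), `config`.
#' @export
screen <- function(pool, cfg = screening_config(), encoder = NULL,
                   quality_ratings = NULL) {
  df <- as.data.frame(pool)
  df <- df[order(df$phrase), ]           # canonical order
  need <- c("phrase", "n_words", "total_freq", "doc_freq", "relevance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pool missing columns: ", paste(miss, collapse = ", "))

  p1_thr <- cfg$pool_min_freq
  if (cfg$use_q3_pool_threshold && nrow(df))
    p1_thr <- max(p1_thr, quartile_pool_threshold(df))
  p1 <- df[df$total_freq >= p1_thr, ]
  p2 <- p1[p1$total_freq >= cfg$min_total_freq &
           p1$doc_freq >= cfg$min_doc_freq, ]
  p3 <- p2[p2$relevance >= cfg$min_relevance, ]

  p4 <- p3[p3$n_words <= cfg$max_words, ]
  p4 <- p4[!(p4$n_words == 1L & p4$phrase %in% cfg$generic_word_list), ]
  if (cfg$apply_tfidf) {
    if (is.null(p4$tfidf_norm)) stop("pool missing tfidf_norm for the TF-IDF floor")
    p4 <- p4[p4$tfidf_norm >= cfg$min_tfidf, ]
  }
  if (cfg$apply_specificity) {
    if (is.null(p4$specificity)) stop("pool missing specificity for the specificity floor")
    p4 <- p4[p4$specificity >= cfg$min_specificity, ]
  }
  p4 <- p4[!(p4$phrase %in% cfg$blocklist), ]
  if (isTRUE(cfg$absorb_nested))
    p4 <- absorb_nested_phrases(p4, cfg$pool_min_freq)
  if (!is.null(quality_ratings)) {
    fr <- quality_ratings[p4$phrase]
    fr[is.na(fr)] <- 0
    p4 <- p4[fr >= cfg$consensus_threshold, ]
  }
  p4 <- merge_near_duplicates(p4, encoder, cfg$merge_similarity)
  p4 <- p4[order(p4$phrase), ]

  structure(list(
    counts = c(pool = nrow(df), phase1 = nrow(p1), phase2 = nrow(p2),
               phase3 = nrow(p3), phase4 = nrow(p4)),
    retained = list(phase1 = p1$phrase, phase2 = p2$phrase,
                    phase3 = p3$phrase, phase4 = p4$phrase),
    pool4 = p4, config = cfg), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-7s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Threshold sensitivity analysis
#'
#' Re-runs Phases 3-4 at each candidate relevance threshold and reports the
#' number of retained phrases and the overlap fraction with a reference set
#' (`|retained intersect reference| / |reference|`). At the configured
#' default threshold this reproduces the main funnel exactly.
#'
#' @param pool scored `phrase_pool`.
#' @param thresholds relevance thresholds to scan (default 0.55-0.75).
#' @param reference_set non-empty character vector of reference phrases.
#' @param cfg a [screening_config()].
#' @param encoder optional encoder for merging (as in [screen()]).
#' @param quality_ratings optional, as in [screen()].
#' @return `sensitivity_table`: data.frame with columns `threshold`,
#'   `n_retained`, `overlap`.
#' @export
sensitivity_analysis <- function(pool,
                                 thresholds = c(0.55, 0.60, 0.65, 0.70, 0.75),
                                 reference_set, cfg = screening_config(),
                                 encoder = NULL, quality_ratings = NULL) {
  if (!length(reference_set)) stop("reference_set must be non-empty")
  rows <- lapply(thresholds, function(t) {
    cfg_t <- cfg
    cfg_t$min_relevance <- t
    rep_t <- screen(pool, cfg_t, encoder = encoder,
                    quality_ratings = quality_ratings)
    kept <- rep_t$retained$phase4
    data.frame(threshold = t, n_retained = length(kept),
               overlap = length(intersect(kept, reference_set)) /
                 length(reference_set))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Write a funnel report as CSV + JSON + plain-text phrase lists
#'
#' @param report a `funnel_report`.
#' @param dir output directory (created if needed).
#' @export
write_funnel_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(phase = names(report$counts),
                              count = as.integer(report$counts)),
                   file.path(dir, "funnel_counts.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.list(report$counts), retained = report$retained),
    file.path(dir, "funnel_report.json"), auto_unbox = TRUE, pretty = TRUE)
  for (ph in names(report$retained))
    writeLines(report$retained[[ph]],
               file.path(dir, paste0("retained_", ph, ".txt")))
  invisible(dir)
}
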