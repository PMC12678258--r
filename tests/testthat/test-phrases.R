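test_that("n-gram extraction enumerates and counts exactly", {
  # one 3-token document, max_n = 2: 3 unigrams + 2 bigrams
  seqs <- list(resilmine:::token_seq_from_tokens("d1", c("a", "b", "c")))
  pool <- extract_ngrams(seqs, max_n = 2)
  expect_equal(nrow(pool), 5)
  expect_setequal(pool$phrase, c("a", "b", "c", "a b", "b c"))
  expect_true(all(pool$total_freq == 1L))
  expect_true(all(pool$doc_freq <= pool$total_freq))

  # planted generator counts are recovered exactly
  gen <- planted_fixture()
  seqs <- preprocess_corpus(gen$corpus)
  pool <- extract_ngrams(seqs, max_n = 3)
  for (k in seq_len(nrow(gen$truth$phrases))) {
    ph <- gen$truth$phrases[k, ]
    row <- pool[pool$phrase == ph$phrase, ]
    expect_equal(row$total_freq, ph$total_freq, info = ph$phrase)
    expect_equal(row$doc_freq, ph$doc_freq, info = ph$phrase)
  }

  # brute-force substring recount equals reported counts on a sample
  set.seed(2)
  for (p in sample(pool$phrase, 12)) {
    cnt <- brute_count_ngram(seqs, p)
    expect_equal(unname(cnt["total"]), pool$total_freq[pool$phrase == p])
    expect_equal(unname(cnt["docs"]), pool$doc_freq[pool$phrase == p])
  }
})

test_that("normalized TF-IDF: ubiquitous phrases get 0, the argmax gets 1", {
  pool <- data.frame(phrase = c("p1", "p2", "p3"), n_words = 1L,
                     total_freq = c(10L, 5L, 8L), doc_freq = c(10L, 2L, 5L))
  out <- tfidf_norm(pool, n_docs = 10)
  raw <- out$total_freq * log(10 / out$doc_freq)
  expect_equal(out$tfidf_norm, raw / max(raw))
  expect_equal(out$tfidf_norm[1], 0)        # ln(N/N) = 0
  expect_equal(out$tfidf_norm[2], 1)        # argmax: 5 ln 5 > 8 ln 2
  expect_equal(out$tfidf_norm[3], 8 * log(2) / (5 * log(5)))
})

test_that("relevance is the affinely rescaled cosine to the domain centroid", {
  enc <- hash_encoder(d = 16, seed = 3)
  emb <- resilmine:::phrase_embedding(enc, "alpha beta")
  expect_equal(relevance_score("alpha beta", enc, emb), 1)
  expect_equal(relevance_score("alpha beta", enc, -emb), 0)
  centroid <- emb + rnorm(16)
  expect_equal(relevance_score("alpha beta", enc, centroid),
               (cosine_similarity(emb, centroid) + 1) / 2)
})

test_that("specificity index is normalized mean token IDF, clipped to [0,1]", {
  mk <- function(id, toks) resilmine:::token_seq_from_tokens(id, toks)
  seqs <- list(mk("1", c("common", "rare", "mid")),
               mk("2", c("common", "mid")),
               mk("3", c("common")),
               mk("4", c("common")),
               mk("5", c("common")))
  pool <- data.frame(phrase = c("common common", "rare", "mid rare", "unseen"),
                     n_words = c(2L, 1L, 2L, 1L),
                     total_freq = 1L, doc_freq = 1L)
  out <- specificity_index(pool, seqs)
  idf <- c(common = log(5 / 5), mid = log(5 / 2), rare = log(5 / 1))
  denom <- unname(stats::quantile(idf, 0.95, type = 7))
  expect_equal(out$specificity[1], 0)
  expect_equal(out$specificity[2], min(idf[["rare"]] / denom, 1))
  expect_equal(out$specificity[3],
               min(mean(c(idf[["mid"]], idf[["rare"]])) / denom, 1))
  expect_equal(out$specificity[4], min(log(5) / denom, 1))  # unseen -> max IDF
  expect_true(all(out$specificity >= 0 & out$specificity <= 1))
})

test_that("upper-quartile threshold uses the linear-interpolation quantile", {
  mkpool <- function(f) data.frame(phrase = paste0("p", seq_along(f)),
                                   n_words = 1L, total_freq = f, doc_freq = 1L)
  expect_equal(quartile_pool_threshold(mkpool(c(1, 2, 3, 100))), 27.25)
  expect_equal(quartile_pool_threshold(mkpool(rep(6, 9))), 6)
  expect_equal(quartile_pool_threshold(mkpool(5)), 5)
  empty <- data.frame(phrase = character(0), n_words = integer(0),
                      total_freq = numeric(0), doc_freq = numeric(0))
  expect_error(quartile_pool_threshold(empty), "empty")
})

test_that("the four-phase funnel matches a brute-force filter oracle", {
  pool <- scored_pool()
  cfg <- screening_config(pool_min_freq = 5L, min_total_freq = 7L,
                          min_doc_freq = 10L, min_relevance = 0.65,
                          generic_word_list = c("epsilon", "lambda"))
  rep <- screen(pool, cfg)

  # independent recomputation, straight from the rules
  p1 <- pool[pool$total_freq >= 5, ]
  p2 <- p1[p1$total_freq >= 7 & p1$doc_freq >= 10, ]
  p3 <- p2[p2$relevance >= 0.65, ]
  p4 <- p3[p3$n_words <= 6 &
           !(p3$n_words == 1 & p3$phrase %in% c("epsilon", "lambda")) &
           p3$tfidf_norm >= 0.45 & p3$specificity >= 0.50, ]
  expect_equal(unname(rep$counts),
               c(nrow(pool), nrow(p1), nrow(p2), nrow(p3), nrow(p4)))
  expect_setequal(rep$retained$phase4, p4$phrase)

  # a 7-word phrase meeting all score thresholds is removed at Phase 4
  expect_true("mu nu xi omicron pi rho sigma" %in% rep$retained$phase3)
  expect_false("mu nu xi omicron pi rho sigma" %in% rep$retained$phase4)

  # funnel monotonicity and subset chain
  expect_true(all(diff(unname(rep$counts)) <= 0))
  expect_true(all(rep$retained$phase2 %in% rep$retained$phase1))
  expect_true(all(rep$retained$phase3 %in% rep$retained$phase2))
  expect_true(all(rep$retained$phase4 %in% rep$retained$phase3))
})

test_that("screening is invariant to pool row order", {
  pool <- scored_pool()
  cfg <- screening_config(generic_word_list = c("epsilon", "lambda"))
  enc <- hash_encoder(d = 16, seed = 5)
  rep1 <- screen(pool, cfg, encoder = enc)
  set.seed(9)
  for (i in 1:5) {
    shuffled <- pool[sample(nrow(pool)), ]
    rep2 <- screen(shuffled, cfg, encoder = enc)
    expect_identical(rep2$counts, rep1$counts)
    expect_identical(rep2$retained, rep1$retained)
  }
})

test_that("an engineered pool passes exactly 12 phrases through Phase 2", {
  passing <- data.frame(phrase = paste0("pass", 1:12, " x"), n_words = 2L,
                        total_freq = 10L, doc_freq = 11L,
                        tfidf_norm = 0.5, relevance = 0.7, specificity = 0.6)
  failing <- data.frame(phrase = paste0("fail", 1:8), n_words = 1L,
                        total_freq = c(rep(6L, 4), rep(9L, 4)),
                        doc_freq = c(rep(6L, 4), rep(4L, 4)),
                        tfidf_norm = 0.5, relevance = 0.7, specificity = 0.6)
  rep <- screen(rbind(passing, failing), screening_config())
  expect_equal(unname(rep$counts["phase2"]), 12L)

  # empty pool: all phase counts 0
  rep0 <- screen(scored_pool()[0, ], screening_config())
  expect_true(all(rep0$counts == 0))
})

test_that("near-duplicate merging keeps the higher-relevance member", {
  enc <- hash_encoder(d = 16, seed = 7)
  pool <- data.frame(
    phrase = c("alpha beta", "beta alpha", "gamma delta"),
    n_words = 2L, total_freq = 20L, doc_freq = 12L,
    tfidf_norm = 0.8, relevance = c(0.9, 0.8, 0.85), specificity = 0.7,
    stringsAsFactors = FALSE)
  # same token bag embeds identically -> cosine 1 -> merged, keeping the
  # higher-relevance member
  m <- resilmine:::merge_near_duplicates(pool, enc, 0.9)
  expect_equal(nrow(m), 2)
  expect_true("alpha beta" %in% m$phrase)
  expect_false("beta alpha" %in% m$phrase)
  expect_true("gamma delta" %in% m$phrase)
})

test_that("nested phrases are absorbed into the longer expression", {
  df <- data.frame(
    phrase = c("triage", "surge", "triage surge", "w0051"),
    n_words = c(1L, 1L, 2L, 1L),
    total_freq = c(24L, 25L, 24L, 60L),
    doc_freq = c(12L, 12L, 12L, 40L),
    stringsAsFactors = FALSE)
  out <- resilmine:::absorb_nested_phrases(df, min_residual = 5L)
  expect_setequal(out$phrase, c("triage surge", "w0051"))
})

test_that("sensitivity analysis scans thresholds and reproduces the funnel", {
  pool <- scored_pool()
  cfg <- screening_config(generic_word_list = c("epsilon", "lambda"))
  main <- screen(pool, cfg)
  ref <- main$retained$phase4
  tab <- sensitivity_analysis(pool, thresholds = c(0.55, 0.60, 0.65, 0.70, 0.75),
                              reference_set = ref, cfg = cfg)
  expect_s3_class(tab, "sensitivity_table")
  expect_equal(nrow(tab), 5)
  # at the configured default threshold the main funnel is reproduced
  expect_equal(tab$n_retained[tab$threshold == 0.65], length(ref))
  expect_equal(tab$overlap[tab$threshold == 0.65], 1.0)
  # monotonicity: raising the threshold never grows the retained count
  expect_true(all(diff(tab$n_retained) <= 0))
  # brute-force recomputation at 0.70
  cfg70 <- cfg; cfg70$min_relevance <- 0.70
  rep70 <- screen(pool, cfg70)
  expect_equal(tab$n_retained[tab$threshold == 0.70],
               length(rep70$retained$phase4))
  expect_equal(tab$overlap[tab$threshold == 0.70],
               length(intersect(rep70$retained$phase4, ref)) / length(ref))
  expect_error(sensitivity_analysis(pool, reference_set = character(0),
                                    cfg = cfg), "non-empty")
})

test_that("funnel reports round-trip to disk", {
  dir <- withr::local_tempdir()
  rep <- screen(scored_pool(), screening_config(generic_word_list = "epsilon"))
  write_funnel_report(rep, dir)
  counts <- utils::read.csv(file.path(dir, "funnel_counts.csv"))
  expect_equal(counts$count, unname(as.integer(rep$counts)))
  js <- jsonlite::read_json(file.path(dir, "funnel_report.json"),
                            simplifyVector = TRUE)
  expect_equal(unlist(js$counts), rep$counts)
  expect_equal(readLines(file.path(dir, "retained_phase4.txt")),
               rep$retained$phase4)
})
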