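test_that("cosine similarity matches its definition and rejects zero vectors", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  set.seed(4)
  for (i in 1:20) {
    u <- rnorm(5); v <- rnorm(5); s <- runif(1, 0.1, 10)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
    expect_equal(cosine_similarity(u, v), cosine_similarity(s * u, v),
                 tolerance = 1e-12)
    expect_lte(abs(cosine_similarity(u, v)), 1 + 1e-12)
  }
})

test_that("InfoNCE loss: closed-form cases and brute-force softmax oracle", {
  # all similarities equal, 15 negatives -> uniform softmax over 16 terms
  anchor <- c(1, 0)
  expect_equal(info_nce_loss(anchor, c(0, 1), rep(list(c(0, 1)), 15), tau = 1),
               log(16), tolerance = 1e-12)
  # sim(a,p)=1, one negative with sim=0, tau=1 -> -log(e/(e+1))
  expect_equal(info_nce_loss(c(1, 0), c(2, 0), list(c(0, 3)), tau = 1),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  # positive sim -> 1, negatives -> -1 at tau = 0.07: loss -> 0
  expect_lt(info_nce_loss(c(1, 0), c(1, 0) * 2, rep(list(c(-1, 0)), 5),
                          tau = 0.07), 1e-6)

  # brute-force oracle on random small inputs
  set.seed(7)
  for (rep_i in 1:25) {
    d <- sample(2:6, 1); nneg <- sample(1:7, 1); tau <- runif(1, 0.05, 2)
    a <- rnorm(d); p <- rnorm(d)
    negs <- lapply(seq_len(nneg), function(i) rnorm(d))
    sims <- c(cosine_similarity(a, p),
              vapply(negs, function(v) cosine_similarity(a, v), numeric(1)))
    oracle <- -log(exp(sims[1] / tau) / sum(exp(sims / tau)))
    expect_equal(info_nce_loss(a, p, negs, tau), oracle, tolerance = 1e-10)
    expect_gte(info_nce_loss(a, p, negs, tau), 0)
    # permuting the negatives leaves the loss unchanged
    expect_equal(info_nce_loss(a, p, rev(negs), tau),
                 info_nce_loss(a, p, negs, tau), tolerance = 1e-12)
  }
  expect_error(info_nce_loss(c(1, 0), c(0, 1), list(c(1, 1)), tau = 0), "tau")
  expect_error(info_nce_loss(c(1, 0), c(0, 1), list(), tau = 1), "negative")
})

test_that("augmentation: identity config, exact mask count, determinism", {
  ts <- preprocess(document("d", body = paste(
    paste0("tok", 1:50, collapse = " "), ".",
    paste0("tok", 51:100, collapse = " "), ".")), stopwords = character(0))
  expect_length(ts$tokens, 100)

  id_spec <- augmentation_spec(mask_rate = 0, do_sentence_reorder = FALSE,
                               synonym_lexicon = NULL, seed = 1)
  expect_identical(augment(ts, id_spec)$tokens, ts$tokens)

  m_spec <- augmentation_spec(mask_rate = 0.15, do_sentence_reorder = FALSE,
                              synonym_lexicon = NULL, seed = 2)
  out <- augment(ts, m_spec)
  expect_length(out$tokens, 100)                       # count preserved
  expect_equal(sum(out$tokens == "[mask]"), 15)        # round(0.15 * 100)

  expect_identical(augment(ts, m_spec), augment(ts, m_spec))
  expect_false(identical(augment(ts, m_spec, seed = 3)$tokens,
                         augment(ts, m_spec, seed = 4)$tokens))

  r_spec <- augmentation_spec(mask_rate = 0, do_sentence_reorder = TRUE,
                              synonym_lexicon = NULL, seed = 5)
  reord <- augment(ts, r_spec)
  expect_length(reord$tokens, 100)
  expect_setequal(reord$tokens, ts$tokens)

  empty_ts <- preprocess(document("d", body = "the"), stopwords = "the")
  expect_error(augment(empty_ts, m_spec), "empty")
})

test_that("synonym replacement consults the lexicon at the configured rate", {
  ts <- token_seq <- resilmine:::token_seq_from_tokens("d", rep("clinic", 400))
  spec <- augmentation_spec(mask_rate = 0, do_sentence_reorder = FALSE,
                            synonym_lexicon = c(clinic = "ward"),
                            synonym_rate = 0.1, seed = 8)
  out <- augment(ts, spec)
  n_rep <- sum(out$tokens == "ward")
  expect_gt(n_rep, 15)   # ~40 expected, binomial(400, 0.1)
  expect_lt(n_rep, 80)
  expect_equal(sum(out$tokens %in% c("clinic", "ward")), 400)
})

test_that("lr schedule hits the warmup peak and decays to zero", {
  # 10% warmup of 100 steps: peak at step 10, zero at step 100
  expect_equal(lr_schedule(10, 100, peak = 2e-5), 2e-5)
  expect_equal(lr_schedule(100, 100, peak = 2e-5), 0)
  expect_equal(lr_schedule(5, 100, peak = 2e-5), 1e-5)
  expect_equal(lr_schedule(55, 100, peak = 2e-5), 2e-5 * 45 / 90)
  sched <- lr_schedule(1:100, 100, peak = 1)
  expect_equal(which.max(sched), 10)
  expect_true(all(diff(sched[10:100]) <= 0))
})

test_that("validation metrics agree with exhaustive rank enumeration", {
  gen <- planted_fixture()
  seqs <- preprocess_corpus(gen$corpus)[1:8]
  aug <- augmentation_spec(mask_rate = 0, do_sentence_reorder = FALSE,
                           synonym_lexicon = NULL, seed = 1)

  # identity augmentation + injective encoder -> perfect ranking
  enc <- hash_encoder(d = 32, seed = 2)
  vm <- validate_encoder(enc, seqs, aug)
  expect_equal(vm$contrastive_accuracy, 1.0)
  expect_equal(vm$mrr, 1.0)

  # constant encoder: worst-case tie rule -> every rank = n
  vocab <- unique(unlist(lapply(seqs, `[[`, "tokens")))
  enc_const <- embedding_encoder(vocab, d = 4, seed = 1)
  enc_const$E[] <- rep(c(1, 0, 0, 0), each = nrow(enc_const$E))
  vm2 <- validate_encoder(enc_const, seqs, aug)
  n <- length(seqs)
  expect_equal(vm2$mrr, 1 / n)
  expect_equal(vm2$contrastive_accuracy, 0)

  # brute-force oracle on a generic encoder with masking noise
  aug2 <- augmentation_spec(mask_rate = 0.2, do_sentence_reorder = FALSE,
                            synonym_lexicon = NULL, seed = 3)
  vm3 <- validate_encoder(enc, seqs, aug2)
  A <- t(vapply(seqs, function(s) encode(enc, s), numeric(enc$d)))
  P <- t(vapply(seq_along(seqs), function(i)
    encode(enc, augment(seqs[[i]], aug2,
                        seed = resilmine:::derive_seed(aug2$seed, 5000L + i))),
    numeric(enc$d)))
  ranks <- vapply(seq_len(n), function(i) {
    sims <- vapply(seq_len(n), function(j) cosine_similarity(A[i, ], P[j, ]),
                   numeric(1))
    1L + sum(sims[-i] >= sims[i])
  }, integer(1))
  expect_equal(vm3$mrr, mean(1 / ranks))
  expect_equal(vm3$contrastive_accuracy, mean(ranks == 1))

  # coherence: sentinel without pairs, mean cosine with pairs
  expect_true(is.na(vm$coherence))
  pairs <- rbind(c(1, 2), c(3, 4))
  vm4 <- validate_encoder(enc, seqs, aug, same_topic_pairs = pairs)
  expect_equal(vm4$coherence,
               mean(c(cosine_similarity(A[1, ], A[2, ]),
                      cosine_similarity(A[3, ], A[4, ]))))
  expect_error(validate_encoder(enc, seqs[1], aug), "at least 2")
})

test_that("training reduces the contrastive loss on a planted corpus", {
  gen <- planted_fixture(seed = 21L, n_docs = 80L)
  res <- train_contrastive(
    gen$corpus,
    cfg = training_config(batch_size = 16, epochs = 15, lr = 0.2,
                          val_every = 1000, patience = 50, seed = 3),
    aug = augmentation_spec(seed = 4))
  expect_gt(nrow(res$log), 30)
  expect_lt(mean(tail(res$log$loss, 5)), mean(head(res$log$loss, 5)))
})

test_that("early stopping halts after exactly `patience` stale validation checks", {
  gen <- planted_fixture(seed = 22L, n_docs = 40L)
  # identity augmentation keeps MRR constant at 1 -> the first check sets
  # the best; each later check is stale; halt at check 1 + patience
  res <- train_contrastive(
    gen$corpus,
    cfg = training_config(batch_size = 16, epochs = 50, lr = 1e-4,
                          val_every = 1, patience = 5, seed = 5),
    aug = augmentation_spec(mask_rate = 0, do_sentence_reorder = FALSE,
                            synonym_lexicon = NULL, seed = 6))
  checks <- which(!is.na(res$log$val_mrr))
  expect_equal(length(checks), 6)          # 1 best + 5 stale
  expect_true(all(res$log$val_mrr[checks] == 1))
  expect_equal(nrow(res$log), 6)
})

test_that("training is reproducible: same seeds give identical logs", {
  gen <- planted_fixture(seed = 23L, n_docs = 40L)
  cfg <- training_config(batch_size = 8, epochs = 2, lr = 0.1,
                         val_every = 2, seed = 11)
  aug <- augmentation_spec(seed = 12)
  r1 <- train_contrastive(gen$corpus, cfg = cfg, aug = aug)
  r2 <- train_contrastive(gen$corpus, cfg = cfg, aug = aug)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$encoder$E, r2$encoder$E)
})
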