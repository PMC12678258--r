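# Contrastive representation learning: seeded augmentation (masking,
# sentence reordering, synonym replacement), the InfoNCE objective with
# in-batch negatives, a linear warmup/decay training loop with gradient
# accumulation, clipping and MRR-based early stopping, and the three
# validation metrics (contrastive accuracy, MRR, embedding coherence).

#' Augmentation specification
#'
#' @param mask_rate fraction of tokens replaced by the reserved `[mask]`
#'   token; exactly `round(mask_rate * n_tokens)` positions are masked,
#'   sampled without replacement.
#' @param do_sentence_reorder permute sentence order before masking.
#' @param synonym_lexicon named character vector `word -> synonym`; each
#'   eligible token is replaced with probability `synonym_rate`.
#' @param synonym_rate per-token replacement probability.
#' @param seed integer seed.
#' @return object of class `"augmentation_spec"`.
#' @export
augmentation_spec <- function(mask_rate = 0.15, do_sentence_reorder = TRUE,
                              synonym_lexicon = default_synonyms(),
                              synonym_rate = 0.1, seed = 1L) {
  if (mask_rate < 0 || mask_rate >= 1) stop("mask_rate must be in [0, 1)")
  structure(list(mask_rate = mask_rate,
                 do_sentence_reorder = isTRUE(do_sentence_reorder),
                 synonym_lexicon = synonym_lexicon,
                 synonym_rate = synonym_rate, seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Packaged synonym lexicon
#'
#' A small static English synonym map shipped with the package (CSV under
#' `extdata`), used by the synonym-replacement augmentation.
#'
#' @return named character vector `word -> synonym`.
#' @export
default_synonyms <- function() {
  path <- system.file("extdata", "synonyms_en.csv", package = "resilmine")
  if (!nzchar(path)) return(stats::setNames(character(0), character(0)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$synonym, df$word)
}

#' Generate a positive sample by augmentation
#'
#' Applies, in order: sentence reordering (if enabled and more than one
#' sentence), synonym replacement, and random masking. Token count is
#' preserved; exactly `round(mask_rate * n)` positions carry the `[mask]`
#' token. Deterministic given `spec$seed`.
#'
#' @param ts a `token_seq`.
#' @param spec an [augmentation_spec()].
#' @param seed override seed (defaults to `spec$seed`).
#' @return an augmented `token_seq`.
#' @export
augment <- function(ts, spec, seed = spec$seed) {
  stopifnot(inherits(ts, "token_seq"), inherits(spec, "augmentation_spec"))
  if (!length(ts$tokens)) stop("cannot augment an empty token sequence")
  with_seed(seed, {
    tokens <- ts$tokens
    sentences <- ts$sentences
    if (spec$do_sentence_reorder && length(sentences) > 1L) {
      ord <- sample(length(sentences))
      tokens <- unlist(lapply(ord, function(k) ts$tokens[sentences[[k]]]),
                       use.names = FALSE)
      lens <- lengths(sentences)[ord]
      ends <- cumsum(lens)
      sentences <- mapply(function(a, b) seq.int(a, b),
                          ends - lens + 1L, ends, SIMPLIFY = FALSE)
    }
    lex <- spec$synonym_lexicon
    if (length(lex) && spec$synonym_rate > 0) {
      eligible <- which(tokens %in% names(lex))
      if (length(eligible)) {
        hit <- eligible[stats::runif(length(eligible)) < spec$synonym_rate]
        tokens[hit] <- unname(lex[tokens[hit]])
      }
    }
    n_mask <- round(spec$mask_rate * length(tokens))
    if (n_mask > 0) {
      pos <- sample.int(length(tokens), n_mask)
      tokens[pos] <- "[mask]"
    }
    token_seq_from_tokens(ts$doc_id, tokens, sentences)
  })
}

#' Cosine similarity
#'
#' `sim(u, v) = (u . v) / (||u|| ||v||)`, in [-1, 1].
#'
#' @param u,v numeric vectors of equal length, both nonzero.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- l2norm(u); nv <- l2norm(v)
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

#' InfoNCE loss for one anchor
#'
#' `-log( exp(sim(a, p)/tau) / (exp(sim(a, p)/tau) + sum_j exp(sim(a, n_j)/tau)) )`
#' where the denominator runs over the positive plus all negatives
#' (in-batch negatives in training). Always non-negative.
#'
#' @param anchor,positive numeric vectors.
#' @param negatives list of numeric vectors (at least one).
#' @param tau temperature, > 0 (default 0.07).
#' @return scalar loss.
#' @export
info_nce_loss <- function(anchor, positive, negatives, tau = 0.07) {
  if (tau <= 0) stop("tau must be > 0")
  if (!length(negatives)) stop("at least one negative is required")
  s_pos <- cosine_similarity(anchor, positive) / tau
  s_neg <- vapply(negatives, function(v) cosine_similarity(anchor, v) / tau,
                  numeric(1))
  m <- max(s_pos, s_neg)
  -(s_pos - m) + log(sum(exp(c(s_pos, s_neg) - m)))
}

#' Training configuration
#'
#' Defaults mirror the standard fine-tuning schedule used throughout the
#' package: temperature 0.07, batch size 16 with 2-step gradient
#' accumulation (effective batch 32), peak learning rate 2e-5 with linear
#' warmup over 10% of steps then linear decay to 0, gradient-norm clipping
#' at 1.0, 3 epochs, a 15% validation split checked every 50 steps, and
#' early stopping after 5 checks without MRR improvement.
#'
#' @param temperature softmax temperature, > 0.
#' @param batch_size documents per step.
#' @param grad_accum steps accumulated per parameter update.
#' @param lr peak learning rate.
#' @param warmup_fraction fraction of total steps spent in linear warmup.
#' @param max_grad_norm global gradient-norm clip.
#' @param epochs passes over the training split.
#' @param val_fraction held-out fraction (round-half-up of
#'   `val_fraction * N` documents).
#' @param val_every validate every this many steps.
#' @param patience validation checks without MRR improvement before
#'   stopping.
#' @param seed integer seed for the split, shuffles and augmentations.
#' @return object of class `"training_config"`.
#' @export
training_config <- function(temperature = 0.07, batch_size = 16L,
                            grad_accum = 2L, lr = 2e-5,
                            warmup_fraction = 0.10, max_grad_norm = 1.0,
                            epochs = 3L, val_fraction = 0.15,
                            val_every = 50L, patience = 5L, seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (patience < 1) stop("patience must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  structure(list(temperature = temperature, batch_size = as.integer(batch_size),
                 grad_accum = as.integer(grad_accum), lr = lr,
                 warmup_fraction = warmup_fraction,
                 max_grad_norm = max_grad_norm, epochs = as.integer(epochs),
                 val_fraction = val_fraction, val_every = as.integer(val_every),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

#' Linear warmup / linear decay learning-rate schedule
#'
#' Ramps linearly from 0 to `peak` over the first
#' `warmup_fraction * total_steps` steps (reaching `peak` exactly at the end
#' of warmup), then decays linearly to 0 at `total_steps`.
#'
#' @param step step number (1-based).
#' @param total_steps total training steps.
#' @param peak peak learning rate.
#' @param warmup_fraction fraction of steps in warmup.
#' @return learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, peak, warmup_fraction = 0.10) {
  warmup <- round(warmup_fraction * total_steps)
  ifelse(step <= warmup,
         peak * step / max(warmup, 1L),
         peak * (total_steps - step) / max(total_steps - warmup, 1L))
}

round_half_up <- function(x) floor(x + 0.5)

# Batch loss and embedding-matrix gradient for the in-batch InfoNCE task.
# anchors/positives: lists of vocab-index vectors; E: embedding matrix.
# Returns list(loss, grad) where grad has the shape of E.
batch_loss_grad <- function(E, anchor_idx, positive_idx, tau) {
  b <- length(anchor_idx)
  d <- ncol(E)
  A <- t(vapply(anchor_idx, function(ii)
    if (length(ii)) colMeans(E[ii, , drop = FALSE]) else numeric(d),
    numeric(d)))
  P <- t(vapply(positive_idx, function(ii)
    if (length(ii)) colMeans(E[ii, , drop = FALSE]) else numeric(d),
    numeric(d)))
  na <- sqrt(rowSums(A^2)); np <- sqrt(rowSums(P^2))
  ok <- na > 0 & np > 0
  if (!all(ok)) stop("zero embedding encountered in batch")
  Cmat <- (A %*% t(P)) / (na %o% np)        # cosine matrix b x b
  S <- Cmat / tau
  S <- S - apply(S, 1, max)
  Pr <- exp(S) / rowSums(exp(S))
  loss <- -mean(log(Pr[cbind(seq_len(b), seq_len(b))]))
  G <- (Pr - diag(b)) / (tau * b)           # dLoss/dCmat
  # dcos(a_i, p_j)/da_i = p_j/(na_i np_j) - cos_ij a_i/na_i^2
  dA <- (G / (na %o% np)) %*% P - (rowSums(G * Cmat) / na^2) * A
  dP <- t(G / (na %o% np)) %*% A - (colSums(G * Cmat) / np^2) * P
  grad <- matrix(0, nrow(E), ncol(E))
  for (i in seq_len(b)) {
    ii <- anchor_idx[[i]]
    tab <- tabulate(ii, nbins = nrow(E))
    nz <- which(tab > 0)
    grad[nz, ] <- grad[nz, ] + (tab[nz] / length(ii)) %o% dA[i, ]
    jj <- positive_idx[[i]]
    tab <- tabulate(jj, nbins = nrow(E))
    nz <- which(tab > 0)
    grad[nz, ] <- grad[nz, ] + (tab[nz] / length(jj)) %o% dP[i, ]
  }
  list(loss = loss, grad = grad)
}

#' Train a token-embedding encoder with the in-batch InfoNCE objective
#'
#' Each step draws a batch of documents, augments each into a positive
#' sample, and treats all other in-batch positives as negatives. Parameters
#' follow the warmup/decay schedule with gradient accumulation and global
#' gradient-norm clipping; validation (contrastive accuracy, MRR, coherence)
#' runs every `cfg$val_every` steps on a held-out split, and training stops
#' early after `cfg$patience` checks without MRR improvement. The returned
#' encoder is the best-MRR checkpoint.
#'
#' @param x a [corpus()] or a list of `token_seq`.
#' @param encoder an [embedding_encoder()]; if `NULL`, one is built from the
#'   corpus vocabulary with `d = 32`.
#' @param cfg a [training_config()].
#' @param aug an [augmentation_spec()].
#' @param same_topic_pairs optional 2-column matrix of validation-document
#'   index pairs for the coherence metric.
#' @return list with `encoder` (best checkpoint), `log` (data.frame: step,
#'   lr, loss, val_accuracy, val_mrr, val_coherence), and `val_idx`.
#' @export
train_contrastive <- function(x, encoder = NULL, cfg = training_config(),
                              aug = augmentation_spec(),
                              same_topic_pairs = NULL) {
  seqs <- if (inherits(x, "corpus")) preprocess_corpus(x) else x
  seqs <- Filter(function(s) length(s$tokens) > 0, seqs)
  N <- length(seqs)
  if (N <= cfg$batch_size)
    stop("corpus (", N, " non-empty docs) must be larger than one batch (",
         cfg$batch_size, ")")
  if (is.null(encoder)) {
    vocab <- unique(unlist(lapply(seqs, `[[`, "tokens"), use.names = FALSE))
    encoder <- embedding_encoder(vocab, d = 32L, seed = cfg$seed)
  }
  stopifnot(inherits(encoder, "embedding_encoder"))

  n_val <- max(1L, round_half_up(cfg$val_fraction * N))
  split_order <- with_seed(derive_seed(cfg$seed, 11L), sample.int(N))
  val_idx <- sort(split_order[seq_len(n_val)])
  train_idx <- setdiff(seq_len(N), val_idx)
  if (length(train_idx) < cfg$batch_size)
    stop("training split smaller than one batch")
  val_seqs <- seqs[val_idx]

  E <- encoder$E
  steps_per_epoch <- length(train_idx) %/% cfg$batch_size
  total_steps <- cfg$epochs * steps_per_epoch
  log <- data.frame(step = integer(0), lr = numeric(0), loss = numeric(0),
                    val_accuracy = numeric(0), val_mrr = numeric(0),
                    val_coherence = numeric(0))
  best_mrr <- -Inf; best_E <- E; stale <- 0L; step <- 0L
  accum <- matrix(0, nrow(E), ncol(E)); n_accum <- 0L
  stopped <- FALSE

  for (epoch in seq_len(cfg$epochs)) {
    if (stopped) break
    order_e <- with_seed(derive_seed(cfg$seed, 100L + epoch),
                         sample(train_idx))
    for (bi in seq_len(steps_per_epoch)) {
      step <- step + 1L
      batch <- order_e[((bi - 1L) * cfg$batch_size + 1L):(bi * cfg$batch_size)]
      enc_now <- encoder; enc_now$E <- E
      anchor_idx <- lapply(seqs[batch], function(s)
        vocab_indices(encoder, s$tokens))
      positive_idx <- lapply(seq_along(batch), function(k) {
        s <- seqs[[batch[k]]]
        a <- augment(s, aug, seed = derive_seed(aug$seed, 1000L + step * 64L + k))
        vocab_indices(encoder, a$tokens)
      })
      bg <- batch_loss_grad(E, anchor_idx, positive_idx, cfg$temperature)
      accum <- accum + bg$grad; n_accum <- n_accum + 1L
      lr_t <- lr_schedule(step, total_steps, cfg$lr, cfg$warmup_fraction)
      if (n_accum == cfg$grad_accum || step == total_steps) {
        g <- accum / n_accum
        gn <- sqrt(sum(g^2))
        if (gn > cfg$max_grad_norm) g <- g * (cfg$max_grad_norm / gn)
        E <- E - lr_t * g
        accum[] <- 0; n_accum <- 0L
      }
      row <- data.frame(step = step, lr = lr_t, loss = bg$loss,
                        val_accuracy = NA_real_, val_mrr = NA_real_,
                        val_coherence = NA_real_)
      if (step %% cfg$val_every == 0L || step == total_steps) {
        enc_now$E <- E
        vm <- validate_encoder(enc_now, val_seqs, aug,
                               same_topic_pairs = same_topic_pairs)
        row$val_accuracy <- vm$contrastive_accuracy
        row$val_mrr <- vm$mrr
        row$val_coherence <- vm$coherence
        if (vm$mrr > best_mrr) {
          best_mrr <- vm$mrr; best_E <- E; stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= cfg$patience) stopped <- TRUE
        }
      }
      log <- rbind(log, row)
      if (stopped) break
    }
  }
  if (is.infinite(best_mrr)) best_E <- E
  encoder$E <- best_E
  list(encoder = encoder, log = log, val_idx = val_idx)
}

#' Validation metrics for an encoder
#'
#' Ranks, for each validation document, its own augmented positive against
#' the positives of all other validation documents (the in-batch ranking
#' task). Ties are broken pessimistically: any candidate with similarity
#' greater than or equal to the positive's counts as ranked above it.
#' Coherence is the mean cosine similarity over the supplied same-topic
#' pairs, or `NA` when no pairs are given.
#'
#' @param encoder an encoder.
#' @param val_docs a [corpus()] or list of `token_seq` (at least 2).
#' @param aug an [augmentation_spec()]; the augmentation seed is fixed per
#'   document so repeated validation is comparable.
#' @param same_topic_pairs optional 2-column matrix of document index pairs.
#' @return list with `contrastive_accuracy`, `mrr`, `coherence`.
#' @export
validate_encoder <- function(encoder, val_docs, aug = augmentation_spec(),
                             same_topic_pairs = NULL) {
  seqs <- if (inherits(val_docs, "corpus")) preprocess_corpus(val_docs)
          else val_docs
  n <- length(seqs)
  if (n < 2) stop("validation needs at least 2 documents")
  A <- t(vapply(seqs, function(s) encode(encoder, s), numeric(encoder$d)))
  P <- t(vapply(seq_len(n), function(i)
    encode(encoder, augment(seqs[[i]], aug,
                            seed = derive_seed(aug$seed, 5000L + i))),
    numeric(encoder$d)))
  na <- sqrt(rowSums(A^2)); np <- sqrt(rowSums(P^2))
  na[na == 0] <- 1; np[np == 0] <- 1
  S <- (A %*% t(P)) / (na %o% np)
  ranks <- vapply(seq_len(n), function(i)
    1L + sum(S[i, -i] >= S[i, i]), integer(1))
  coh <- NA_real_
  if (!is.null(same_topic_pairs) && nrow(same_topic_pairs) > 0) {
    coh <- mean(vapply(seq_len(nrow(same_topic_pairs)), function(k) {
      i <- same_topic_pairs[k, 1]; j <- same_topic_pairs[k, 2]
      cosine_similarity(A[i, ], A[j, ])
    }, numeric(1)))
  }
  list(contrastive_accuracy = mean(ranks == 1L),
       mrr = mean(1 / ranks),
       coherence = coh)
}
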