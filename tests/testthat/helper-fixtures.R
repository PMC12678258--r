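# Shared fixtures, built in code at test time.

# A tiny deterministic corpus of hand-written documents.
tiny_corpus <- function() {
  corpus(list(
    document("d1", title = "Clinic capacity",
             body = "The clinic expanded triage capacity. Triage capacity grew."),
    document("d2", title = "Ward report",
             body = "The ward report notes clinic staffing. Staffing held steady."),
    document("d3", title = "Greenway",
             body = "Greenway access improved. Residents used the greenway daily.")))
}

# A synthetic corpus with planted phrases meeting the screening thresholds.
planted_fixture <- function(seed = 11L, n_docs = 40L) {
  phrases <- data.frame(
    phrase = c("telemedicine uplink", "mutual aid", "greenway access",
               "contact tracing", "surge staffing", "modular shelter",
               "sparse one", "sparse two"),
    total_freq = c(12L, 11L, 10L, 9L, 8L, 8L, 3L, 2L),
    doc_freq   = c(11L, 10L, 10L, 9L, 8L, 8L, 3L, 2L),
    topic      = c("med", "soc", "eco", "med", "med", "spa", "noise", "noise"),
    stringsAsFactors = FALSE)
  spec <- synthetic_spec(n_docs, vocab_size = 80, planted_phrases = phrases,
                         topic_hierarchy = data.frame(parent = "med",
                                                      child = c("soc", "eco", "spa")),
                         doc_length = 15, seed = seed)
  generate_corpus(spec)
}

# A scored phrase pool with every column populated by hand; screening on it
# can be recomputed by brute force in tests.
scored_pool <- function() {
  df <- data.frame(
    phrase = c("alpha beta", "gamma delta", "epsilon", "zeta eta theta",
               "iota kappa", "lambda", "mu nu xi omicron pi rho sigma",
               "tau upsilon", "phi chi", "psi omega"),
    n_words = c(2L, 2L, 1L, 3L, 2L, 1L, 7L, 2L, 2L, 2L),
    total_freq = c(20L, 15L, 12L, 11L, 9L, 8L, 30L, 7L, 6L, 4L),
    doc_freq = c(14L, 12L, 12L, 10L, 6L, 8L, 20L, 7L, 5L, 4L),
    tfidf_norm = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.55, 1.0, 0.5, 0.4, 0.3),
    relevance = c(0.9, 0.8, 0.7, 0.66, 0.9, 0.64, 0.9, 0.7, 0.8, 0.9),
    specificity = c(0.8, 0.7, 0.6, 0.55, 0.9, 0.5, 0.9, 0.45, 0.7, 0.8),
    stringsAsFactors = FALSE)
  class(df) <- c("phrase_pool", "data.frame")
  df
}

# A regular tree with unit edge lengths: path-distance matrix and edges.
tree_fixture <- function(levels = 3L, branch = 3L, scale = 1) {
  parent <- NULL; nodes <- 1L; cur <- 1L
  for (l in seq_len(levels)) {
    nxt <- integer(0)
    for (p in cur) for (b in seq_len(branch)) {
      nodes <- nodes + 1L
      parent <- rbind(parent, c(p, nodes))
      nxt <- c(nxt, nodes)
    }
    cur <- nxt
  }
  n <- nodes
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(parent))) {
    adj[parent[k, 1], parent[k, 2]] <- TRUE
    adj[parent[k, 2], parent[k, 1]] <- TRUE
  }
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ])) if (D[s, w] > D[s, v] + 1) {
        D[s, w] <- D[s, v] + 1; q <- c(q, w)
      }
    }
  }
  list(D = D * scale, H = hierarchy_edges(parent[, 1], parent[, 2]), n = n)
}

# Brute-force n-gram recount by scanning sentence token runs directly.
brute_count_ngram <- function(seqs, phrase) {
  ptoks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  total <- 0L; docs <- 0L
  for (s in seqs) {
    hits <- 0L
    for (span in s$sentences) {
      toks <- s$tokens[span]
      L <- length(toks); n <- length(ptoks)
      if (L < n) next
      for (st in seq_len(L - n + 1L))
        if (all(toks[st:(st + n - 1L)] == ptoks)) hits <- hits + 1L
    }
    total <- total + hits
    if (hits > 0L) docs <- docs + 1L
  }
  c(total = total, docs = docs)
}

# random points in the open ball with norm <= max_norm
random_ball_points <- function(n, dim, max_norm = 0.9) {
  dir <- matrix(stats::rnorm(n * dim), n, dim)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * (max_norm * stats::runif(n)^(1 / dim))
}
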