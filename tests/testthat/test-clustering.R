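test_that("tangent projection applies the origin log map point-wise", {
  coords <- rbind(c(0, 0), c(0.5, 0), c(0.2, 0.3))
  emb <- embedding_set(coords, "hyperbolic")
  pts <- tangent_project(emb)
  expect_equal(pts[1, ], c(0, 0))
  expect_equal(pts[2, ], c(4 / 3, 0), tolerance = 1e-12)
  expect_equal(pts[3, ], 2 / (1 - 0.13) * c(0.2, 0.3), tolerance = 1e-12)
  # norm ordering preserved
  r_in <- sqrt(rowSums(coords^2))
  r_out <- sqrt(rowSums(pts^2))
  expect_equal(order(r_in), order(r_out))
  expect_error(tangent_project(embedding_set(coords, "euclidean")),
               "hyperbolic")
})

test_that("k-means recovers planted blobs and is deterministic", {
  set.seed(1)
  blobs <- rbind(matrix(rnorm(40, mean = 0, sd = 0.1), ncol = 2),
                 matrix(rnorm(40, mean = 5, sd = 0.1), ncol = 2))
  truth <- rep(1:2, each = 20)
  res <- kmeans_cluster(blobs, 2, seed = 3)
  expect_equal(length(unique(paste(res$labels, truth))), 2)  # label-permuted match

  # k = n gives zero within-cluster sum of squares
  pts <- matrix(rnorm(12), 6, 2)
  res_n <- kmeans_cluster(pts, 6, seed = 4)
  expect_equal(res_n$wss, 0, tolerance = 1e-12)

  expect_identical(kmeans_cluster(blobs, 3, seed = 5),
                   kmeans_cluster(blobs, 3, seed = 5))
  expect_error(kmeans_cluster(pts, 7, seed = 1), "exceeds")

  # within-cluster sum of squares is no worse than the stats::kmeans fit
  km <- stats::kmeans(blobs, 2, nstart = 10)
  expect_lte(res$wss, km$tot.withinss + 1e-8)
})

test_that("silhouette matches the per-definition loop and cluster::silhouette", {
  brute_sil <- function(points, labels) {
    D <- as.matrix(dist(points)); n <- nrow(points)
    mean(vapply(seq_len(n), function(i) {
      own <- setdiff(which(labels == labels[i]), i)
      if (!length(own)) return(0)
      a <- mean(D[i, own])
      b <- min(vapply(setdiff(unique(labels), labels[i]),
                      function(k) mean(D[i, labels == k]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
  }
  set.seed(6)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    labels <- sample(1:2, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- 3 - labels[1]
    expect_equal(silhouette_score(pts, labels), brute_sil(pts, labels),
                 tolerance = 1e-12)
  }
  # independent implementation cross-check (no singletons)
  skip_if_not_installed("cluster")
  set.seed(7)
  pts <- rbind(matrix(rnorm(20, 0, 0.5), ncol = 2),
               matrix(rnorm(20, 4, 0.5), ncol = 2))
  labels <- rep(1:2, each = 10)
  ref <- mean(cluster::silhouette(labels, dist(pts))[, "sil_width"])
  expect_equal(silhouette_score(pts, labels), ref, tolerance = 1e-10)

  # two tight far-separated clusters -> near 1
  tight <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
                 matrix(rnorm(20, 10, 0.01), ncol = 2))
  expect_gt(silhouette_score(tight, rep(1:2, each = 10)), 0.9)

  # all points identical in 2 forced clusters -> 0 by the a = b = 0 rule
  same <- matrix(1, 4, 2)
  expect_equal(silhouette_score(same, c(1, 1, 2, 2)), 0)
  expect_error(silhouette_score(same, rep(1, 4)), "2 clusters")
})

test_that("Davies-Bouldin matches its formula and is scale-invariant", {
  brute_db <- function(points, labels) {
    ks <- sort(unique(labels)); k <- length(ks)
    cent <- t(sapply(ks, function(kk) colMeans(points[labels == kk, , drop = FALSE])))
    s <- sapply(seq_len(k), function(j) {
      pts <- points[labels == ks[j], , drop = FALSE]
      mean(sqrt(rowSums(sweep(pts, 2, cent[j, ])^2)))
    })
    mean(sapply(seq_len(k), function(i) max(sapply(setdiff(seq_len(k), i),
      function(j) (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))))))
  }
  # two point-mass clusters at distance 1 -> 0
  pm <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0))
  expect_equal(davies_bouldin(pm, c(1, 1, 2, 2)), 0)

  set.seed(8)
  pts <- matrix(rnorm(12), 6, 2)
  labels <- c(1, 1, 2, 2, 3, 3)
  expect_equal(davies_bouldin(pts, labels), brute_db(pts, labels),
               tolerance = 1e-12)
  expect_equal(davies_bouldin(pts * 7.3, labels),
               davies_bouldin(pts, labels), tolerance = 1e-12)

  dup <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  expect_error(davies_bouldin(dup, c(1, 1, 2, 2)), "coincident")
})

test_that("NPMI coherence: co-occurrence limits and hand computation", {
  mk <- function(id, toks) resilmine:::token_seq_from_tokens(id, toks)
  # phrases a and b always co-occur; c never co-occurs with them
  seqs <- c(lapply(1:5, function(i) mk(paste0("ab", i), c("a", "b"))),
            lapply(1:5, function(i) mk(paste0("c", i), c("c", "d"))))
  expect_equal(topic_coherence(c(1, 1), c("a", "b"), seqs), 1,
               tolerance = 1e-12)
  expect_lt(topic_coherence(c(1, 1), c("a", "c"), seqs), 0)

  # hand-computed 2-phrase NPMI with add-one smoothing
  seqs2 <- c(lapply(1:4, function(i) mk(paste0("x", i), c("p", "q"))),
             lapply(1:4, function(i) mk(paste0("y", i), c("p", "r"))),
             lapply(1:2, function(i) mk(paste0("z", i), c("s"))))
  N <- 10
  pab <- (4 + 1) / (N + 1); pa <- (8 + 1) / (N + 1); pb <- (4 + 1) / (N + 1)
  hand <- log(pab / (pa * pb)) / (-log(pab))
  expect_equal(topic_coherence(c(1, 1), c("p", "q"), seqs2), hand,
               tolerance = 1e-12)

  # zero-document-frequency phrases are excluded with a warning
  expect_warning(val <- topic_coherence(c(1, 1, 1), c("p", "q", "zz"), seqs2),
                 "zero document frequency")
  expect_equal(val, hand, tolerance = 1e-12)
})

test_that("model selection recovers 4 planted blobs under all three metrics", {
  set.seed(9)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  pts <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(20, sd = 0.3), 10, 2), 2, centers[k, ], `+`)))
  # phrases grouped so that same-blob phrases always co-occur
  phrases <- paste0("ph", 1:40)
  mk <- function(id, toks) resilmine:::token_seq_from_tokens(id, toks)
  seqs <- unlist(lapply(1:4, function(k)
    lapply(1:6, function(r) mk(paste0("doc", k, "_", r),
                               phrases[((k - 1) * 10 + 1):(k * 10)]))),
    recursive = FALSE)
  sel <- select_k(pts, phrases = phrases, seqs = seqs, k_range = 3:7,
                  seed = 10)
  expect_equal(sel$best_k, 4)
  tab <- sel$table
  expect_equal(nrow(tab), 5)
  expect_equal(tab$k[which.max(tab$silhouette)], 4)
  expect_equal(tab$k[which.min(tab$davies_bouldin)], 4)
  expect_equal(tab$k[which.max(tab$coherence)], 4)
})

test_that("model selection is invariant to point order", {
  set.seed(11)
  pts <- rbind(sweep(matrix(rnorm(30, 0, 0.2), ncol = 2), 2, c(0, 0), `+`),
               sweep(matrix(rnorm(30, 0, 0.2), ncol = 2), 2, c(5, 5), `+`),
               sweep(matrix(rnorm(30, 0, 0.2), ncol = 2), 2, c(0, 5), `+`))
  s1 <- select_k(pts, k_range = 2:4, seed = 12)
  perm <- sample(nrow(pts))
  s2 <- select_k(pts[perm, ], k_range = 2:4, seed = 12)
  expect_equal(s2$best_k, s1$best_k)
  expect_equal(s2$table$silhouette, s1$table$silhouette, tolerance = 1e-8)
  expect_equal(s2$table$davies_bouldin, s1$table$davies_bouldin,
               tolerance = 1e-8)
})

test_that("the k-means objective never increases across Lloyd iterations", {
  set.seed(13)
  pts <- matrix(rnorm(60), 30, 2)
  init <- resilmine:::farthest_point_init(pts, 3, seed = 14)
  centers <- init
  prev <- Inf
  for (it in 1:10) {
    d2 <- sapply(1:3, function(j)
      rowSums(sweep(pts, 2, centers[j, ])^2))
    labels <- max.col(-d2, ties.method = "first")
    wss <- sum(d2[cbind(seq_len(nrow(pts)), labels)])
    expect_lte(wss, prev + 1e-10)
    prev <- wss
    for (j in 1:3) if (any(labels == j))
      centers[j, ] <- colMeans(pts[labels == j, , drop = FALSE])
  }
})
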