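# Tangent-space clustering of ball embeddings with three-metric model
# selection (silhouette, Davies-Bouldin, NPMI topic coherence).

#' Project a hyperbolic embedding to the tangent space at the origin
#'
#' Applies the origin log map point-wise; the result is a Euclidean point
#' set suitable for k-means. Norm ordering of points is preserved.
#'
#' @param emb a hyperbolic [embedding_set()].
#' @return n x dim numeric matrix.
#' @export
tangent_project <- function(emb) {
  stopifnot(inherits(emb, "embedding_set"))
  if (emb$space != "hyperbolic")
    stop("tangent projection expects a hyperbolic embedding")
  t(apply(emb$coords, 1, log_map_origin))
}

farthest_point_init <- function(points, k, seed) {
  n <- nrow(points)
  centers <- integer(k)
  centers[1] <- with_seed(seed, sample.int(n, 1))
  if (k > 1) {
    d2 <- rowSums((points - matrix(points[centers[1], ], n, ncol(points),
                                   byrow = TRUE))^2)
    for (j in 2:k) {
      centers[j] <- which.max(d2)
      d2 <- pmin(d2, rowSums((points - matrix(points[centers[j], ], n,
                                              ncol(points), byrow = TRUE))^2))
    }
  }
  points[centers, , drop = FALSE]
}

lloyd_once <- function(points, centers, max_iter = 100L) {
  n <- nrow(points); k <- nrow(centers)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j)
      rowSums((points - matrix(centers[j, ], n, ncol(points), byrow = TRUE))^2))
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster rule: re-seed the centroid at the point farthest from
    # its assigned centroid
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        new_labels[far] <- j
      }
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(points[new_labels == j, , drop = FALSE])
    if (it > 1 && all(new_labels == labels)) { labels <- new_labels; break }
    labels <- new_labels
  }
  wss <- sum((points - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centers = centers, wss = wss)
}

#' Seeded k-means (Lloyd) with farthest-point initialization
#'
#' Best of `restarts` seeded farthest-point initializations by
#' within-cluster sum of squares; Lloyd iterations run to label
#' convergence. An emptied cluster is re-seeded at the point farthest from
#' its current centroid. Deterministic for a fixed seed.
#'
#' @param points n x d numeric matrix.
#' @param k number of clusters, `k <= n`.
#' @param seed integer seed.
#' @param restarts number of initializations (default 10).
#' @return object of class `"clustering_result"`: list with `k`, `labels`,
#'   `centroids`, `wss`, `seed`.
#' @export
kmeans_cluster <- function(points, k, seed = 1L, restarts = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k (", k, ") exceeds number of points (", n, ")")
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- farthest_point_init(points, k, derive_seed(seed, 500L + r))
    fit <- lloyd_once(points, init)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  structure(list(k = as.integer(k), labels = best$labels,
                 centroids = best$centers, wss = best$wss,
                 seed = as.integer(seed)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result> k = ", x$k, ", sizes: ",
      paste(tabulate(x$labels, x$k), collapse = "/"),
      ", WSS = ", format(x$wss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean distance to its own cluster's other
#' members and `b` the minimum over other clusters of the mean distance to
#' that cluster; the silhouette is `(b - a) / max(a, b)`. Singleton
#' clusters contribute 0, as does the degenerate `a = b = 0` case.
#' Euclidean distances.
#'
#' @param points n x d matrix.
#' @param labels integer cluster labels (at least 2 clusters, all
#'   non-empty).
#' @return scalar in [-1, 1].
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette requires at least 2 clusters")
  D <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }                 # singleton rule
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(ks, labels[i]), function(kk)
      mean(D[i, labels == kk]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' `(1/k) sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j)` where `s` is the
#' mean Euclidean distance of a cluster's points to its centroid and `c`
#' the centroids. Lower is better; scale-invariant.
#'
#' @inheritParams silhouette_score
#' @return non-negative scalar; errors on coincident centroids.
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) stop("Davies-Bouldin requires at least 2 clusters")
  cent <- t(vapply(ks, function(kk)
    colMeans(points[labels == kk, , drop = FALSE]), numeric(ncol(points))))
  scat <- vapply(seq_len(k), function(j) {
    pts <- points[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(cent[j, ], nrow(pts), ncol(points),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  ratios <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    dc <- l2norm(cent[i, ] - cent[j, ])
    if (dc == 0)
      stop("coincident centroids for clusters ", ks[i], " and ", ks[j])
    ratios[i, j] <- (scat[i] + scat[j]) / dc
  }
  mean(apply(ratios, 1, max, na.rm = TRUE))
}

#' NPMI topic coherence of a clustering of phrases
#'
#' For each within-cluster phrase pair, the add-one-smoothed normalized
#' pointwise mutual information of document co-occurrence:
#' `NPMI = log(p(a,b) / (p(a) p(b))) / (-log p(a,b))` with
#' `p(.) = (df + 1) / (N + 1)`. Cluster coherence is the mean over its
#' pairs; the score is the mean over clusters that contain at least one
#' pair. Phrases never co-occurring in any document yield negative values;
#' phrases that always co-occur approach 1.
#'
#' @param labels integer cluster label per phrase.
#' @param phrases character vector of phrase texts (same length).
#' @param seqs list of `token_seq` or a [corpus()] supplying document
#'   co-occurrence.
#' @return scalar in [-1, 1] (`NA` if no cluster has >= 2 phrases).
#' @export
topic_coherence <- function(labels, phrases, seqs) {
  if (inherits(seqs, "corpus")) seqs <- preprocess_corpus(seqs)
  N <- length(seqs)
  # document occurrence sets per phrase (contiguous token-run match)
  occ <- lapply(phrases, function(p) {
    ptoks <- strsplit(p, " ", fixed = TRUE)[[1]]
    which(vapply(seqs, function(s) contains_run(s, ptoks), logical(1)))
  })
  df_ <- lengths(occ)
  if (any(df_ == 0))
    warning("phrases with zero document frequency excluded: ",
            paste(phrases[df_ == 0], collapse = ", "))
  per_cluster <- vapply(sort(unique(labels)), function(kk) {
    idx <- which(labels == kk & df_ > 0)
    if (length(idx) < 2) return(NA_real_)
    pairs <- utils::combn(idx, 2)
    vals <- apply(pairs, 2, function(ij) {
      a <- ij[1]; b <- ij[2]
      pab <- (length(intersect(occ[[a]], occ[[b]])) + 1) / (N + 1)
      pa <- (df_[a] + 1) / (N + 1)
      pb <- (df_[b] + 1) / (N + 1)
      log(pab / (pa * pb)) / (-log(pab))
    })
    mean(vals)
  }, numeric(1))
  if (all(is.na(per_cluster))) return(NA_real_)
  mean(per_cluster, na.rm = TRUE)
}

contains_run <- function(s, ptoks) {
  for (span in s$sentences) {
    toks <- s$tokens[span]
    L <- length(toks); n <- length(ptoks)
    if (L < n) next
    for (start in seq_len(L - n + 1L))
      if (all(toks[start:(start + n - 1L)] == ptoks)) return(TRUE)
  }
  FALSE
}

#' Select the number of clusters by three-metric majority vote
#'
#' Clusters the points at every `k` in `k_range`, computes the silhouette
#' coefficient (max wins), Davies-Bouldin index (min wins) and NPMI topic
#' coherence (max wins), and elects the `k` winning the majority of the
#' three votes; ties break toward the smaller `k`.
#'
#' @param points n x d matrix (tangent-space projections).
#' @param phrases phrase text per point (for coherence); may be `NULL` to
#'   skip coherence (vote then uses the two geometric metrics).
#' @param seqs corpus or `token_seq` list backing co-occurrence; may be
#'   `NULL` when `phrases` is `NULL`.
#' @param k_range candidate cluster counts (default 3:7).
#' @param seed,restarts passed to [kmeans_cluster()].
#' @return list with `best_k`, `table` (data.frame k, silhouette,
#'   davies_bouldin, coherence), and `results` (per-k
#'   `clustering_result`).
#' @export
select_k <- function(points, phrases = NULL, seqs = NULL, k_range = 3:7,
                     seed = 1L, restarts = 10L) {
  points <- as.matrix(points)
  if (max(k_range) > nrow(points))
    stop("k_range exceeds the number of points")
  results <- lapply(k_range, function(k)
    kmeans_cluster(points, k, seed = seed, restarts = restarts))
  tab <- data.frame(
    k = k_range,
    silhouette = vapply(results, function(r)
      silhouette_score(points, r$labels), numeric(1)),
    davies_bouldin = vapply(results, function(r)
      davies_bouldin(points, r$labels), numeric(1)),
    coherence = vapply(results, function(r) {
      if (is.null(phrases)) NA_real_
      else topic_coherence(r$labels, phrases, seqs)
    }, numeric(1)))
  votes <- integer(length(k_range))
  cast <- function(idx) votes[idx] <<- votes[idx] + 1L
  cast(which.max(tab$silhouette))
  cast(which.min(tab$davies_bouldin))
  if (!all(is.na(tab$coherence))) cast(which.max(tab$coherence))
  best_k <- k_range[which.max(votes)]   # which.max breaks ties low
  list(best_k = best_k, table = tab, results = results)
}
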