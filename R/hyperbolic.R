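# Poincare-ball geometry and hierarchy-aware embedding.
#
# Points live in the open unit ball B^n = { x : ||x|| < 1 } with distance
#   d(x, y) = acosh( 1 + 2 ||x - y||^2 / ((1 - ||x||^2)(1 - ||y||^2)) ).
# Embeddings are fitted by minimising a weighted metric stress
#   sum_{i<j} w_ij (d(x_i, x_j) - delta_ij)^2
# by projected gradient descent with step backtracking and re-clipping into
# the ball; an optional margin term pushes parents to smaller radius than
# their children when a hierarchy is supplied. A Euclidean baseline fits the
# same stress under the flat metric. Hierarchy preservation is scored by the
# Hierarchical Fidelity Score (HFS): the fraction of parent->child edges
# whose parent is strictly closer to the origin than the child.

check_in_ball <- function(x, name = "point") {
  if (l2norm(x) >= 1)
    stop(name, " is outside the open unit ball (norm = ", l2norm(x), ")")
  invisible(x)
}

#' Poincare-ball distance
#'
#' @param x,y numeric vectors with Euclidean norm < 1.
#' @return non-negative distance; `d(0, x) = 2 atanh(||x||)`.
#' @export
poincare_distance <- function(x, y) {
  check_in_ball(x, "x"); check_in_ball(y, "y")
  num <- sum((x - y)^2)
  den <- (1 - sum(x^2)) * (1 - sum(y^2))
  acosh(1 + 2 * num / den)
}

#' Clip a point into the open ball
#'
#' Points with norm >= `1 - margin` are radially rescaled to norm
#' `1 - margin`; interior points are returned unchanged. Numerical guard
#' for the ball optimizer.
#'
#' @param x numeric vector.
#' @param margin epsilon in (0, 0.1).
#' @return vector with norm <= `1 - margin`.
#' @export
clip_to_ball <- function(x, margin = 1e-5) {
  stopifnot(margin > 0, margin < 0.1)
  n <- l2norm(x)
  if (n >= 1 - margin) x * ((1 - margin) / n) else x
}

#' Logarithmic map at the origin
#'
#' `log_o(x) = 2 / (1 - ||x||^2) * x`: the radial tangent-space projection
#' used before Euclidean clustering. Collinear with `x`; its norm is
#' strictly increasing in `||x||`.
#'
#' @param x numeric vector with norm < 1.
#' @return tangent vector.
#' @export
log_map_origin <- function(x) {
  check_in_ball(x)
  (2 / (1 - sum(x^2))) * x
}

#' Hierarchy edge list
#'
#' @param parent,child integer vectors of indicator indices; the directed
#'   graph must be acyclic with no self-edges.
#' @return object of class `"hierarchy_edges"` (data.frame parent/child).
#' @export
hierarchy_edges <- function(parent, child) {
  stopifnot(length(parent) == length(child))
  if (any(parent == child)) stop("self-edges are not allowed")
  if (has_cycle_edges(as.character(parent), as.character(child)))
    stop("hierarchy must be acyclic")
  structure(data.frame(parent = as.integer(parent),
                       child = as.integer(child)),
            class = c("hierarchy_edges", "data.frame"))
}

#' Embedding set
#'
#' @param coords n x dim matrix, one row per indicator.
#' @param space `"hyperbolic"` (all rows must have norm < 1) or
#'   `"euclidean"`.
#' @return object of class `"embedding_set"`.
#' @export
embedding_set <- function(coords, space = c("hyperbolic", "euclidean")) {
  space <- match.arg(space)
  coords <- as.matrix(coords)
  if (space == "hyperbolic" && any(sqrt(rowSums(coords^2)) >= 1))
    stop("hyperbolic embedding has points outside the open ball")
  structure(list(coords = coords, space = space, n = nrow(coords)),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("<embedding_set> ", x$n, " points, dim ", ncol(x$coords), ", ",
      x$space, " space\n", sep = "")
  invisible(x)
}

space_distance <- function(emb, i, j) {
  if (emb$space == "hyperbolic")
    poincare_distance(emb$coords[i, ], emb$coords[j, ])
  else
    l2norm(emb$coords[i, ] - emb$coords[j, ])
}

root_distances <- function(emb) {
  if (emb$space == "hyperbolic")
    apply(emb$coords, 1, function(p) 2 * atanh(min(l2norm(p), 1 - 1e-15)))
  else
    sqrt(rowSums(emb$coords^2))
}

#' Hierarchical Fidelity Score
#'
#' Fraction of parent->child edges whose parent lies strictly closer to the
#' origin (the hierarchy root) than its child, under the embedding's own
#' metric (ball distance from the origin, or Euclidean norm for the
#' baseline).
#'
#' @param emb an [embedding_set()].
#' @param H a [hierarchy_edges()] with at least one edge.
#' @return scalar in [0, 1].
#' @export
hfs <- function(emb, H) {
  if (!nrow(H)) stop("hierarchy is empty")
  if (max(H$parent, H$child) > emb$n)
    stop("hierarchy references indicators beyond the embedding")
  r <- root_distances(emb)
  mean(r[H$parent] < r[H$child])
}

# pairwise matrices -----------------------------------------------------

pairwise_ball_dist <- function(X) {
  A <- as.matrix(stats::dist(X))^2
  B <- 1 - rowSums(X^2)
  u <- 1 + 2 * A / (B %o% B)
  diag(u) <- 1
  acosh(pmax(u, 1))
}

pairwise_eucl_dist <- function(X) as.matrix(stats::dist(X))

# Stress and gradient, vectorised. Returns list(value, grad n x dim).
stress_grad_hyper <- function(X, delta, W) {
  n <- nrow(X)
  sq <- as.matrix(stats::dist(X))^2
  B <- 1 - rowSums(X^2)
  u <- 1 + 2 * sq / (B %o% B)
  diag(u) <- 1
  D <- acosh(pmax(u, 1))
  R <- D - delta; diag(R) <- 0
  value <- sum(W * R^2) / 2            # each pair counted once
  dDdu <- 1 / sqrt(pmax(u^2 - 1, 1e-12))
  G <- 2 * W * R * dDdu; diag(G) <- 0  # dStress/du_ij
  # du_ij/dx_i = 4 (x_i - x_j) / (B_i B_j) + 4 sq_ij x_i / (B_i^2 B_j)
  M <- G / (B %o% B)                   # n x n
  term1 <- 4 * (rowSums(M) * X - M %*% X)
  coef2 <- 4 * rowSums(G * sq / ((B^2) %o% B))
  grad <- term1 + coef2 * X
  list(value = value, grad = grad)
}

stress_grad_eucl <- function(X, delta, W) {
  D <- as.matrix(stats::dist(X))
  R <- D - delta; diag(R) <- 0
  value <- sum(W * R^2) / 2
  Dsafe <- D; Dsafe[Dsafe == 0] <- 1
  G <- 2 * W * R / Dsafe; diag(G) <- 0
  grad <- rowSums(G) * X - G %*% X
  list(value = value, grad = grad)
}

# Hinge margin term pushing parents to smaller radius than children:
# sum over edges max(0, ||x_p|| - ||x_c|| + m)^2
margin_grad <- function(X, H, m) {
  r <- sqrt(rowSums(X^2))
  viol <- pmax(0, r[H$parent] - r[H$child] + m)
  value <- sum(viol^2)
  grad <- matrix(0, nrow(X), ncol(X))
  act <- which(viol > 0)
  for (k in act) {
    p <- H$parent[k]; c_ <- H$child[k]
    up <- if (r[p] > 0) X[p, ] / r[p] else rep(0, ncol(X))
    uc <- if (r[c_] > 0) X[c_, ] / r[c_] else rep(0, ncol(X))
    grad[p, ] <- grad[p, ] + 2 * viol[k] * up
    grad[c_, ] <- grad[c_, ] - 2 * viol[k] * uc
  }
  list(value = value, grad = grad)
}

init_ball <- function(n, dim, seed, radius = 0.1) {
  with_seed(seed, {
    dir <- matrix(stats::rnorm(n * dim), n, dim)
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
    r <- radius * stats::runif(n)^(1 / dim)
    dir * r
  })
}

# Initialization: classical MDS gives the angular arrangement; for the
# ball, radii are mapped by r -> tanh(r / 2) (the Euclidean norm of a
# point at hyperbolic distance r from the origin), keeping every point
# strictly inside. Seeded Gaussian jitter differentiates restarts and
# breaks ties; falls back to a small random ball when MDS degenerates.
init_embedding <- function(delta, dim, seed, space, clip_eps = 1e-5) {
  n <- nrow(delta)
  X0 <- tryCatch({
    M <- suppressWarnings(stats::cmdscale(stats::as.dist(delta), k = dim))
    if (!is.matrix(M) || ncol(M) < dim)
      M <- cbind(M, matrix(0, n, dim - ncol(M)))
    M
  }, error = function(e) NULL)
  jit <- with_seed(seed, matrix(stats::rnorm(n * dim, sd = 0.01), n, dim))
  if (is.null(X0) || !all(is.finite(X0)) || max(abs(X0)) == 0)
    return(init_ball(n, dim, seed))
  if (space == "euclidean") return(X0 + jit)
  nr <- sqrt(rowSums(X0^2))
  Xb <- X0 * ifelse(nr > 0, tanh(nr / 2) / nr, 0) + jit
  t(apply(Xb, 1, clip_to_ball, margin = clip_eps))
}

fit_stress <- function(delta, dim, seed, iters, lr, space, H = NULL,
                       hierarchy_weight = 1.0, margin = 0.05, W = NULL,
                       clip_eps = 1e-5) {
  n <- nrow(delta)
  if (is.null(W)) { W <- matrix(1, n, n); diag(W) <- 0 }
  X <- init_embedding(delta, dim, seed, space, clip_eps)
  sg <- function(X) {
    base <- if (space == "hyperbolic") stress_grad_hyper(X, delta, W)
            else stress_grad_eucl(X, delta, W)
    if (!is.null(H) && nrow(H) && hierarchy_weight > 0) {
      mg <- margin_grad(X, H, margin)
      base$value <- base$value + hierarchy_weight * mg$value
      base$grad <- base$grad + hierarchy_weight * mg$grad
    }
    base
  }
  cur <- sg(X)
  step <- lr
  trace_stress <- numeric(0)
  for (it in seq_len(iters)) {
    if (space == "hyperbolic") {
      # Riemannian preconditioning: the inverse Poincare metric
      # (1 - ||x||^2)^2 / 4 rescales the Euclidean gradient so step sizes
      # stay comparable between the centre and the boundary.
      lam <- (1 - rowSums(X^2))^2 / 4
      cand <- X - step * (lam * cur$grad)
      cand <- t(apply(cand, 1, clip_to_ball, margin = clip_eps))
    } else {
      cand <- X - step * cur$grad
    }
    new <- sg(cand)
    if (is.finite(new$value) && new$value <= cur$value) {
      X <- cand; cur <- new
      step <- min(step * 1.05, lr * 10)   # cautious step growth
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
    trace_stress <- c(trace_stress, cur$value)
  }
  list(coords = X, stress = cur$value, trace = trace_stress)
}

#' Embed a dissimilarity matrix in the Poincare ball
#'
#' Minimises the weighted metric stress between ball distances and the
#' target dissimilarities by projected gradient descent with backtracking
#' (stress is non-increasing over accepted steps) and re-clipping into the
#' ball. When a hierarchy is supplied, a hinge margin term additionally
#' pushes each parent to a smaller radius than its children
#' (`hierarchy_weight = 0` disables it). Deterministic for fixed inputs and
#' seed.
#'
#' @param dissimilarity symmetric non-negative matrix with zero diagonal.
#' @param H optional [hierarchy_edges()].
#' @param dim ball dimension (default 2).
#' @param seed integer seed (jitters the classical-MDS initialization;
#'   see Details).
#' @param iters gradient iterations (default 2000).
#' @param lr initial learning rate (default 0.05).
#' @param hierarchy_weight weight of the margin term (default 1).
#' @param margin radial margin of the hinge (default 0.05).
#' @return an [embedding_set()] (hyperbolic) with attribute `"stress"`.
#' @export
embed_ball <- function(dissimilarity, H = NULL, dim = 2L, seed = 1L,
                       iters = 2000L, lr = 0.05, hierarchy_weight = 1.0,
                       margin = 0.05) {
  delta <- as.matrix(dissimilarity)
  if (!isTRUE(all.equal(delta, t(delta), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  if (any(diag(delta) != 0)) stop("dissimilarity diagonal must be zero")
  fit <- fit_stress(delta, dim, derive_seed(seed, 21L), iters, lr,
                    "hyperbolic", H, hierarchy_weight, margin)
  out <- embedding_set(fit$coords, "hyperbolic")
  attr(out, "stress") <- fit$stress
  out
}

#' Embed a dissimilarity matrix in Euclidean space (baseline)
#'
#' Same stress objective and optimizer as [embed_ball()] under the flat
#' metric; the comparison baseline.
#'
#' @inheritParams embed_ball
#' @return an [embedding_set()] (euclidean) with attribute `"stress"`.
#' @export
embed_euclidean <- function(dissimilarity, H = NULL, dim = 2L, seed = 1L,
                            iters = 2000L, lr = 0.05,
                            hierarchy_weight = 1.0, margin = 0.05) {
  delta <- as.matrix(dissimilarity)
  if (!isTRUE(all.equal(delta, t(delta), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  if (any(diag(delta) != 0)) stop("dissimilarity diagonal must be zero")
  fit <- fit_stress(delta, dim, derive_seed(seed, 22L), iters, lr,
                    "euclidean", H, hierarchy_weight, margin)
  out <- embedding_set(fit$coords, "euclidean")
  attr(out, "stress") <- fit$stress
  out
}

#' Scale-aligned mean relative distortion
#'
#' Embedded pairwise distances are first aligned to the reference by the
#' least-squares scalar `s* = sum(d_emb d_ref) / sum(d_emb^2)`; the
#' distortion is the mean over pairs of
#' `|s* d_emb - d_ref| / d_ref`. Zero for an embedding reproducing the
#' reference exactly (up to global scale).
#'
#' @param emb an [embedding_set()].
#' @param reference symmetric dissimilarity matrix with positive
#'   off-diagonal entries.
#' @return non-negative scalar.
#' @export
distortion_rate <- function(emb, reference) {
  ref <- as.matrix(reference)
  n <- emb$n
  stopifnot(nrow(ref) == n)
  D <- if (emb$space == "hyperbolic") pairwise_ball_dist(emb$coords)
       else pairwise_eucl_dist(emb$coords)
  iu <- upper.tri(ref)
  if (any(ref[iu] <= 0))
    stop("reference has non-positive off-diagonal entries")
  d_emb <- D[iu]; d_ref <- ref[iu]
  s <- sum(d_emb * d_ref) / sum(d_emb^2)
  mean(abs(s * d_emb - d_ref) / d_ref)
}

#' Compare hyperbolic and Euclidean embeddings of the same inputs
#'
#' Fits both spaces from the same dissimilarities and seed (pure stress,
#' no hierarchy margin, so the geometry alone drives the comparison) and
#' reports the Hierarchical Fidelity Score and distortion rate of each.
#'
#' @inheritParams embed_ball
#' @return list: `hfs_hyperbolic`, `hfs_euclidean`, `distortion_hyperbolic`,
#'   `distortion_euclidean`, plus both embeddings.
#' @export
compare_spaces <- function(dissimilarity, H, dim = 2L, seed = 1L,
                           iters = 2000L, lr = 0.05) {
  eh <- embed_ball(dissimilarity, H = NULL, dim = dim, seed = seed,
                   iters = iters, lr = lr, hierarchy_weight = 0)
  ee <- embed_euclidean(dissimilarity, H = NULL, dim = dim, seed = seed,
                        iters = iters, lr = lr, hierarchy_weight = 0)
  list(hfs_hyperbolic = hfs(eh, H),
       hfs_euclidean = hfs(ee, H),
       distortion_hyperbolic = distortion_rate(eh, dissimilarity),
       distortion_euclidean = distortion_rate(ee, dissimilarity),
       hyperbolic = eh, euclidean = ee)
}

#' Write an embedding set as CSV
#'
#' @param emb an [embedding_set()].
#' @param path output CSV (id, space, one column per coordinate).
#' @param ids optional indicator ids (default 1..n).
#' @export
write_embedding <- function(emb, path, ids = seq_len(emb$n)) {
  df <- data.frame(id = ids, space = emb$space)
  cdf <- as.data.frame(emb$coords)
  names(cdf) <- paste0("x", seq_len(ncol(cdf)))
  utils::write.csv(cbind(df, cdf), path, row.names = FALSE)
  invisible(path)
}
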