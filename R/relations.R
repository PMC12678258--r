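# Multi-head self-attention relation matrix over indicator embeddings, the
# trace-exponential acyclicity penalty h(C) = tr(e^{C o C}) - n, its
# enforcement by an augmented-penalty gradient scheme, and symmetrization.

#' Matrix exponential (scaling and squaring with Pade approximation)
#'
#' [6/6] diagonal Pade approximant after scaling the matrix to 1-norm
#' <= 0.5, followed by repeated squaring; accurate to ~1e-10 or better on
#' matrices with entries in [-2, 2].
#'
#' @param A square numeric matrix.
#' @return matrix exponential of `A`.
#' @export
expm_ss <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("matrix must be square")
  nrm <- max(colSums(abs(A)))
  s <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0L
  As <- A / 2^s
  m <- 6L
  c_ <- numeric(m + 1); c_[1] <- 1
  for (k in 0:(m - 1))
    c_[k + 2] <- c_[k + 1] * (m - k) / ((2 * m - k) * (k + 1))
  P <- diag(n); N <- c_[1] * diag(n); D <- c_[1] * diag(n)
  sign <- 1
  for (k in seq_len(m)) {
    P <- P %*% As
    N <- N + c_[k + 1] * P
    sign <- -sign
    D <- D + sign * c_[k + 1] * P
  }
  R <- solve(D, N)
  if (s > 0) for (k in seq_len(s)) R <- R %*% R
  R
}

#' Acyclicity penalty of a weighted relation matrix
#'
#' `h(C) = tr(exp(C o C)) - n` where `o` is the Hadamard (entry-wise)
#' product. Non-negative for every real matrix and zero exactly when the
#' weighted graph of `C o C` is acyclic (tiny negative values from
#' floating-point roundoff are clamped to zero).
#'
#' @param C square numeric matrix.
#' @return non-negative scalar.
#' @export
dag_penalty <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("relation matrix must be square")
  val <- sum(diag(expm_ss(C * C))) - nrow(C)
  max(val, 0)
}

orthogonal_init <- function(nr, nc, seed) {
  with_seed(seed, {
    M <- matrix(stats::rnorm(max(nr, nc)^2), max(nr, nc))
    Q <- qr.Q(qr(M))
    Q[seq_len(nr), seq_len(nc), drop = FALSE]
  })
}

#' Multi-head self-attention parameters
#'
#' Per-head query/key/value projections (`d x d_k`, seeded orthogonal
#' init) and an output projection mapping each indicator's concatenated
#' head outputs (`h * d_k`) to an `n_out`-vector of relation scores.
#'
#' @param d input embedding dimension.
#' @param n_out output dimension per indicator (the indicator count, for a
#'   square relation matrix).
#' @param h number of heads (default 8).
#' @param d_k key/query/value dimension per head (default 64).
#' @param seed integer seed.
#' @return object of class `"attention_params"`.
#' @export
attention_params <- function(d, n_out, h = 8L, d_k = 64L, seed = 1L) {
  stopifnot(h >= 1, d_k >= 1)
  heads <- lapply(seq_len(h), function(i) list(
    W_Q = orthogonal_init(d, d_k, derive_seed(seed, 300L + 3L * i)),
    W_K = orthogonal_init(d, d_k, derive_seed(seed, 301L + 3L * i)),
    W_V = orthogonal_init(d, d_k, derive_seed(seed, 302L + 3L * i))))
  W_O <- orthogonal_init(h * d_k, n_out, derive_seed(seed, 399L))
  structure(list(heads = heads, W_O = W_O, h = as.integer(h),
                 d_k = as.integer(d_k), d = as.integer(d),
                 n_out = as.integer(n_out), seed = as.integer(seed)),
            class = "attention_params")
}

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' One scaled-dot-product attention head
#'
#' `Q = H W_Q`, `K = H W_K`, `V = H W_V`;
#' `weights = softmax(Q K' / sqrt(d_k))` row-wise; `output = weights V`.
#'
#' @param Hmat n x d matrix of indicator embeddings (rows).
#' @param head list with `W_Q`, `W_K`, `W_V` (each `d x d_k`).
#' @return list with `weights` (n x n, rows sum to 1) and `output`
#'   (n x d_k).
#' @export
attention_head <- function(Hmat, head) {
  Hmat <- as.matrix(Hmat)
  if (ncol(Hmat) != nrow(head$W_Q))
    stop("embedding dimension (", ncol(Hmat), ") does not match W_Q (",
         nrow(head$W_Q), " rows)")
  Q <- Hmat %*% head$W_Q
  K <- Hmat %*% head$W_K
  V <- Hmat %*% head$W_V
  W <- row_softmax(Q %*% t(K) / sqrt(ncol(head$W_Q)))
  list(weights = W, output = W %*% V)
}

#' Multi-head self-attention relation matrix
#'
#' Runs all heads, concatenates their outputs per indicator, and applies
#' the output projection to produce the `n x n_out` relation matrix `C`.
#' Deterministic for fixed parameters; permuting the indicator rows
#' permutes `C`'s rows (and, via the learned projection of the permuted
#' concat, the score columns follow the same indicators).
#'
#' @param Hmat n x d matrix of indicator embeddings.
#' @param params an [attention_params()].
#' @return `n x n_out` matrix `C`.
#' @export
mhsa_relation_matrix <- function(Hmat, params) {
  outs <- lapply(params$heads, function(h) attention_head(Hmat, h)$output)
  concat <- do.call(cbind, outs)
  concat %*% params$W_O
}

#' Symmetrize a relation matrix
#'
#' `S = (C + C') / 2`; idempotent.
#'
#' @param C square matrix.
#' @return symmetric matrix.
#' @export
symmetrize <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("relation matrix must be square")
  (C + t(C)) / 2
}

# gradient of h(X) = tr(e^{X o X}) - n:  (e^{X o X})' o (2 X)
dag_penalty_grad <- function(X) t(expm_ss(X * X)) * (2 * X)

# DFS cycle detection on a logical adjacency matrix; returns an integer
# vector of nodes forming a directed cycle (first == last), or NULL.
find_cycle <- function(A) {
  n <- nrow(A)
  color <- integer(n)          # 0 white, 1 grey, 2 black
  parent <- integer(n)
  for (root in seq_len(n)) {
    if (color[root] != 0L) next
    stack <- list(list(v = root, nbrs = which(A[root, ])))
    color[root] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      if (length(top$nbrs)) {
        w <- top$nbrs[1]
        stack[[length(stack)]]$nbrs <- top$nbrs[-1]
        if (color[w] == 1L) {
          # back edge: unwind the grey path from w to top$v
          path <- vapply(stack, function(e) e$v, integer(1))
          start <- match(w, path)
          return(c(path[start:length(path)], w))
        } else if (color[w] == 0L) {
          color[w] <- 1L
          parent[w] <- top$v
          stack[[length(stack) + 1L]] <- list(v = w, nbrs = which(A[w, ]))
        }
      } else {
        color[top$v] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

# Deterministic cleanup: while the |x| > thr graph has a directed cycle,
# zero the smallest-magnitude edge on that cycle. Zeroing entries of C
# only shrinks C o C entry-wise, so the trace-exponential penalty never
# increases.
break_residual_cycles <- function(X, thr = 1e-6) {
  repeat {
    cyc <- find_cycle(abs(X) > thr)
    if (is.null(cyc)) break
    edges <- cbind(cyc[-length(cyc)], cyc[-1])
    w <- abs(X[edges])
    kill <- edges[which.min(w), , drop = FALSE]
    X[kill] <- 0
  }
  X
}

#' Project a relation matrix onto the acyclic set
#'
#' Minimises `||X - C||_F^2 + lambda h(X)` by gradient descent with step
#' backtracking, doubling `lambda` whenever the inner iteration converges
#' with `h` still above tolerance (an augmented-penalty schedule). Accepted
#' steps never increase the acyclicity penalty. An already-acyclic matrix
#' is returned unchanged.
#'
#' Exact two-cycles (`X_ij = X_ji`) are stationary under symmetric
#' dynamics, so a deterministic infinitesimal tie-break favouring the
#' upper triangle is applied before optimising. After convergence,
#' entries whose magnitude fell below `snap_tol` (optimisation residue of
#' broken cycles) are snapped to exactly zero, and any cycle remaining in
#' the `|x| > 1e-6` thresholded graph is broken by zeroing its
#' smallest-magnitude edge; both cleanups shrink `C o C` entry-wise and
#' therefore never increase the penalty.
#'
#' @param C square numeric matrix.
#' @param tol acyclicity tolerance (default 1e-8).
#' @param lambda0 initial penalty weight.
#' @param max_outer maximum lambda doublings.
#' @param inner_steps gradient steps per lambda value.
#' @param lr initial step size.
#' @param snap_tol entries with `|x| < snap_tol` are zeroed after
#'   convergence (default 1e-3).
#' @return matrix `C'` with `dag_penalty(C') <= tol`, with attribute
#'   `"penalty"`; errors (carrying the final penalty) if the tolerance is
#'   not reached within the step budget.
#' @export
enforce_dag <- function(C, tol = 1e-8, lambda0 = 1, max_outer = 60L,
                        inner_steps = 200L, lr = 0.1, snap_tol = 1e-3) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("relation matrix must be square")
  h0 <- dag_penalty(C)
  if (h0 <= tol) {
    attr(C, "penalty") <- h0
    return(C)
  }
  X <- C
  X[lower.tri(X)] <- X[lower.tri(X)] * (1 - 1e-6)   # symmetry tie-break
  lambda <- lambda0
  h_cur <- h0
  for (outer in seq_len(max_outer)) {
    f_cur <- sum((X - C)^2) + lambda * h_cur
    step <- lr
    for (it in seq_len(inner_steps)) {
      g <- 2 * (X - C) + lambda * dag_penalty_grad(X)
      cand <- X - step * g
      h_new <- dag_penalty(cand)
      f_new <- sum((cand - C)^2) + lambda * h_new
      if (is.finite(f_new) && f_new <= f_cur && h_new <= h_cur + 1e-15) {
        X <- cand; f_cur <- f_new; h_cur <- h_new
        step <- min(step * 1.1, 1)
      } else {
        step <- step / 2
        if (step < 1e-14) break
      }
      if (h_cur <= tol) break
    }
    if (h_cur <= tol) break
    lambda <- lambda * 2
  }
  X[abs(X) < snap_tol] <- 0
  X <- break_residual_cycles(X)
  h_final <- dag_penalty(X)
  if (h_final > tol)
    stop("enforce_dag did not reach tolerance ", tol,
         "; final penalty = ", format(h_final))
  attr(X, "penalty") <- h_final
  X
}

#' Write a labeled relation matrix as CSV
#'
#' @param C square matrix.
#' @param path output path.
#' @param ids row/column labels.
#' @export
write_relation_matrix <- function(C, path, ids = seq_len(nrow(C))) {
  df <- as.data.frame(C)
  names(df) <- ids
  utils::write.csv(cbind(id = ids, df), path, row.names = FALSE)
  invisible(path)
}
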