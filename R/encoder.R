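# Encoder contract: any object for which encode() maps a token vector (or a
# token_seq) to a fixed-dimension numeric vector, deterministically given the
# object's parameters. Two implementations ship:
#   * hash_encoder      - deterministic seeded random-projection bag-of-tokens
#                         encoder; the desk-scale default, needs no training.
#   * embedding_encoder - a trainable token-embedding model (mean of learned
#                         token vectors) optimised by train_contrastive().

#' Encode tokens into a vector
#'
#' @param encoder an encoder object.
#' @param x a character vector of tokens, or a `token_seq`.
#' @return numeric vector of length `encoder$d`.
#' @export
encode <- function(encoder, x) UseMethod("encode")

as_tokens <- function(x) {
  if (inherits(x, "token_seq")) x$tokens
  else if (is.character(x)) x
  else stop("cannot encode object of class ", paste(class(x), collapse = "/"))
}

#' Deterministic random-projection bag-of-tokens encoder
#'
#' Every token type is assigned a fixed direction keyed by a stable string
#' hash and the encoder seed; a text is encoded as the mean of its token
#' directions. Identical input always yields an identical finite vector,
#' across sessions, with no training step. Serves as the default
#' document/phrase representation wherever a fine-tuned language model is
#' out of scope.
#'
#' Token directions share a common anisotropy component: each direction is
#' `sqrt(anisotropy) * g + sqrt(1 - anisotropy) * r_token` with `g` a fixed
#' unit vector and `r_token` the token's private Gaussian direction.
#' Transformer embedding spaces are strongly anisotropic (cosines between
#' arbitrary texts sit well above 0), and absolute cosine thresholds such
#' as a 0.65 relevance floor are only meaningful in such a geometry; the
#' default `anisotropy = 0.3` reproduces that regime.
#'
#' @param d embedding dimension (default 64; configurable).
#' @param seed integer seed fixing all token directions.
#' @param anisotropy fraction of direction variance shared by all tokens,
#'   in [0, 1).
#' @return object of class `"hash_encoder"`.
#' @export
hash_encoder <- function(d = 64L, seed = 1L, anisotropy = 0.3) {
  stopifnot(anisotropy >= 0, anisotropy < 1)
  enc <- structure(list(d = as.integer(d), seed = as.integer(seed),
                        anisotropy = anisotropy,
                        cache = new.env(parent = emptyenv())),
                   class = "hash_encoder")
  g <- with_seed(derive_seed(seed, 12345L), stats::rnorm(d))
  enc$g <- g / l2norm(g)
  enc
}

token_direction <- function(enc, token) {
  v <- enc$cache[[token]]
  if (is.null(v)) {
    r <- with_seed(derive_seed(enc$seed, hash_string(token)),
                   stats::rnorm(enc$d))
    a <- enc$anisotropy %||% 0
    v <- sqrt(a) * enc$g * l2norm(r) + sqrt(1 - a) * r
    enc$cache[[token]] <- v
  }
  v
}

#' @export
encode.hash_encoder <- function(encoder, x) {
  toks <- as_tokens(x)
  if (!length(toks)) return(numeric(encoder$d))
  out <- numeric(encoder$d)
  for (t in toks) out <- out + token_direction(encoder, t)
  out / length(toks)
}

#' Trainable token-embedding encoder
#'
#' Holds a vocabulary and an embedding matrix `E` (one row per token plus a
#' reserved `[mask]` row); a text is encoded as the mean of its token rows.
#' Out-of-vocabulary tokens map to a zero row. Parameters are initialised
#' with seeded Gaussian noise and updated by [train_contrastive()].
#'
#' @param vocab character vector of token types.
#' @param d embedding dimension.
#' @param seed integer seed for the initial parameters.
#' @return object of class `"embedding_encoder"`.
#' @export
embedding_encoder <- function(vocab, d = 32L, seed = 1L) {
  vocab <- unique(c(vocab, "[mask]"))
  E <- with_seed(derive_seed(seed, 3L),
                 matrix(stats::rnorm(length(vocab) * d, sd = 0.5),
                        nrow = length(vocab), ncol = d,
                        dimnames = list(vocab, NULL)))
  structure(list(d = as.integer(d), vocab = vocab, E = E,
                 seed = as.integer(seed)),
            class = "embedding_encoder")
}

#' @export
encode.embedding_encoder <- function(encoder, x) {
  toks <- as_tokens(x)
  idx <- match(toks, encoder$vocab)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(numeric(encoder$d))
  colMeans(encoder$E[idx, , drop = FALSE])
}

# token-index multiset of a doc restricted to the vocabulary
vocab_indices <- function(encoder, toks) {
  idx <- match(toks, encoder$vocab)
  idx[!is.na(idx)]
}
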