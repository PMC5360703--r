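# Internal numeric and indexing helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  out <- m + log(rowSums(exp(M - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Mixed-radix (first-position-fastest) index of joint categorical states.
# `states` is an n x k matrix of 0-based states, `cards` the k cardinalities.
# Returns 1-based joint indices in 1..prod(cards).
mr_index <- function(states, cards) {
  n <- if (is.matrix(states)) nrow(states) else 1L
  if (length(cards) == 0L) return(rep.int(1L, n))
  strides <- cumprod(c(1, cards[-length(cards)]))
  as.integer(round(states %*% strides)) + 1L
}

# Inverse of mr_index: decode 1-based joint indices into a matrix of 0-based
# states, first position fastest.
mr_decode <- function(idx, cards) {
  idx <- as.integer(idx) - 1L
  out <- matrix(0L, length(idx), length(cards))
  for (j in seq_along(cards)) {
    out[, j] <- idx %% cards[j]
    idx <- idx %/% cards[j]
  }
  out
}

# All joint assignments of the given cardinalities, 0-based, first column
# fastest (column order matches mr_index).
mr_grid <- function(cards) {
  if (length(cards) == 0L) return(matrix(integer(0), 1L, 0L))
  g <- as.matrix(expand.grid(lapply(cards, function(k) 0:(k - 1L)),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- list(NULL, names(cards))
  storage.mode(g) <- "integer"
  g
}

# Column-normalized Dirichlet(alpha) draws: nr x nc stochastic matrix.
rdirichlet_cols <- function(nr, nc, alpha = 1) {
  g <- matrix(stats::rgamma(nr * nc, shape = alpha), nr, nc)
  sweep(g, 2L, colSums(g), "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
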