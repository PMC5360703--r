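#' Bayesian model evidence with an accuracy-complexity decomposition
#'
#' Each conditional-table column (one parameter simplex per joint parent
#' configuration) carries an independent symmetric Dirichlet prior with
#' concentration `alpha` per cell. For complete data the log marginal
#' likelihood is available in closed form (log-Gamma normalizer ratios) and
#' decomposes *exactly* as accuracy minus complexity, where accuracy is the
#' posterior-expected log-likelihood (digamma terms) and complexity is the
#' Kullback-Leibler divergence between the posterior and prior over the
#' table parameters. With hidden variables the evidence is the sum of
#' complete-data evidences over all joint completions (exact, for tiny
#' datasets) or an EM + BIC approximation ([approx_evidence_bic()]).
#'
#' @name evidence
NULL

evidence_result <- function(log_evidence, accuracy, complexity, method,
                            detail = list()) {
  structure(list(log_evidence = log_evidence, accuracy = accuracy,
                 complexity = complexity, method = method, detail = detail),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("log evidence %.6f = accuracy %.6f - complexity %.6f  [%s]\n",
              x$log_evidence, x$accuracy, x$complexity, x$method))
  invisible(x)
}

# Columns of `data` relevant to the model, as an integer matrix.
data_matrix <- function(model, data, required = names(model$cards)) {
  missing <- setdiff(required, colnames(data))
  if (length(missing))
    stop("incomplete-data error: data lacks column(s) ",
         paste(missing, collapse = ", "))
  M <- as.matrix(data[, required, drop = FALSE])
  storage.mode(M) <- "integer"
  bad <- vapply(required, function(v)
    any(M[, v] < 0L | M[, v] >= model$cards[[v]]), logical(1))
  if (any(bad))
    stop("data states out of declared cardinality for ",
         paste(required[bad], collapse = ", "))
  M
}

# Count matrix (joint child state x joint parent config) for one block.
block_counts <- function(model, block, M) {
  nr <- prod(model$cards[block$children])
  nc <- prod(c(1, model$cards[block$parents]))
  r <- mr_index(M[, block$children, drop = FALSE], model$cards[block$children])
  cc <- mr_index(M[, block$parents, drop = FALSE], model$cards[block$parents])
  matrix(tabulate(r + (cc - 1L) * nr, nr * nc), nr, nc)
}

# Evidence, accuracy and KL complexity of one block from its count matrix.
# Identity log_ev = acc - kl holds exactly (the digamma terms cancel).
block_score <- function(N, alpha) {
  K <- nrow(N)
  n <- colSums(N)
  a <- alpha + N
  A <- K * alpha + n
  ev <- sum(lgamma(K * alpha) - lgamma(A)) + sum(lgamma(a) - lgamma(alpha))
  dg <- digamma(a) - rep(digamma(A), each = K)
  acc <- sum(N * dg)
  kl <- sum(lgamma(A)) - sum(lgamma(a)) -
    length(n) * (lgamma(K * alpha) - K * lgamma(alpha)) + sum(N * dg)
  list(ev = ev, acc = acc, kl = kl)
}

#' Closed-form log marginal likelihood for complete data
#'
#' Every model variable (latents included) must be observed in every record.
#' The evidence is the product over blocks and parent configurations of
#' Dirichlet-multinomial normalizer ratios; accuracy and complexity come
#' from the exact conjugate posterior, and
#' `log_evidence == accuracy - complexity` holds to machine precision.
#'
#' @param structure A `gen_model` skeleton. Tables of blocks whose tag is in
#'   `fixed_tags` are treated as known (they contribute plain log-likelihood
#'   and no parameter complexity); all other tables are ignored - only the
#'   graph and cardinalities matter, their parameters are integrated out.
#' @param data Data frame with one 0-based state column per model variable.
#' @param alpha Symmetric Dirichlet concentration per table cell
#'   (default 1).
#' @param fixed_tags Tags of blocks with known tables; defaults to the
#'   observation-noise blocks (the sensor model), matching [fit_em()].
#' @return An `evidence_result` with `method = "complete_closed_form"` and a
#'   per-block detail table.
#' @export
log_marginal_complete <- function(structure, data, alpha = 1,
                                  fixed_tags = "observation") {
  if (!is.numeric(alpha) || alpha <= 0) stop("prior error: alpha must be > 0")
  M <- data_matrix(structure, data)
  ev <- acc <- kl <- 0
  detail <- list()
  for (b in structure$blocks) {
    if (b$tag %in% fixed_tags) {
      N <- block_counts(structure, b, M)
      ll <- sum(N[N > 0] * log(b$table)[N > 0]) # -Inf if a zero cell is hit
      ev <- ev + ll; acc <- acc + ll
      detail[[b$name]] <- c(log_evidence = ll, accuracy = ll, complexity = 0)
      next
    }
    s <- block_score(block_counts(structure, b, M), alpha)
    ev <- ev + s$ev; acc <- acc + s$acc; kl <- kl + s$kl
    detail[[b$name]] <- c(log_evidence = s$ev, accuracy = s$acc,
                          complexity = s$kl)
  }
  evidence_result(ev, acc, kl, "complete_closed_form", detail)
}

#' Exact evidence with hidden variables summed out
#'
#' The marginal likelihood of the observed columns: the sum over every joint
#' completion of the hidden variables across records of the complete-data
#' evidence. Exact but exponential in the record count; guarded by a
#' completion budget (use [approx_evidence_bic()] beyond it). The accuracy
#' and complexity fields are completion-posterior-weighted averages of the
#' complete-data terms and are therefore approximate for this method (the
#' exact decomposition identity applies to complete data only).
#'
#' @param structure A `gen_model`.
#' @param data Data frame containing the observed columns; model variables
#'   absent from it are treated as hidden.
#' @param alpha Dirichlet concentration per cell.
#' @param observed Character vector naming the observed model variables;
#'   defaults to the model variables present in `data` minus any columns
#'   flagged as ground truth via `attr(data, "latent_cols")`.
#' @param budget Maximum number of joint completions (default `1e6`).
#' @param fixed_tags Tags of blocks with known tables (see
#'   [log_marginal_complete()]); completions inconsistent with a
#'   deterministic known table contribute nothing.
#' @return An `evidence_result` with `method = "latent_exact"`.
#' @export
log_marginal_latent_exact <- function(structure, data, alpha = 1,
                                      observed = NULL, budget = 1e6,
                                      fixed_tags = "observation") {
  if (!is.numeric(alpha) || alpha <= 0) stop("prior error: alpha must be > 0")
  observed <- observed %||% setdiff(
    intersect(names(structure$cards), colnames(data)),
    attr(data, "latent_cols"))
  hidden <- setdiff(names(structure$cards), observed)
  n <- nrow(data)
  if (length(hidden) == 0L)
    return(log_marginal_complete(structure, data, alpha, fixed_tags))
  m <- prod(structure$cards[hidden])
  total <- m^n
  if (total > budget)
    stop("budget error: ", m, "^", n, " = ", format(total, big.mark = ","),
         " completions exceed the budget of ", format(budget, big.mark = ","),
         "; use approx_evidence_bic() instead")
  Mobs <- data_matrix(structure, data, observed)
  hgrid <- mr_grid(structure$cards[hidden])
  full <- matrix(0L, n, length(structure$cards),
                 dimnames = list(NULL, names(structure$cards)))
  full[, observed] <- Mobs
  evs <- accs <- kls <- numeric(total)
  for (i in seq_len(total)) {
    cfg_idx <- mr_decode(i, rep(m, n))[1, ] # per-record hidden config, base m
    full[, hidden] <- hgrid[cfg_idx + 1L, , drop = FALSE]
    r <- log_marginal_complete(structure, as.data.frame(full), alpha,
                               fixed_tags)
    evs[i] <- r$log_evidence; accs[i] <- r$accuracy; kls[i] <- r$complexity
  }
  lz <- logsumexp(evs)
  w <- exp(evs - lz)
  pos <- w > 0
  evidence_result(lz, sum(w[pos] * accs[pos]), sum(w[pos] * kls[pos]),
                  "latent_exact",
                  detail = list(completions = total,
                                contributing = sum(is.finite(evs))))
}
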