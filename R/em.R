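#' Expectation-maximization over hidden variables
#'
#' Maximum a posteriori table estimation under the per-column symmetric
#' Dirichlet prior, by EM over the joint states of the hidden variables.
#' Blocks whose tag is in `fixed_tags` keep the tables of the supplied
#' structure (by default the observation-noise blocks: the sensor model is
#' treated as known, which is what makes hidden features identifiable);
#' all other tables are re-estimated.
#'
#' @param structure A valid `gen_model`; tables of fixed blocks are used
#'   as-is, tables of free blocks only provide the shapes.
#' @param data Data frame of records with 0-based state columns.
#' @param alpha Dirichlet concentration per cell; the M-step maximizes the
#'   posterior (counts plus `alpha - 1`). `alpha = 1` gives maximum
#'   likelihood.
#' @param restarts Number of random restarts (best final objective wins).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative convergence tolerance on the objective
#'   (log-likelihood plus log-prior): iteration stops when the objective
#'   improves by less than `tol * (1 + |objective|)`.
#' @param seed Mandatory integer seed for the random initializations.
#' @param fixed_tags Tags of blocks whose tables are held fixed.
#' @param observed Observed model variables; defaults to the model variables
#'   present in `data` minus any `attr(data, "latent_cols")` columns.
#' @return A list with elements `model` (structure with fitted tables),
#'   `loglik` (log-likelihood of the data at the fitted tables), `logpost`
#'   (the EM objective), `trace` (objective per iteration of the winning
#'   restart), `converged` (flag; non-convergence is returned with a
#'   warning, not an error), `iterations`, and `seed`.
#' @export
fit_em <- function(structure, data, alpha = 1, restarts = 2L, max_iter = 200L,
                   tol = 1e-6, seed, fixed_tags = "observation",
                   observed = NULL) {
  if (missing(seed)) stop("fit_em requires an explicit seed")
  if (restarts < 1L) stop("restarts must be >= 1")
  if (alpha < 1) warning("alpha < 1 makes the MAP M-step degenerate; ",
                         "estimates are clamped at zero")
  observed <- observed %||% setdiff(
    intersect(names(structure$cards), colnames(data)),
    attr(data, "latent_cols"))
  hidden <- setdiff(names(structure$cards), observed)
  Mobs <- data_matrix(structure, data, observed)
  n <- nrow(Mobs)
  free <- which(vapply(structure$blocks,
                       function(b) !(b$tag %in% fixed_tags), logical(1)))

  if (length(hidden) == 0L) {
    # complete data: closed-form MAP in one step
    model <- structure
    for (i in free) {
      b <- model$blocks[[i]]
      N <- block_counts(model, b, Mobs) + alpha - 1
      N[N < 0] <- 0
      cs <- colSums(N)
      tab <- sweep(N, 2L, ifelse(cs > 0, cs, 1), "/")
      tab[, cs == 0] <- 1 / nrow(N)
      model$blocks[[i]]$table <- tab
    }
    ll <- sum(log_joint_matrix(model, Mobs))
    lpri <- em_log_prior(model, free, alpha)
    return(list(model = model, loglik = ll, logpost = ll + lpri,
                trace = ll + lpri, converged = TRUE, iterations = 1L,
                seed = seed))
  }

  m <- prod(structure$cards[hidden])
  hgrid <- mr_grid(structure$cards[hidden])
  # Per-block flat cell indices for every (record, hidden config) pair.
  # Row/column indices split additively between observed and hidden parts.
  idx <- lapply(structure$blocks, function(b) {
    ch <- b$children; pa <- b$parents
    nr <- prod(structure$cards[ch])
    part <- function(vars, cards) {
      ov <- intersect(vars, observed); hv <- intersect(vars, hidden)
      strides <- cumprod(c(1, cards[-length(cards)]))
      names(strides) <- vars
      dpart <- if (length(ov))
        as.integer(Mobs[, ov, drop = FALSE] %*% strides[ov]) else
          integer(n) * 0L
      hpart <- if (length(hv))
        as.integer(hgrid[, hv, drop = FALSE] %*% strides[hv]) else
          rep.int(0L, m)
      list(d = dpart, h = hpart)
    }
    r <- part(ch, structure$cards[ch])
    cc <- if (length(pa)) part(pa, structure$cards[pa]) else
      list(d = integer(n) * 0L, h = rep.int(0L, m))
    # flat index = (row) + nr * (col), both 0-based, then + 1; kept as a
    # plain vector so table lookups are always linear (a two-column index
    # matrix would otherwise trigger coordinate indexing)
    list(flat = as.vector(outer(r$d + nr * cc$d, r$h + nr * cc$h, "+")) + 1L,
         ncell = length(b$table))
  })

  set.seed(seed)
  best <- NULL
  for (rs in seq_len(restarts)) {
    model <- structure
    for (i in free) {
      b <- model$blocks[[i]]
      model$blocks[[i]]$table <- rdirichlet_cols(nrow(b$table), ncol(b$table))
    }
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # E-step: log p(record, hidden config) for all pairs
      L <- matrix(0, n, m)
      for (bi in seq_along(model$blocks)) {
        lt <- log(model$blocks[[bi]]$table)
        L <- L + matrix(lt[idx[[bi]]$flat], n, m)
      }
      rl <- row_logsumexp(L)
      R <- exp(L - rl)
      obj <- sum(rl) + em_log_prior(model, free, alpha)
      trace <- c(trace, obj)
      # M-step on free blocks
      w <- as.vector(R)
      for (bi in free) {
        b <- model$blocks[[bi]]
        cnt <- numeric(idx[[bi]]$ncell)
        agg <- rowsum(w, idx[[bi]]$flat)
        cnt[as.integer(rownames(agg))] <- agg
        N <- matrix(cnt, nrow(b$table), ncol(b$table)) + alpha - 1
        N[N < 0] <- 0
        cs <- colSums(N)
        tab <- sweep(N, 2L, ifelse(cs > 0, cs, 1), "/")
        tab[, cs == 0] <- 1 / nrow(b$table)
        model$blocks[[bi]]$table <- tab
      }
      if (is.finite(prev) && abs(obj - prev) < tol * (1 + abs(obj))) {
        converged <- TRUE
        break
      }
      prev <- obj
    }
    # final objective/likelihood at the last parameter values
    L <- matrix(0, n, m)
    for (bi in seq_along(model$blocks))
      L <- L + matrix(log(model$blocks[[bi]]$table)[idx[[bi]]$flat], n, m)
    rl <- row_logsumexp(L)
    ll <- sum(rl)
    obj <- ll + em_log_prior(model, free, alpha)
    cand <- list(model = model, loglik = ll, logpost = obj,
                 trace = c(trace, obj), converged = converged,
                 iterations = length(trace), seed = seed)
    if (is.null(best) || cand$logpost > best$logpost) best <- cand
  }
  if (!best$converged)
    warning("EM did not converge within ", max_iter, " iterations")
  best
}

# log Dirichlet prior density over the free blocks' tables, dropping the
# constant normalizer (it cancels in EM comparisons); zero when alpha == 1.
em_log_prior <- function(model, free, alpha) {
  if (alpha == 1) return(0)
  s <- 0
  for (i in free) {
    tab <- model$blocks[[i]]$table
    lt <- log(tab)
    lt[tab == 0] <- 0 # 0 * log 0 convention; alpha > 1 keeps mass interior
    s <- s + (alpha - 1) * sum(lt)
  }
  s
}

# Free parameters of the selected blocks: cells minus one normalization
# constraint per parent configuration. This is the standard count used by
# the BIC penalty and deliberately differs from the raw cell counts of the
# characteristic-parameter calculus.
free_parameters <- function(model, block_idx) {
  sum(vapply(model$blocks[block_idx], function(b)
    (nrow(b$table) - 1) * ncol(b$table), numeric(1)))
}

#' BIC-approximated log evidence via EM
#'
#' Fits the free tables by [fit_em()] and reports
#' `loglik - (k / 2) * log(n)` where `k` counts the free parameters of the
#' fitted blocks (cells minus one normalization constraint per parent
#' configuration). The accuracy field carries the maximized log-likelihood
#' and the complexity field the BIC penalty, so the decomposition reading
#' is preserved in spirit; the exact KL identity applies only to the
#' complete-data method.
#'
#' @inheritParams fit_em
#' @return An `evidence_result` with `method = "em_bic"`; the detail list
#'   carries `k`, the EM fit, and the seed.
#' @export
approx_evidence_bic <- function(structure, data, alpha = 1, seed,
                                restarts = 2L, max_iter = 200L, tol = 1e-6,
                                fixed_tags = "observation", observed = NULL) {
  fit <- fit_em(structure, data, alpha = alpha, restarts = restarts,
                max_iter = max_iter, tol = tol, seed = seed,
                fixed_tags = fixed_tags, observed = observed)
  free <- which(vapply(structure$blocks,
                       function(b) !(b$tag %in% fixed_tags), logical(1)))
  k <- free_parameters(structure, free)
  penalty <- k / 2 * log(nrow(data))
  evidence_result(fit$loglik - penalty, fit$loglik, penalty, "em_bic",
                  detail = list(k = k, seed = seed, fit = fit))
}

#' Rank candidate structures by log evidence
#'
#' All candidates must expose the same observed variables as the data.
#' Ties (within 1e-9) are broken by fewer total table cells, then by input
#' order.
#'
#' @param candidates Named list of `gen_model` structures.
#' @param data Data frame of records.
#' @param method `"bic"` ([approx_evidence_bic()]), `"latent_exact"`
#'   ([log_marginal_latent_exact()]) or `"complete"`
#'   ([log_marginal_complete()]).
#' @param alpha Dirichlet concentration per cell.
#' @param seed Seed, required for `"bic"`.
#' @param ... Passed to the chosen evidence function.
#' @return A data frame (one row per candidate, best first) with columns
#'   `model`, `log_evidence`, `accuracy`, `complexity`, `method`,
#'   `total_cells`; the per-candidate `evidence_result`s are attached as
#'   attribute `results`.
#' @export
select_model <- function(candidates, data, method = c("bic", "latent_exact",
                                                      "complete"),
                         alpha = 1, seed = NULL, ...) {
  method <- match.arg(method)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    names(candidates) <- paste0("model_", seq_along(candidates))
  obs_sets <- lapply(candidates, function(s) setdiff(
    intersect(names(s$cards), colnames(data)), attr(data, "latent_cols")))
  if (length(unique(lapply(obs_sets, sort))) != 1L)
    stop("schema error: candidates do not share the data's observation schema")
  if (length(obs_sets[[1]]) == 0L)
    stop("schema error: no candidate variable matches a data column")
  results <- lapply(candidates, function(s) switch(
    method,
    bic = {
      if (is.null(seed)) stop("method 'bic' requires a seed")
      approx_evidence_bic(s, data, alpha = alpha, seed = seed, ...)
    },
    latent_exact = log_marginal_latent_exact(s, data, alpha = alpha, ...),
    complete = log_marginal_complete(s, data, alpha = alpha)))
  cells <- vapply(candidates, function(s) count_block_cells(s), numeric(1))
  ev <- vapply(results, `[[`, numeric(1), "log_evidence")
  ord <- order(-round(ev / 1e-9) * 1e-9, cells, seq_along(ev))
  out <- data.frame(model = names(candidates)[ord],
                    log_evidence = ev[ord],
                    accuracy = vapply(results, `[[`, numeric(1), "accuracy")[ord],
                    complexity = vapply(results, `[[`, numeric(1), "complexity")[ord],
                    method = vapply(results, `[[`, character(1), "method")[ord],
                    total_cells = cells[ord],
                    row.names = NULL)
  attr(out, "results") <- results
  out
}
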