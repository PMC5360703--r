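# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized index machinery: cells are located by naive
# digit-by-digit arithmetic and evidences by the sequential predictive rule.

oracle_cell <- function(block, cards, assign) {
  ridx <- 0; mult <- 1
  for (v in block$children) {
    ridx <- ridx + assign[[v]] * mult
    mult <- mult * cards[[v]]
  }
  cidx <- 0; mult <- 1
  for (v in block$parents) {
    cidx <- cidx + assign[[v]] * mult
    mult <- mult * cards[[v]]
  }
  block$table[ridx + 1, cidx + 1]
}

oracle_joint <- function(model, assign) {
  prod(vapply(model$blocks, oracle_cell, numeric(1), cards = model$cards,
              assign = assign))
}

# Full joint table by per-assignment evaluation.
oracle_joint_grid <- function(model) {
  g <- expand.grid(lapply(model$cards, function(k) 0:(k - 1)),
                   KEEP.OUT.ATTRS = FALSE)
  g$p <- vapply(seq_len(nrow(g)), function(i)
    oracle_joint(model, as.list(g[i, names(model$cards)])), numeric(1))
  g
}

# Posterior by filtering and aggregating the full joint table.
oracle_posterior <- function(model, clamped, query) {
  g <- oracle_joint_grid(model)
  keep <- rep(TRUE, nrow(g))
  for (v in names(clamped)) keep <- keep & g[[v]] == clamped[[v]]
  g <- g[keep, , drop = FALSE]
  agg <- stats::aggregate(g$p, by = g[, query, drop = FALSE], FUN = sum)
  agg <- agg[do.call(order, rev(agg[, query, drop = FALSE])), , drop = FALSE]
  agg$x / sum(agg$x)
}

# Complete-data log evidence by the sequential predictive rule: records are
# scored one at a time with probability (alpha + count so far) over
# (K alpha + column total so far).
oracle_complete_evidence <- function(model, data, alpha = 1) {
  lp <- 0
  counts <- lapply(model$blocks, function(b) {
    nr <- prod(model$cards[b$children])
    nc <- prod(c(1, model$cards[b$parents]))
    matrix(0, nr, nc)
  })
  for (i in seq_len(nrow(data))) {
    assign <- as.list(data[i, names(model$cards)])
    for (bi in seq_along(model$blocks)) {
      b <- model$blocks[[bi]]
      ridx <- 0; mult <- 1
      for (v in b$children) {
        ridx <- ridx + assign[[v]] * mult
        mult <- mult * model$cards[[v]]
      }
      cidx <- 0; mult <- 1
      for (v in b$parents) {
        cidx <- cidx + assign[[v]] * mult
        mult <- mult * model$cards[[v]]
      }
      N <- counts[[bi]]
      K <- nrow(N)
      lp <- lp + log((alpha + N[ridx + 1, cidx + 1]) /
                       (K * alpha + sum(N[, cidx + 1])))
      counts[[bi]][ridx + 1, cidx + 1] <- N[ridx + 1, cidx + 1] + 1
    }
  }
  lp
}

# Hidden-variable evidence by explicit recursion over per-record hidden
# completions, summing complete-data evidences.
oracle_latent_evidence <- function(model, data, hidden, alpha = 1) {
  hcards <- model$cards[hidden]
  hconfigs <- expand.grid(lapply(hcards, function(k) 0:(k - 1)),
                          KEEP.OUT.ATTRS = FALSE)
  n <- nrow(data)
  m <- nrow(hconfigs)
  lps <- numeric(0)
  rec <- function(i, filled) {
    if (i > n) {
      lps[[length(lps) + 1]] <<- oracle_complete_evidence(model, filled, alpha)
      return(invisible())
    }
    for (k in seq_len(m)) {
      filled[i, hidden] <- as.integer(hconfigs[k, ])
      rec(i + 1, filled)
    }
  }
  filled <- data
  for (h in hidden) filled[[h]] <- 0L
  rec(1L, filled)
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# Random small DAG model with Dirichlet tables; occasionally a joint
# two-child block. All variables get the observation role so any of them
# may be clamped in posterior checks.
random_model <- function(nvars = 4, max_card = 3, p_edge = 0.4,
                         joint_block = FALSE) {
  cards <- sample(2:max_card, nvars, replace = TRUE)
  nms <- paste0("V", seq_len(nvars))
  vars <- lapply(seq_len(nvars), function(i)
    gm_variable(nms[i], "observation", cards[i]))
  groups <- as.list(seq_len(nvars))
  if (joint_block && nvars >= 3) {
    pair <- sort(sample(2:nvars, 2)) # keep V1 available as a parent
    groups <- c(list(pair), as.list(setdiff(seq_len(nvars), pair)))
  }
  blocks <- list()
  done <- integer(0)
  for (g in groups) {
    pool <- setdiff(done, g)
    parents <- pool[stats::runif(length(pool)) < p_edge]
    nr <- prod(cards[g])
    nc <- prod(c(1, cards[parents]))
    tab <- matrix(stats::rgamma(nr * nc, 1), nr, nc)
    tab <- sweep(tab, 2, colSums(tab), "/")
    blocks[[length(blocks) + 1]] <- gm_block(nms[g], nms[parents], tab)
    done <- c(done, g)
  }
  gen_model(vars, blocks)
}

random_cfg <- function() {
  structure_config(F = sample(1:4, 1), n_f = sample(2:3, 1),
                   F1 = sample(1:3, 1), F2 = sample(1:3, 1),
                   n_f1 = sample(2:3, 1), n_f2 = sample(2:3, 1),
                   n_L1 = sample(2:4, 1), n_L2 = sample(2:4, 1),
                   n_c = sample(2:3, 1), n_a = sample(2:3, 1),
                   n_g = sample(2:3, 1), epsilon = stats::runif(1, 0, 0.3))
}

tv_cols_mean <- function(A, B) mean(colSums(abs(A - B)) / 2)

block_by_tag <- function(model, tag) {
  model$blocks[[which(vapply(model$blocks, function(b) b$tag == tag,
                             logical(1)))[1]]]
}
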