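#' Synthetic ground-truth worlds
#'
#' A world is a fully parameterized generative model used as ground truth:
#' flat (independent features, goal tied to the full feature-action
#' combination), latent (features generated by one latent cause),
#' hierarchical (two latent levels) or contextual (hierarchy plus a context
#' variable gating the goal rule). Feature tables concentrate mass on one
#' designated pattern per latent state (probability `1 - feature_slack`,
#' the rest uniform over other patterns); the goal rule assigns each
#' parent configuration a preferred action that attains the goal with
#' probability `1 - goal_slack`. All randomness is seeded.
#'
#' @param kind `"flat"`, `"latent"`, `"hierarchical"` or `"contextual"`.
#' @param cfg A [structure_config()]; `n_g` must be 2 for rule-based goals.
#' @param determinism List with `feature_slack` and `goal_slack` in
#'   `[0, 1)` (defaults 0.05 and 0.1; zero gives a deterministic world).
#' @param goal_rule Optional explicit rule: a list with `preferred`, an
#'   integer vector of 0-based preferred actions indexed by the joint
#'   configuration of the goal block's non-action parents (first parent
#'   fastest). Default `NULL` draws preferred actions from the seeded
#'   generator (distinct across latent states whenever `n_a` allows, so
#'   the latent stays action-relevant).
#' @param patterns Optional explicit list of designated patterns:
#'   `low` (0-based joint pattern index of the low feature subset per L1
#'   state), `high` (joint index of the (high-subset, L1) child group per
#'   L2 state, for hierarchical/contextual kinds). Default `NULL` samples
#'   distinct patterns.
#' @param seed Integer seed.
#' @return A `world_spec` object.
#' @export
world_spec <- function(kind = c("flat", "latent", "hierarchical",
                                "contextual"),
                       cfg = structure_config(),
                       determinism = list(), goal_rule = NULL,
                       patterns = NULL, seed = 1L) {
  kind <- match.arg(kind)
  det <- utils::modifyList(list(feature_slack = 0.05, goal_slack = 0.1),
                           determinism)
  if (det$feature_slack < 0 || det$feature_slack >= 1 ||
      det$goal_slack < 0 || det$goal_slack >= 1)
    stop("spec error: slack probabilities must lie in [0, 1)")
  if (cfg$n_g != 2L)
    stop("spec error: rule-based worlds need a binary goal (n_g = 2)")
  structure(list(kind = kind, cfg = cfg, determinism = det,
                 goal_rule = goal_rule, patterns = patterns,
                 seed = as.integer(seed)),
            class = "world_spec")
}

# Draw k designated patterns over a feature subset, well separated: the
# first pattern is uniform, each further pattern is drawn uniformly among
# the unchosen patterns maximizing the minimum Hamming distance to those
# already chosen. Latent causes mark many features at once (a predator
# explains fur, teeth and crest together), so prototype patterns of
# different categories should disagree on many features; purely uniform
# draws frequently produce near-identical prototypes that no model could
# tell apart. Returns 0-based joint pattern indices.
sample_separated_patterns <- function(cards, k) {
  npat <- prod(cards)
  if (k >= npat) return(c(seq_len(npat) - 1L, sample(npat, k - npat,
                                                     replace = TRUE) - 1L))
  all_pat <- mr_decode(seq_len(npat), cards)
  chosen <- sample(npat, 1L)
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(npat), chosen)
    dmin <- vapply(rest, function(i)
      min(vapply(chosen, function(j)
        sum(all_pat[i, ] != all_pat[j, ]), numeric(1))), numeric(1))
    best <- rest[dmin == max(dmin)]
    chosen <- c(chosen, if (length(best) == 1L) best else sample(best, 1L))
  }
  chosen - 1L
}

# One column concentrating 1 - slack on `at` (1-based row), rest uniform.
peaked_col <- function(nr, at, slack) {
  col <- if (nr > 1) rep(slack / (nr - 1), nr) else 1
  col[at] <- 1 - slack
  col
}

peaked_table <- function(nr, at_per_col, slack) {
  vapply(at_per_col, function(at) peaked_col(nr, at, slack), numeric(nr))
}

# Goal table for parents (nonaction..., A), first parent fastest:
# columns ordered with the non-action configuration fastest.
goal_table_from_rule <- function(n_nonact, n_a, preferred, slack) {
  stopifnot(length(preferred) == n_nonact)
  p_attain <- outer(seq_len(n_nonact), 0:(n_a - 1),
                    function(i, a) ifelse(a == preferred[i], 1 - slack, slack))
  rbind(1 - as.vector(p_attain), as.vector(p_attain))
}

draw_preferred <- function(n_states, n_a) {
  if (n_a >= n_states) sample(0:(n_a - 1), n_states)
  else sample(0:(n_a - 1), n_states, replace = TRUE)
}

#' Materialize a ground-truth world
#'
#' @param spec A [world_spec()].
#' @return A validated `gen_model` whose metadata records the spec.
#' @export
make_world <- function(spec) {
  if (!inherits(spec, "world_spec")) stop("spec error: not a world_spec")
  cfg <- spec$cfg
  det <- spec$determinism
  set.seed(spec$seed)
  tables <- list()
  if (spec$kind == "flat") {
    npat <- cfg$n_f^cfg$F
    gname <- paste0("G|", paste(paste0("F", seq_len(cfg$F)), collapse = ","),
                    ",A")
    if (!is.null(spec$goal_rule$preferred)) {
      pref <- spec$goal_rule$preferred
      tables[[gname]] <- goal_table_from_rule(npat, cfg$n_a, pref,
                                              det$goal_slack)
    } else {
      # each (feature combination, action) pair independently attains the
      # goal with high or low probability: the full combination matters,
      # so no coarse latent partition can summarize the rule
      pref <- NULL
      p_attain <- matrix(sample(c(1 - det$goal_slack, det$goal_slack),
                                npat * cfg$n_a, replace = TRUE),
                         npat, cfg$n_a)
      tables[[gname]] <- rbind(1 - as.vector(p_attain), as.vector(p_attain))
    }
    m <- build_m1(cfg, tables)
  } else if (spec$kind == "latent") {
    pats <- spec$patterns$low %||%
      sample_separated_patterns(rep(cfg$n_f, cfg$F), cfg$n_L1)
    npat <- cfg$n_f^cfg$F
    fnames <- paste0("F", seq_len(cfg$F))
    tables[[paste0(paste(fnames, collapse = ","), "|L1")]] <-
      peaked_table(npat, pats + 1L, det$feature_slack)
    pref <- spec$goal_rule$preferred %||% draw_preferred(cfg$n_L1, cfg$n_a)
    tables[["G|L1,A"]] <- goal_table_from_rule(cfg$n_L1, cfg$n_a, pref,
                                               det$goal_slack)
    m <- build_m2(cfg, tables)
  } else {
    fl <- feature_layout(cfg, "split")
    npat_low <- cfg$n_f1^cfg$F1
    npat_high <- cfg$n_f2^cfg$F2 * cfg$n_L1
    # per L2 state: a designated (high-subset pattern, L1 state) pair
    high <- spec$patterns$high %||% {
      hp <- sample_separated_patterns(rep(cfg$n_f2, cfg$F2), cfg$n_L2)
      l1 <- (seq_len(cfg$n_L2) - 1L) %% cfg$n_L1
      hp + cfg$n_f2^cfg$F2 * l1
    }
    low <- spec$patterns$low %||%
      sample_separated_patterns(rep(cfg$n_f1, cfg$F1), cfg$n_L1)
    tables[[paste0(paste(fl$high, collapse = ","), ",L1|L2")]] <-
      peaked_table(npat_high, high + 1L, det$feature_slack)
    tables[[paste0(paste(fl$low, collapse = ","), "|L1")]] <-
      peaked_table(npat_low, low + 1L, det$feature_slack)
    if (spec$kind == "hierarchical") {
      pref <- spec$goal_rule$preferred %||% draw_preferred(cfg$n_L1, cfg$n_a)
      tables[["G|L1,A"]] <- goal_table_from_rule(cfg$n_L1, cfg$n_a, pref,
                                                 det$goal_slack)
      m <- build_m3(cfg, tables)
    } else {
      pref <- spec$goal_rule$preferred %||%
        draw_preferred(cfg$n_L1 * cfg$n_c, cfg$n_a)
      tables[["G|L1,C,A"]] <- goal_table_from_rule(cfg$n_L1 * cfg$n_c,
                                                   cfg$n_a, pref,
                                                   det$goal_slack)
      m <- build_m4(cfg, tables)
    }
  }
  m$metadata$world <- list(kind = spec$kind, seed = spec$seed,
                           determinism = det,
                           preferred_action = as.integer(pref))
  m
}

#' Sample a record collection from a world
#'
#' Ancestral sampling: latents and context first, then features, then
#' epsilon-noised observations; the action comes from the policy (never
#' from the features - actions influence only the goal); the goal from the
#' goal table. The returned data frame contains every variable; the
#' ground-truth columns (features, latents, context) are flagged through
#' `attr(, "latent_cols")`, and `attr(, "observed_vars")` names the columns
#' an agent would actually see (observations, action, goal).
#'
#' @param world A `gen_model` (typically from [make_world()]).
#' @param n Number of records (>= 1).
#' @param action_policy `"uniform_random"` (actions drawn uniformly) or
#'   `"oracle"` (the action maximizing the ground-truth attainment
#'   probability given the record's true latent/context states).
#' @param seed Integer seed.
#' @return A data frame of 0-based states with provenance attributes
#'   (`world_id`, `seed`, `n`).
#' @export
simulate_world <- function(world, n, action_policy = c("uniform_random",
                                                       "oracle"),
                           seed = 1L) {
  action_policy <- match.arg(action_policy)
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  vars <- names(world$cards)
  act <- vars_by_role(world, "action")
  gl <- vars_by_role(world, "goal")
  blocks <- world$blocks
  owner <- vapply(blocks, function(b) b$children[1], character(1))
  is_action <- vapply(blocks, function(b) act %in% b$children, logical(1))
  is_goal <- vapply(blocks, function(b) gl %in% b$children, logical(1))
  # topological order over blocks, action block forced before the goal block
  ord <- integer(0)
  done <- character(0)
  pend <- seq_along(blocks)
  while (length(pend)) {
    ready <- pend[vapply(pend, function(i)
      all(blocks[[i]]$parents %in% done), logical(1))]
    # defer action (policy may need the goal parents) and goal as long as possible
    ready <- ready[order(is_goal[ready], is_action[ready])]
    i <- ready[1]
    ord <- c(ord, i)
    done <- c(done, blocks[[i]]$children)
    pend <- setdiff(pend, i)
  }
  S <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  goal_block <- blocks[[which(is_goal)]]
  for (i in ord) {
    b <- blocks[[i]]
    if (is_action[i] && action_policy == "oracle") {
      # argmax_a p(G = attained | goal parents, a) under the true tables
      pa_other <- setdiff(goal_block$parents, act)
      cards <- world$cards[goal_block$parents]
      strides <- cumprod(c(1, cards[-length(cards)]))
      names(strides) <- goal_block$parents
      base <- if (length(pa_other))
        as.integer(S[, pa_other, drop = FALSE] %*% strides[pa_other]) else
          rep.int(0L, n)
      attained_row <- 2L # goal state 1 (attained), rows are states 0, 1
      pmat <- vapply(0:(world$cards[[act]] - 1L), function(a)
        goal_block$table[attained_row, base + a * strides[[act]] + 1L],
        numeric(n))
      S[, act] <- max.col(pmat, ties.method = "first") - 1L
      next
    }
    cards <- world$cards[b$children]
    nr <- nrow(b$table)
    cidx <- mr_index(S[, b$parents, drop = FALSE], world$cards[b$parents])
    draw <- integer(n)
    for (cc in unique(cidx)) {
      rows <- which(cidx == cc)
      draw[rows] <- sample.int(nr, length(rows), replace = TRUE,
                               prob = b$table[, cc]) - 1L
    }
    S[, b$children] <- mr_decode(draw + 1L, cards)
  }
  out <- as.data.frame(S)
  obs <- c(vars_by_role(world, c("observation", "context_observation")),
           act, gl)
  attr(out, "observed_vars") <- obs
  attr(out, "latent_cols") <- setdiff(vars, obs)
  attr(out, "world_id") <- world$metadata$id %||% "world"
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n") <- as.integer(n)
  out
}

#' Write a record collection to CSV
#'
#' Ground-truth columns are written with a `truth_` prefix so the observed
#' schema is recoverable from the header alone.
#'
#' @param data Data frame from [simulate_world()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  out <- data
  lat <- attr(data, "latent_cols")
  names(out)[names(out) %in% lat] <- paste0("truth_", lat)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a record collection written by [write_dataset()]
#'
#' @param path CSV path.
#' @return Data frame with `latent_cols` / `observed_vars` attributes
#'   restored from the `truth_` prefixes.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path)
  lat <- sub("^truth_", "", names(d)[startsWith(names(d), "truth_")])
  names(d) <- sub("^truth_", "", names(d))
  attr(d, "latent_cols") <- lat
  attr(d, "observed_vars") <- setdiff(names(d), lat)
  d
}
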