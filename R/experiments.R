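#' Structure-recovery and action-inference experiments
#'
#' Seeded simulation experiments demonstrating that evidence-based selection
#' recovers latent, hierarchical and contextual structure exactly when the
#' world has it, and that a contextual world makes the context-appropriate
#' action inferable. Every experiment is fully reproducible from
#' `(experiment_id, params, seed)`.
#'
#' @section Experiments:
#' * `E1_flat_vs_latent` - data from a latent-cause world; candidates: flat
#'   vs single-latent structure; reports the selection frequency of the
#'   latent structure.
#' * `E1_null` - the flat-world control: independent features, goal tied to
#'   the full feature-action combination; same candidates.
#' * `E2_hierarchy` - data from a hierarchical world (the five-feature
#'   animal configuration); candidates: single-latent vs hierarchical.
#' * `E3_context` - the deterministic predator/context world; exact action
#'   inference for every latent-consistent feature pattern in both
#'   contexts.
#' * `E4_action_merging` - two perceptually similar stimulus types plus a
#'   distinct one; candidate category systems with 2 (merged) vs 3 (split)
#'   categories and fixed perceptual mappings; in the same-action condition
#'   evidence merges the similar types into one category, in the
#'   different-action condition it splits them.
#'
#' @param experiment_id One of the ids above.
#' @param params Named list overriding the experiment's default parameters
#'   (`n`, `replicates`, `epsilon`, `method`, EM settings).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return An `experiment_report` list: id, resolved params, seed,
#'   per-replicate table, and summary frequencies.
#' @export
run_experiment <- function(experiment_id = c("E1_flat_vs_latent", "E1_null",
                                             "E2_hierarchy", "E3_context",
                                             "E4_action_merging"),
                           params = list(), seed = 1L) {
  experiment_id <- match.arg(experiment_id)
  fn <- switch(experiment_id,
               E1_flat_vs_latent = experiment_e1,
               E1_null = experiment_e1,
               E2_hierarchy = experiment_e2,
               E3_context = experiment_e3,
               E4_action_merging = experiment_e4)
  rep <- fn(experiment_id, params, as.integer(seed))
  structure(c(list(experiment = experiment_id, seed = as.integer(seed)), rep),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment", x$experiment, "(seed", x$seed, ")\n")
  if (!is.null(x$selection_frequency)) {
    cat("  selection frequency:\n")
    for (nm in names(x$selection_frequency))
      cat(sprintf("    %s: %.2f\n", nm, x$selection_frequency[[nm]]))
  }
  if (!is.null(x$accuracy_by_context)) {
    cat("  action-inference accuracy by context:\n")
    print(x$accuracy_by_context)
  }
  invisible(x)
}

rep_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(2^31 - 2, k)
}

selection_run <- function(worlds, candidates, n, replicates, seeds, method,
                          em = list()) {
  winners <- character(replicates)
  evtabs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    w <- worlds(seeds[r])
    d <- simulate_world(w, n, "uniform_random", seed = seeds[r] %% 2^20 + r)
    rank <- do.call(select_model,
                    c(list(candidates = candidates, data = d,
                           method = method, seed = seeds[r]), em))
    winners[r] <- rank$model[1]
    evtabs[[r]] <- rank[, c("model", "log_evidence")]
  }
  freq <- table(factor(winners, levels = names(candidates))) / replicates
  list(replicate_winners = winners,
       selection_frequency = as.list(freq),
       evidence = evtabs)
}

experiment_e1 <- function(id, params, seed) {
  p <- utils::modifyList(list(n = 500L, replicates = 20L, epsilon = 0.1,
                              method = "bic", F = 4L, n_L1 = 2L,
                              restarts = 2L, max_iter = 150L, tol = 1e-5),
                         params)
  cfg <- structure_config(F = p$F, n_f = 2, n_L1 = p$n_L1,
                          epsilon = p$epsilon)
  kind <- if (id == "E1_null") "flat" else "latent"
  candidates <- list(flat = build_m1(cfg), latent = build_m2(cfg))
  seeds <- rep_seeds(seed, p$replicates)
  res <- selection_run(function(s) make_world(world_spec(kind, cfg, seed = s)),
                       candidates, p$n, p$replicates, seeds, p$method,
                       em = list(restarts = p$restarts,
                                 max_iter = p$max_iter, tol = p$tol))
  c(list(params = p, world_kind = kind), res)
}

experiment_e2 <- function(id, params, seed) {
  p <- utils::modifyList(list(n = 300L, replicates = 20L, epsilon = 0.1,
                              method = "bic", restarts = 2L, max_iter = 150L,
                              tol = 1e-5), params)
  cfg <- structure_config(F1 = 2, F2 = 3, n_f1 = 2, n_f2 = 2, n_L1 = 2,
                          n_L2 = 2, epsilon = p$epsilon)
  candidates <- list(latent = build_m2(cfg, features = "split"),
                     hierarchical = build_m3(cfg))
  seeds <- rep_seeds(seed, p$replicates)
  res <- selection_run(function(s)
    make_world(world_spec("hierarchical", cfg, seed = s)),
    candidates, p$n, p$replicates, seeds, p$method,
    em = list(restarts = p$restarts, max_iter = p$max_iter, tol = p$tol))
  c(list(params = p, world_kind = "hierarchical"), res)
}

# Deterministic contextual world: exact inference must pick the
# context-appropriate action for every latent-consistent feature pattern.
experiment_e3 <- function(id, params, seed) {
  fx <- load_fixture("lion_context")
  world <- make_world(fx$payload)
  cfg <- fx$payload$cfg
  goal_block <- world$blocks[[which(vapply(world$blocks,
                                           function(b) "G" %in% b$children,
                                           logical(1)))]]
  pref <- world$metadata$world$preferred_action
  fl <- feature_layout(cfg, "split")
  rows <- list()
  for (l2 in 0:(cfg$n_L2 - 1L)) {
    # the feature pattern this L2 state generates (deterministic tables)
    hb <- world$blocks[[which(vapply(world$blocks,
                                     function(b) b$tag == "feature_high",
                                     logical(1)))]]
    joint <- which.max(hb$table[, l2 + 1L]) - 1L
    dec <- mr_decode(joint + 1L, c(rep(cfg$n_f2, cfg$F2), cfg$n_L1))[1, ]
    l1 <- dec[length(dec)]
    high_states <- dec[-length(dec)]
    lb <- world$blocks[[which(vapply(world$blocks,
                                     function(b) b$tag == "feature",
                                     logical(1)))]]
    low_states <- mr_decode(which.max(lb$table[, l1 + 1L]),
                            rep(cfg$n_f1, cfg$F1))[1, ]
    obs_states <- setNames(c(low_states, high_states),
                           paste0("O", seq_len(cfg$F1 + cfg$F2)))
    for (cx in 0:(cfg$n_c - 1L)) {
      want <- pref[l1 + cfg$n_L1 * cx + 1L]
      pt <- infer_action(world, c(obs_states, OC = cx))
      rows[[length(rows) + 1L]] <- data.frame(
        L1 = l1, context = cx, best_action = attr(pt, "best"),
        correct_action = want,
        best_prob = max(pt$prob),
        match = attr(pt, "best") == want)
    }
  }
  tab <- do.call(rbind, rows)
  acc <- stats::aggregate(match ~ context, tab, mean)
  c(list(params = list(), results = tab, accuracy_by_context = acc,
         overall_accuracy = mean(tab$match)))
}

# Candidate category systems for E4: latent-cause structures with fixed
# perceptual mappings (the designated stimulus patterns) and 2 vs 3
# categories; priors and the goal table are learned.
e4_candidates <- function(cfg, pat) {
  fnames <- paste0("F", seq_len(cfg$F))
  npat <- cfg$n_f^cfg$F
  fb <- paste0(paste(fnames, collapse = ","), "|L1")
  split_cfg <- structure_config(F = cfg$F, n_f = cfg$n_f, n_L1 = 3,
                                epsilon = cfg$epsilon)
  merged_cfg <- structure_config(F = cfg$F, n_f = cfg$n_f, n_L1 = 2,
                                 epsilon = cfg$epsilon)
  split_tab <- matrix(0, npat, 3)
  split_tab[cbind(pat + 1L, 1:3)] <- 1
  merged_tab <- matrix(0, npat, 2)
  merged_tab[pat[1] + 1L, 1] <- 0.5
  merged_tab[pat[2] + 1L, 1] <- 0.5
  merged_tab[pat[3] + 1L, 2] <- 1
  list(merged = build_m2(merged_cfg, setNames(list(merged_tab), fb)),
       split = build_m2(split_cfg, setNames(list(split_tab), fb)))
}

experiment_e4 <- function(id, params, seed) {
  p <- utils::modifyList(list(n = 200L, replicates = 20L, epsilon = 0.2,
                              method = "bic", restarts = 2L, max_iter = 150L,
                              tol = 1e-6, goal_slack = 0.1), params)
  cfg <- structure_config(F = 4, n_f = 2, n_L1 = 3, epsilon = p$epsilon)
  # stimulus types: two perceptually similar (differ in one feature) and one
  # distinct; joint pattern indices, first feature fastest
  pat <- c(0L, 8L, 7L) # (0,0,0,0), (0,0,0,1), (1,1,1,0)
  rules <- list(same_action = c(0L, 0L, 1L),
                different_action = c(0L, 1L, 0L))
  candidates <- e4_candidates(cfg, pat)
  out <- list()
  for (cond in names(rules)) {
    seeds <- rep_seeds(seed + match(cond, names(rules)), p$replicates)
    worlds <- function(s) make_world(world_spec(
      "latent", cfg,
      determinism = list(feature_slack = 0, goal_slack = p$goal_slack),
      goal_rule = list(preferred = rules[[cond]]),
      patterns = list(low = pat), seed = s))
    res <- selection_run(worlds, candidates, p$n, p$replicates, seeds,
                         p$method,
                         em = list(restarts = p$restarts,
                                   max_iter = p$max_iter, tol = p$tol,
                                   fixed_tags = c("observation", "feature")))
    out[[cond]] <- res
  }
  c(list(params = p),
    list(conditions = out,
         selection_frequency = list(
           same_action_merged = out$same_action$selection_frequency$merged,
           different_action_split = out$different_action$selection_frequency$split)))
}
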