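#' Structure configuration
#'
#' Holds every cardinality symbol used by the four canonical structures and
#' the complexity calculus.
#'
#' @param F Number of features in the flat feature set (structures one/two).
#' @param n_f States per feature in the flat set.
#' @param F1,n_f1 Count of, and states per, features attached to the
#'   low-order latent variable (hierarchical structures).
#' @param F2,n_f2 Count of, and states per, features attached to the
#'   high-order latent variable.
#' @param n_L1 States of the low-order latent L1. In the contextual
#'   comparison this is the *content-only* state count, before any context
#'   folding.
#' @param n_L2 States of the high-order latent L2.
#' @param n_c States of the context variable.
#' @param n_a States of the action variable.
#' @param n_g States of the goal variable (2 by convention: not attained /
#'   attained).
#' @param epsilon Observation noise: probability that an observation
#'   misreports its feature's state (spread uniformly over the wrong
#'   states); must lie in `[0, 0.5]`.
#' @return A `structure_config` object.
#' @export
structure_config <- function(F = 2, n_f = 2, F1 = 2, F2 = 2, n_f1 = 2,
                             n_f2 = 2, n_L1 = 2, n_L2 = 2, n_c = 2, n_a = 2,
                             n_g = 2, epsilon = 0.1) {
  cfg <- list(F = as.integer(F), n_f = as.integer(n_f), F1 = as.integer(F1),
              F2 = as.integer(F2), n_f1 = as.integer(n_f1),
              n_f2 = as.integer(n_f2), n_L1 = as.integer(n_L1),
              n_L2 = as.integer(n_L2), n_c = as.integer(n_c),
              n_a = as.integer(n_a), n_g = as.integer(n_g),
              epsilon = as.numeric(epsilon))
  for (k in c("F", "F1", "F2"))
    if (is.na(cfg[[k]]) || cfg[[k]] < 1L)
      stop("config error: ", k, " must be >= 1")
  for (k in c("n_f", "n_f1", "n_f2", "n_L1", "n_L2", "n_c", "n_a", "n_g"))
    if (is.na(cfg[[k]]) || cfg[[k]] < 2L)
      stop("config error: ", k,
           " must be >= 2 (a categorical variable needs at least two levels)")
  if (is.na(cfg$epsilon) || cfg$epsilon < 0 || cfg$epsilon > 0.5)
    stop("config error: epsilon must lie in [0, 0.5]")
  structure(cfg, class = "structure_config")
}

#' @export
print.structure_config <- function(x, ...) {
  cat("structure_config:",
      sprintf("F=%d n_f=%d | F1=%d n_f1=%d F2=%d n_f2=%d | n_L1=%d n_L2=%d n_c=%d n_a=%d n_g=%d | epsilon=%.3g",
              x$F, x$n_f, x$F1, x$n_f1, x$F2, x$n_f2, x$n_L1, x$n_L2, x$n_c,
              x$n_a, x$n_g, x$epsilon), "\n")
  invisible(x)
}

#' Read a structure configuration from a YAML or JSON file
#'
#' @param path File with any subset of the [structure_config()] fields;
#'   unspecified fields keep their defaults.
#' @return A `structure_config`.
#' @export
read_structure_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- vals[names(vals) %in% names(formals(structure_config))]
  do.call(structure_config, vals)
}

# Symmetric confusion table: correct state with probability 1 - epsilon,
# remaining mass spread uniformly over the other states.
noise_table <- function(card, epsilon) {
  t <- matrix(epsilon / (card - 1), card, card)
  diag(t) <- 1 - epsilon
  t
}

uniform_table <- function(nrow, ncol = 1L) {
  matrix(1 / nrow, nrow, ncol)
}

# Apply user table overrides (a named list keyed by block name) and check.
apply_tables <- function(blocks, tables) {
  if (is.null(tables)) return(blocks)
  unknown <- setdiff(names(tables), vapply(blocks, `[[`, "", "name"))
  if (length(unknown))
    stop("table override(s) for unknown block(s): ",
         paste(unknown, collapse = ", "))
  lapply(blocks, function(b) {
    if (!is.null(tables[[b$name]])) {
      tab <- tables[[b$name]]
      if (is.null(dim(tab))) tab <- matrix(as.numeric(tab), nrow(b$table))
      if (!all(dim(tab) == dim(b$table)))
        stop("override for block '", b$name, "' has wrong shape")
      b$table <- unname(tab)
    }
    b
  })
}

# Feature name/cardinality layout. "flat": F features of n_f states.
# "split": F1 features of n_f1 states attached to L1, then F2 features of
# n_f2 states attached to L2.
feature_layout <- function(cfg, features) {
  if (features == "flat") {
    list(names = paste0("F", seq_len(cfg$F)), cards = rep(cfg$n_f, cfg$F),
         low = paste0("F", seq_len(cfg$F)), high = character(0))
  } else {
    n <- cfg$F1 + cfg$F2
    nms <- paste0("F", seq_len(n))
    list(names = nms, cards = c(rep(cfg$n_f1, cfg$F1), rep(cfg$n_f2, cfg$F2)),
         low = nms[seq_len(cfg$F1)], high = nms[cfg$F1 + seq_len(cfg$F2)])
  }
}

obs_blocks <- function(fl, cfg) {
  lapply(seq_along(fl$names), function(i)
    gm_block(paste0("O", i), fl$names[i], noise_table(fl$cards[i], cfg$epsilon),
             tag = "observation"))
}

obs_vars <- function(fl) {
  mapply(function(i, card) gm_variable(paste0("O", i), "observation", card),
         seq_along(fl$names), fl$cards, SIMPLIFY = FALSE)
}

ag_vars <- function(cfg) {
  list(gm_variable("A", "action", cfg$n_a), gm_variable("G", "goal", cfg$n_g))
}

#' Build structure one: features map directly to the goal
#'
#' Flat structure: independent feature priors, one noisy observation per
#' feature, an action prior, and a single joint goal table conditioned on
#' every feature and the action. No latent variables intervene.
#'
#' @param cfg A [structure_config()].
#' @param tables Optional named list of table overrides keyed by block name
#'   (see `vapply(model$blocks, \(b) b$name, "")`); defaults are uniform
#'   priors and epsilon-noise observation tables.
#' @return A validated `gen_model`.
#' @export
build_m1 <- function(cfg, tables = NULL) {
  fl <- feature_layout(cfg, "flat")
  vars <- c(lapply(seq_along(fl$names), function(i)
              gm_variable(fl$names[i], "feature", fl$cards[i])),
            obs_vars(fl), ag_vars(cfg))
  blocks <- c(
    lapply(seq_along(fl$names), function(i)
      gm_block(fl$names[i], table = uniform_table(fl$cards[i]),
               tag = "feature_prior")),
    obs_blocks(fl, cfg),
    list(gm_block("A", table = uniform_table(cfg$n_a), tag = "action_prior"),
         gm_block("G", c(fl$names, "A"),
                  uniform_table(cfg$n_g, prod(fl$cards) * cfg$n_a),
                  tag = "goal")))
  m <- gen_model(vars, apply_tables(blocks, tables),
                 metadata = list(id = "m1", structure = "flat", cfg = unclass(cfg)))
  stop_if_invalid(m, "build_m1")
}

#' Build structure two: a single latent cause generates all features
#'
#' The latent variable L1 generates the features (one joint table over the
#' full feature pattern per latent state) and projects, with the action, to
#' the goal. Only the latent - not the individual features - causes the goal.
#'
#' @inheritParams build_m1
#' @param features `"flat"` (F features of n_f states) or `"split"` (the
#'   F1 + F2 layout shared with structures three and four, so that competing
#'   structures have identical observation schemas).
#' @return A validated `gen_model`.
#' @export
build_m2 <- function(cfg, tables = NULL, features = c("flat", "split")) {
  features <- match.arg(features)
  fl <- feature_layout(cfg, features)
  vars <- c(list(gm_variable("L1", "latent_low", cfg$n_L1)),
            lapply(seq_along(fl$names), function(i)
              gm_variable(fl$names[i], "feature", fl$cards[i])),
            obs_vars(fl), ag_vars(cfg))
  blocks <- c(
    list(gm_block("L1", table = uniform_table(cfg$n_L1), tag = "latent_prior"),
         gm_block(fl$names, "L1",
                  uniform_table(prod(fl$cards), cfg$n_L1), tag = "feature")),
    obs_blocks(fl, cfg),
    list(gm_block("A", table = uniform_table(cfg$n_a), tag = "action_prior"),
         gm_block("G", c("L1", "A"),
                  uniform_table(cfg$n_g, cfg$n_L1 * cfg$n_a), tag = "goal")))
  m <- gen_model(vars, apply_tables(blocks, tables),
                 metadata = list(id = "m2", structure = "latent",
                                 features = features, cfg = unclass(cfg)))
  stop_if_invalid(m, "build_m2")
}

#' Build structure three: hierarchically organized latent causes
#'
#' A high-order latent L2 jointly generates the high-order feature subset and
#' the low-order latent L1 (one joint table per L2 state); L1 generates the
#' low-order feature subset and projects, with the action, to the goal. The
#' joint grouping of the high-order features with L1 under L2 is the
#' counting convention adopted throughout the complexity calculus.
#'
#' @inheritParams build_m1
#' @return A validated `gen_model`.
#' @export
build_m3 <- function(cfg, tables = NULL) {
  fl <- feature_layout(cfg, "split")
  vars <- c(list(gm_variable("L2", "latent_high", cfg$n_L2),
                 gm_variable("L1", "latent_low", cfg$n_L1)),
            lapply(seq_along(fl$names), function(i)
              gm_variable(fl$names[i], "feature", fl$cards[i])),
            obs_vars(fl), ag_vars(cfg))
  high_cards <- c(rep(cfg$n_f2, cfg$F2), cfg$n_L1)
  blocks <- c(
    list(gm_block("L2", table = uniform_table(cfg$n_L2), tag = "latent_prior"),
         gm_block(c(fl$high, "L1"), "L2",
                  uniform_table(prod(high_cards), cfg$n_L2),
                  tag = "feature_high"),
         gm_block(fl$low, "L1",
                  uniform_table(cfg$n_f1^cfg$F1, cfg$n_L1), tag = "feature")),
    obs_blocks(fl, cfg),
    list(gm_block("A", table = uniform_table(cfg$n_a), tag = "action_prior"),
         gm_block("G", c("L1", "A"),
                  uniform_table(cfg$n_g, cfg$n_L1 * cfg$n_a), tag = "goal")))
  m <- gen_model(vars, apply_tables(blocks, tables),
                 metadata = list(id = "m3", structure = "hierarchical",
                                 cfg = unclass(cfg)))
  stop_if_invalid(m, "build_m3")
}

#' Build structure four: hierarchy plus an explicit context variable
#'
#' As [build_m3()], with a context variable C (own prior and noisy
#' observation OC) added as a third parent of the goal: the mapping from
#' latent category and action to goal attainment is gated by context.
#'
#' @inheritParams build_m1
#' @return A validated `gen_model`.
#' @export
build_m4 <- function(cfg, tables = NULL) {
  base <- build_m3(cfg)
  vars <- c(base$variables,
            list(gm_variable("C", "context", cfg$n_c),
                 gm_variable("OC", "context_observation", cfg$n_c)))
  blocks <- base$blocks
  goal_i <- which(vapply(blocks, function(b) b$tag == "goal", logical(1)))
  blocks[[goal_i]] <- gm_block("G", c("L1", "C", "A"),
                               uniform_table(cfg$n_g,
                                             cfg$n_L1 * cfg$n_c * cfg$n_a),
                               tag = "goal")
  blocks <- c(blocks,
              list(gm_block("C", table = uniform_table(cfg$n_c),
                            tag = "context_prior"),
                   gm_block("OC", "C", noise_table(cfg$n_c, cfg$epsilon),
                            tag = "observation")))
  m <- gen_model(vars, apply_tables(blocks, tables),
                 metadata = list(id = "m4", structure = "contextual",
                                 cfg = unclass(cfg)))
  stop_if_invalid(m, "build_m4")
}

#' Build structure three with context folded into the latent variable
#'
#' The context-free alternative to structure four: a single latent variable
#' whose state space is the product of content states (`n_L1`) and context
#' states (`n_c`), jointly generating the low-order feature subset and the
#' goal given latent and action (one joint feature-and-goal table). This is
#' the declared block grouping under which the folded structure's
#' characteristic cells equal `n_f1^F1 * n_L1 * n_c * n_g * n_a`.
#'
#' @inheritParams build_m1
#' @return A validated `gen_model`.
#' @export
build_m3_folded <- function(cfg, tables = NULL) {
  n_fold <- cfg$n_L1 * cfg$n_c
  fnames <- paste0("F", seq_len(cfg$F1))
  vars <- c(list(gm_variable("L1", "latent_low", n_fold)),
            lapply(fnames, function(nm) gm_variable(nm, "feature", cfg$n_f1)),
            lapply(seq_len(cfg$F1), function(i)
              gm_variable(paste0("O", i), "observation", cfg$n_f1)),
            ag_vars(cfg))
  blocks <- c(
    list(gm_block("L1", table = uniform_table(n_fold), tag = "latent_prior"),
         gm_block(c(fnames, "G"), c("L1", "A"),
                  uniform_table(cfg$n_f1^cfg$F1 * cfg$n_g, n_fold * cfg$n_a),
                  tag = "feature_goal")),
    lapply(seq_len(cfg$F1), function(i)
      gm_block(paste0("O", i), fnames[i], noise_table(cfg$n_f1, cfg$epsilon),
               tag = "observation")),
    list(gm_block("A", table = uniform_table(cfg$n_a), tag = "action_prior")))
  m <- gen_model(vars, apply_tables(blocks, tables),
                 metadata = list(id = "m3_folded", structure = "latent_folded",
                                 cfg = unclass(cfg)))
  stop_if_invalid(m, "build_m3_folded")
}
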