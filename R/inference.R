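#' Exact planning-as-inference
#'
#' Decisions are cast as inference: the goal variable is clamped to its
#' attained state alongside the sensory observations, and the posterior over
#' the action variable is computed exactly by summation over every
#' unclamped variable. Categorization is the same machinery with the latent
#' variables as the query and the goal left unclamped.
#'
#' @name inference
NULL

check_evidence <- function(model, clamped, allow_any) {
  if (length(clamped) == 0L) return(invisible())
  nms <- names(clamped)
  unknown <- setdiff(nms, names(model$cards))
  if (length(unknown))
    stop("clamped variable(s) not in model: ", paste(unknown, collapse = ", "))
  s <- as.integer(clamped)
  bad <- s < 0L | s >= model$cards[nms]
  if (any(bad))
    stop("clamped state out of range for ", paste(nms[bad], collapse = ", "))
  if (!allow_any) {
    ok_roles <- c("observation", "context_observation", "goal")
    notobs <- nms[!model$roles[nms] %in% ok_roles]
    if (length(notobs))
      stop("only observation-role variables and the goal may be clamped ",
           "(offending: ", paste(notobs, collapse = ", "),
           "); use allow_any = TRUE for diagnostics")
  }
  invisible()
}

#' Exact posterior over query variables
#'
#' Computes the conditional distribution of the query variables given the
#' clamped evidence by enumerating every joint configuration of the
#' unclamped variables and summing out the non-query ones.
#'
#' @param model A valid `gen_model`.
#' @param clamped Named integer vector of clamped 0-based states (may be
#'   empty). By convention only observation-role variables and the goal are
#'   clamped; set `allow_any = TRUE` to clamp anything (diagnostics).
#' @param query Character vector of variable names to keep.
#' @param budget Maximum number of joint states of the unclamped variables
#'   that will be enumerated (default `1e7`).
#' @param allow_any Permit clamping of non-observation variables.
#' @return A `posterior_table`: a data frame with one 0-based state column
#'   per query variable and a `prob` column summing to one; attributes carry
#'   the log normalizing constant (the log marginal likelihood of the
#'   evidence).
#' @export
posterior <- function(model, clamped = integer(0), query, budget = 1e7,
                      allow_any = FALSE) {
  check_evidence(model, clamped, allow_any)
  vars <- names(model$cards)
  if (!all(query %in% vars))
    stop("query variable(s) not in model: ",
         paste(setdiff(query, vars), collapse = ", "))
  free <- setdiff(vars, names(clamped))
  size <- prod(model$cards[free])
  if (size > budget)
    stop("budget error: enumerating ", format(size, big.mark = ","),
         " joint states of {",
         paste(sprintf("%s[%d]", free, model$cards[free]), collapse = ", "),
         "} exceeds the budget of ", format(budget, big.mark = ","))
  M <- matrix(0L, size, length(vars), dimnames = list(NULL, vars))
  if (length(free)) M[, free] <- mr_grid(model$cards[free])
  for (v in names(clamped)) M[, v] <- as.integer(clamped[[v]])
  lp <- log_joint_matrix(model, M)
  mx <- max(lp)
  if (!is.finite(mx))
    stop("impossible-evidence error: the clamped evidence has zero marginal ",
         "likelihood under the model")
  w <- exp(lp - mx)
  qcards <- model$cards[query]
  qidx <- mr_index(M[, query, drop = FALSE], qcards)
  p <- numeric(prod(qcards))
  agg <- rowsum(w, qidx)
  p[as.integer(rownames(agg))] <- agg
  z <- sum(p)
  tab <- as.data.frame(mr_grid(qcards))
  names(tab) <- query
  tab$prob <- p / z
  structure(tab, class = c("posterior_table", "data.frame"),
            query = query, log_normalizer = mx + log(z))
}

#' @export
print.posterior_table <- function(x, ...) {
  cat("Posterior over {", paste(attr(x, "query"), collapse = ", "), "}\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Infer the action posterior given observations and a clamped goal
#'
#' Clamps the goal variable to `goal_state` (default: attained, state index
#' 1) in addition to the supplied observations, and returns the exact
#' posterior over the action variable. The maximum a posteriori action is
#' attached as attribute `best` (lowest state index on ties, within 1e-12)
#' together with the full tie set in attribute `ties`.
#'
#' @param model A `gen_model` containing action- and goal-role variables.
#' @param observations Named integer vector of clamped observation states
#'   (no goal entry).
#' @param goal_state 0-based goal state to clamp (1 = attained by
#'   convention).
#' @inheritParams posterior
#' @return A `posterior_table` over the action variable.
#' @export
infer_action <- function(model, observations = integer(0), goal_state = 1L,
                         budget = 1e7) {
  act <- vars_by_role(model, "action")
  gl <- vars_by_role(model, "goal")
  if (length(act) != 1L || length(gl) != 1L)
    stop("model must contain exactly one action and one goal variable")
  if (gl %in% names(observations))
    stop("do not clamp the goal through `observations`; use `goal_state`")
  clamped <- c(observations, setNames(as.integer(goal_state), gl))
  pt <- posterior(model, clamped, act, budget = budget)
  mx <- max(pt$prob)
  ties <- pt[[act]][pt$prob >= mx - 1e-12]
  attr(pt, "best") <- min(ties)
  attr(pt, "ties") <- ties
  pt
}

#' Infer the joint posterior over latent variables (categorization)
#'
#' The perception-only query: the joint posterior over every latent-role
#' variable given the observations, with the goal left unclamped (set
#' `clamp_goal = TRUE` to condition on goal attainment as well).
#'
#' @param model A `gen_model` with at least one latent variable.
#' @param observations Named integer vector of clamped observation states.
#' @param clamp_goal Also clamp the goal to its attained state (index 1).
#' @inheritParams posterior
#' @return A `posterior_table` over the latent variables.
#' @export
infer_category <- function(model, observations = integer(0),
                           clamp_goal = FALSE, budget = 1e7) {
  lat <- vars_by_role(model, c("latent_low", "latent_high"))
  if (length(lat) == 0L) stop("model has no latent variables")
  clamped <- observations
  if (clamp_goal) {
    gl <- vars_by_role(model, "goal")
    clamped <- c(clamped, setNames(1L, gl))
  }
  posterior(model, clamped, lat, budget = budget)
}
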