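#' Discrete generative models with block-structured conditional tables
#'
#' A generative model is a directed acyclic graph of categorical variables.
#' Conditional probability tables are organized in *blocks*: a block owns an
#' ordered group of child variables (counted jointly) and an ordered, possibly
#' empty, list of parent variables. The table of a block is a matrix whose
#' rows index joint child states and whose columns index joint parent
#' configurations, both in mixed radix with the first-listed variable varying
#' fastest. Each column is a probability distribution over the joint child
#' states. This joint-child grouping is deliberate: the complexity calculus
#' counts every cell of a block, so the grouping determines the parameter
#' count attributed to a dependency.
#'
#' @name gm_core
NULL

VARIABLE_ROLES <- c("feature", "observation", "latent_low", "latent_high",
                    "context", "context_observation", "action", "goal")

#' Declare a categorical model variable
#'
#' @param name Variable name, unique within a model.
#' @param role One of `"feature"`, `"observation"`, `"latent_low"`,
#'   `"latent_high"`, `"context"`, `"context_observation"`, `"action"`,
#'   `"goal"`.
#' @param cardinality Number of states; must be at least 2 (a categorical
#'   variable with fewer levels carries no information).
#' @return A `gm_variable` object.
#' @export
gm_variable <- function(name, role, cardinality) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("variable name must be a non-empty string")
  role <- match.arg(role, VARIABLE_ROLES)
  cardinality <- as.integer(cardinality)
  if (is.na(cardinality) || cardinality < 2L)
    stop("cardinality must be an integer >= 2 (got ", cardinality,
         " for variable '", name, "')")
  structure(list(name = name, role = role, cardinality = cardinality),
            class = "gm_variable")
}

#' Declare a conditional-probability block
#'
#' @param children Ordered character vector of child variable names; their
#'   joint distribution given the parents is one table.
#' @param parents Ordered character vector of parent names (empty = prior).
#' @param table Numeric matrix (or vector for a prior block): rows = joint
#'   child states, columns = joint parent configurations, first-listed
#'   variable fastest on both axes. Columns must sum to one.
#' @param tag Free label used to group blocks (e.g. `"observation"`,
#'   `"feature"`, `"goal"`); the complexity calculus selects blocks by tag.
#' @param name Optional block name; defaults to `"children|parents"`.
#' @return A `gm_block` object.
#' @export
gm_block <- function(children, parents = character(0), table, tag = "",
                     name = NULL) {
  children <- as.character(children)
  parents <- as.character(parents)
  if (length(children) == 0L) stop("a block needs at least one child")
  if (is.null(dim(table))) table <- matrix(as.numeric(table), ncol = 1L)
  name <- name %||% paste0(paste(children, collapse = ","),
                           if (length(parents)) "|" else "",
                           paste(parents, collapse = ","))
  structure(list(children = children, parents = parents,
                 table = unname(table), tag = tag, name = name),
            class = "gm_block")
}

#' Assemble a generative model
#'
#' Structural defects (bad normalization, cycles, coverage gaps) are *not*
#' raised here; inspect them with [validate_model()]. This allows defective
#' models to be constructed and examined.
#'
#' @param variables List of [gm_variable()] objects.
#' @param blocks List of [gm_block()] objects covering every variable as a
#'   child exactly once.
#' @param metadata Free-form named list (model id, config used, labels).
#' @return A `gen_model` object.
#' @export
gen_model <- function(variables, blocks, metadata = list()) {
  nms <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  cards <- vapply(variables, function(v) v$cardinality, integer(1))
  names(cards) <- nms
  roles <- vapply(variables, function(v) v$role, character(1))
  names(roles) <- nms
  names(variables) <- nms
  structure(list(variables = variables, blocks = blocks, cards = cards,
                 roles = roles, metadata = metadata),
            class = "gen_model")
}

#' @export
print.gen_model <- function(x, ...) {
  cat("Generative model", if (!is.null(x$metadata$id)) paste0("'", x$metadata$id, "'"),
      "\n  variables:", length(x$variables),
      paste0("(", paste(sprintf("%s[%d]", names(x$cards), x$cards), collapse = " "), ")"),
      "\n  blocks:", length(x$blocks), "with",
      count_block_cells(x, seq_along(x$blocks)), "table cells\n")
  invisible(x)
}

vars_by_role <- function(model, role) {
  names(model$roles)[model$roles %in% role]
}

block_child_cards <- function(model, block) model$cards[block$children]
block_parent_cards <- function(model, block) model$cards[block$parents]

#' Validate a generative model
#'
#' Checks every structural invariant: each variable is covered as a child in
#' exactly one block, block variables exist, tables have the implied shape,
#' entries lie in `[0, 1]`, every column sums to one within `1e-12`, and the
#' child-to-parent relation is acyclic.
#'
#' @param model A `gen_model`.
#' @return Character vector of violation descriptions; empty iff the model is
#'   valid. Violations name the block or variable at fault.
#' @export
validate_model <- function(model) {
  out <- character(0)
  vars <- names(model$cards)
  covered <- unlist(lapply(model$blocks, function(b) b$children))
  for (v in vars[!vars %in% covered])
    out <- c(out, sprintf("variable '%s' is not a child of any block", v))
  for (v in unique(covered[duplicated(covered)]))
    out <- c(out, sprintf("variable '%s' is a child of more than one block", v))
  for (b in model$blocks) {
    unknown <- setdiff(c(b$children, b$parents), vars)
    if (length(unknown)) {
      out <- c(out, sprintf("block '%s' refers to unknown variable(s): %s",
                            b$name, paste(unknown, collapse = ", ")))
      next
    }
    nr <- prod(model$cards[b$children])
    nc <- prod(c(1, model$cards[b$parents]))
    if (nrow(b$table) != nr || ncol(b$table) != nc) {
      out <- c(out, sprintf(
        "block '%s' table is %d x %d but cardinalities imply %d x %d",
        b$name, nrow(b$table), ncol(b$table), nr, nc))
      next
    }
    if (any(b$table < 0 | b$table > 1))
      out <- c(out, sprintf("block '%s' has entries outside [0, 1]", b$name))
    bad <- which(abs(colSums(b$table) - 1) > 1e-12)
    for (j in bad)
      out <- c(out, sprintf(
        "block '%s' column %d sums to %.12g, not 1", b$name, j,
        colSums(b$table)[j]))
  }
  # acyclicity of the child -> parent relation (edges parent -> child)
  if (!length(out) || !any(grepl("unknown variable", out))) {
    parent_of <- lapply(model$blocks, function(b) b$parents)
    names(parent_of) <- vapply(model$blocks, function(b) b$children[1], character(1))
    # map each variable to the parents of its owning block
    pa_map <- list()
    for (b in model$blocks) for (ch in b$children) pa_map[[ch]] <- b$parents
    state <- setNames(rep(0L, length(vars)), vars) # 0 new, 1 visiting, 2 done
    cyc <- FALSE
    visit <- function(v) {
      if (state[[v]] == 1L) { cyc <<- TRUE; return() }
      if (state[[v]] == 2L) return()
      state[[v]] <<- 1L
      for (p in pa_map[[v]] %||% character(0)) visit(p)
      state[[v]] <<- 2L
    }
    for (v in vars) { if (cyc) break; visit(v) }
    if (cyc) out <- c(out, "child-parent structure contains a cycle")
  }
  out
}

stop_if_invalid <- function(model, context) {
  v <- validate_model(model)
  if (length(v))
    stop(context, " produced an invalid model:\n  ", paste(v, collapse = "\n  "))
  model
}

# Log-probability of each row of an assignment matrix (columns named by
# variable, 0-based states). Workhorse for enumeration-based inference.
log_joint_matrix <- function(model, M) {
  lp <- numeric(nrow(M))
  for (b in model$blocks) {
    r <- mr_index(M[, b$children, drop = FALSE], model$cards[b$children])
    cc <- mr_index(M[, b$parents, drop = FALSE], model$cards[b$parents])
    lp <- lp + log(b$table)[r + (cc - 1L) * nrow(b$table)]
  }
  lp
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorized joint: the product over blocks of the table cell
#' selected by the assignment. Computed in log space internally.
#'
#' @param model A valid `gen_model`.
#' @param assignment Named integer vector mapping every variable to a 0-based
#'   state index.
#' @return Probability in `[0, 1]`.
#' @export
joint_probability <- function(model, assignment) {
  vars <- names(model$cards)
  missing <- setdiff(vars, names(assignment))
  if (length(missing))
    stop("incomplete assignment: missing variable(s) ",
         paste(missing, collapse = ", "))
  s <- as.integer(assignment[vars])
  if (any(s < 0L | s >= model$cards))
    stop("assignment state out of range for variable(s) ",
         paste(vars[s < 0L | s >= model$cards], collapse = ", "))
  M <- matrix(s, 1L, dimnames = list(NULL, vars))
  exp(log_joint_matrix(model, M))
}

#' Count conditional-table cells over selected blocks
#'
#' The total number of table cells of the selected blocks, i.e. the product
#' of child cardinalities times the product of parent cardinalities, summed
#' over blocks. This raw cell count is the complexity currency of the
#' characteristic-parameter calculus (no normalization constraints are
#' subtracted) and serves as the brute-force oracle for its closed forms.
#'
#' @param model A `gen_model`.
#' @param block_selector Integer vector of block indices (default all).
#' @return Integer cell count (0 for an empty selector).
#' @export
count_block_cells <- function(model, block_selector = seq_along(model$blocks)) {
  if (length(block_selector) == 0L) return(0L)
  block_selector <- as.integer(block_selector)
  if (any(is.na(block_selector)) || any(block_selector < 1L) ||
      any(block_selector > length(model$blocks)))
    stop("invalid block selector: indices must be in 1..", length(model$blocks))
  sum(vapply(model$blocks[block_selector],
             function(b) length(b$table), numeric(1)))
}

#' Sum of table cells over blocks carrying given tags
#'
#' @param model A `gen_model`.
#' @param tags Character vector of block tags to include.
#' @return Integer cell count.
#' @export
characteristic_cells <- function(model, tags) {
  idx <- which(vapply(model$blocks, function(b) b$tag %in% tags, logical(1)))
  count_block_cells(model, idx)
}

#' Write a generative model to a JSON file
#'
#' Tables are stored as flat vectors in child-major order (rows first, i.e.
#' the first-listed child varies fastest, then parent configurations with the
#' first-listed parent fastest), alongside the declared row/column counts.
#'
#' @param model A `gen_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    variables = lapply(model$variables, function(v)
      list(name = v$name, role = v$role, cardinality = v$cardinality)),
    blocks = lapply(model$blocks, function(b)
      list(name = b$name, tag = b$tag, children = as.list(b$children),
           parents = as.list(b$parents), nrow = nrow(b$table),
           ncol = ncol(b$table), index_order = "child-major",
           table = as.vector(b$table))),
    metadata = model$metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

model_from_list <- function(doc) {
  vars <- lapply(doc$variables, function(v)
    gm_variable(v$name, v$role, v$cardinality))
  blocks <- lapply(doc$blocks, function(b)
    gm_block(unlist(b$children), unlist(b$parents) %||% character(0),
             matrix(as.numeric(unlist(b$table)), b$nrow, b$ncol),
             tag = b$tag %||% "", name = b$name))
  md <- doc$metadata %||% list()
  gen_model(vars, blocks, md)
}

#' Read a generative model from a JSON file
#'
#' @param path File written by [write_model()].
#' @return A `gen_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  model_from_list(doc)
}
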