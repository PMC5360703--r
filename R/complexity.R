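#' Characteristic-parameter complexity calculus
#'
#' Competing structures are compared by their *characteristic parameters*:
#' the conditional-table cells of the blocks that differ between the two
#' structures (blocks common to both, such as the feature-observation
#' mappings, are excluded). Counts are raw cell counts - no normalization
#' constraints are subtracted - because that is the convention under which
#' the closed forms below equal brute-force cell enumeration on the
#' constructed models ([count_block_cells()]).
#'
#' @name complexity
NULL

comparison_result <- function(count_a, count_b, threshold, preferred,
                              label_a, label_b, threshold_on = NA_character_) {
  structure(list(count_a = count_a, count_b = count_b, threshold = threshold,
                 preferred = preferred, label_a = label_a, label_b = label_b,
                 threshold_on = threshold_on),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %g cells  vs  %s: %g cells  ->  preferred: %s\n",
              x$label_a, x$count_a, x$label_b, x$count_b,
              switch(x$preferred, a = x$label_a, b = x$label_b, "tie")))
  if (!is.na(x$threshold))
    cat(sprintf("  threshold on %s: %.6g\n", x$threshold_on, x$threshold))
  invisible(x)
}

prefer <- function(a, b) if (a < b) "a" else if (b < a) "b" else "tie"

#' Compare the flat structure against the single-latent structure
#'
#' Characteristic cells: the flat structure's joint goal table,
#' `n_f^F * n_a * n_g`, against the latent structure's feature table plus
#' goal table, `n_f^F * n_L1 + n_L1 * n_a * n_g`. The latent structure is
#' cheaper exactly when `n_L1` is below the threshold
#' `n_f^F * n_a * n_g / (n_f^F + n_a * n_g)`; at minimal cardinalities the
#' threshold equals 2, so a two-state latent can never win there.
#'
#' @param cfg A [structure_config()].
#' @return A `comparison_result` with the threshold expressed as a bound on
#'   `n_L1`.
#' @export
compare_flat_vs_latent <- function(cfg) {
  if (!inherits(cfg, "structure_config")) stop("config error: not a structure_config")
  npat <- cfg$n_f^cfg$F
  a <- npat * cfg$n_a * cfg$n_g
  b <- npat * cfg$n_L1 + cfg$n_L1 * cfg$n_a * cfg$n_g
  thr <- npat * cfg$n_a * cfg$n_g / (npat + cfg$n_a * cfg$n_g)
  comparison_result(a, b, thr, prefer(a, b), "flat", "latent", "n_L1")
}

#' Compare the single-latent structure against the hierarchical structure
#'
#' Both structures share the observation mappings and the latent-action-goal
#' table, so the characteristic cells are the feature-generating blocks
#' only: `n_f1^F1 * n_f2^F2 * n_L1` for the single latent (one joint table
#' over the full feature pattern) against
#' `n_f2^F2 * n_L1 * n_L2 + n_f1^F1 * n_L1` for the hierarchy (the
#' high-order latent jointly generating the high-order feature subset and
#' L1, plus L1 generating the low-order subset). The hierarchy is cheaper
#' when `n_L2` is below `n_f1^F1 * (n_f2^F2 - 1) / n_f2^F2` (the shared
#' `n_L1` factor cancels). At minimal cardinalities this bound evaluates to
#' 3; with `F2 = 3` it evaluates to 3.5.
#'
#' @param cfg A [structure_config()].
#' @return A `comparison_result` with the threshold expressed as a bound on
#'   `n_L2`.
#' @export
compare_latent_vs_hierarchical <- function(cfg) {
  if (!inherits(cfg, "structure_config")) stop("config error: not a structure_config")
  p1 <- cfg$n_f1^cfg$F1
  p2 <- cfg$n_f2^cfg$F2
  a <- p1 * p2 * cfg$n_L1
  b <- p2 * cfg$n_L1 * cfg$n_L2 + p1 * cfg$n_L1
  thr <- p1 * (p2 - 1) / p2
  comparison_result(a, b, thr, prefer(a, b), "latent", "hierarchical", "n_L2")
}

#' Compare context folded into the latent against an explicit context variable
#'
#' If context must be represented without a context variable, every latent
#' content state is duplicated per context (`n_L1` content states become
#' `n_L1 * n_c` latent states) and features and goal are counted as one
#' joint block given latent and action:
#' `n_f1^F1 * n_L1 * n_c * n_g * n_a` cells. The explicit-context structure
#' factorizes this into features given latent plus goal given latent,
#' context and action: `n_f1^F1 * n_L1 + n_L1 * n_c * n_g * n_a` cells.
#' At minimal cardinalities: 64 against 24. No threshold accompanies this
#' comparison; the factorized form is never more expensive.
#'
#' @param cfg A [structure_config()]; `n_L1` is read as the content-only
#'   state count.
#' @return A `comparison_result` (threshold `NA`).
#' @export
compare_hierarchical_vs_contextual <- function(cfg) {
  if (!inherits(cfg, "structure_config")) stop("config error: not a structure_config")
  p1 <- cfg$n_f1^cfg$F1
  a <- p1 * cfg$n_L1 * cfg$n_c * cfg$n_g * cfg$n_a
  b <- p1 * cfg$n_L1 + cfg$n_L1 * cfg$n_c * cfg$n_g * cfg$n_a
  comparison_result(a, b, NA_real_, prefer(a, b), "context_folded",
                    "explicit_context")
}

# Characteristic block tags per comparison, used to verify closed forms
# against cell enumeration on built models.
characteristic_tags <- function() {
  list(
    flat_latent = list(a = list(build = build_m1, tags = "goal"),
                       b = list(build = build_m2,
                                tags = c("feature", "goal"))),
    latent_hier = list(a = list(build = function(cfg)
                                  build_m2(cfg, features = "split"),
                                tags = "feature"),
                       b = list(build = build_m3,
                                tags = c("feature_high", "feature"))),
    hier_context = list(a = list(build = build_m3_folded,
                                 tags = "feature_goal"),
                        b = list(build = build_m4,
                                 tags = c("feature", "goal"))))
}
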