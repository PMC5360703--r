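#' Frozen worked-example assets
#'
#' Fixtures are JSON data files shipped under `inst/extdata/fixtures` so
#' that they can be reused outside R. Each fixture carries a payload (a
#' structure configuration, a world specification or a full model) and a
#' set of documented oracle values with their provenance (`reference-count`
#' for published counts, `hand-checked` for values verifiable by hand,
#' `derived` for values computed by the stated independent procedure).
#'
#' Registered fixtures: `"minimal"` (all cardinalities at their minimum,
#' two flat features), `"animal_hierarchy"` (the five-binary-feature animal
#' configuration: two low-order and three high-order features, two-state
#' latents at both levels), `"lion_context"` (the deterministic
#' predator/context world: avoid a predator in the wild, approach anything
#' at the zoo), `"chain3"` (a hand-checked three-variable chain model).
#'
#' @param name Fixture name.
#' @return A list with `name`, `kind`, `payload` (constructed object) and
#'   `oracle` (named list of documented values).
#' @export
load_fixture <- function(name) {
  dir <- system.file("extdata", "fixtures", package = "goalcat")
  path <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(path))
    stop("unknown fixture '", name, "'; registered: ",
         paste(sub("\\.json$", "", list.files(dir, "\\.json$")),
               collapse = ", "))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  payload <- switch(
    doc$kind,
    structure_config = do.call(structure_config, doc$payload),
    world_spec = {
      p <- doc$payload
      world_spec(kind = p$kind,
                 cfg = do.call(structure_config, p$cfg),
                 determinism = lapply(p$determinism %||% list(), as.numeric),
                 goal_rule = if (!is.null(p$goal_rule))
                   list(preferred = as.integer(unlist(p$goal_rule$preferred))),
                 patterns = if (!is.null(p$patterns))
                   lapply(p$patterns, function(x) as.integer(unlist(x))),
                 seed = p$seed %||% 1L)
    },
    model = model_from_list(doc$payload),
    stop("fixture '", name, "' has unknown kind '", doc$kind, "'"))
  oracle <- lapply(doc$oracle, function(o) {
    o$value <- unlist(o$value)
    o
  })
  names(oracle) <- vapply(doc$oracle, `[[`, "", "quantity")
  list(name = doc$name, kind = doc$kind, payload = payload, oracle = oracle)
}
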