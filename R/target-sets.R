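#' Map an entity to its target set on the interactome
#'
#' Intersects an entity's annotated targets with the interactome node set.
#' Annotated targets absent from the graph are dropped and counted in
#' `n_dropped`; an entity whose every target falls off-graph is an error,
#' since no distance is then defined for it.
#'
#' For `level = "herb"` the target set is the union of the herb's ingredients'
#' mapped targets (see [herb_target_union()]).
#'
#' @param entity_id Entity identifier present in the catalog at `level`.
#' @param level One of `"ingredient"`, `"herb"`, `"disease"`.
#' @param catalog An `entity_catalog`.
#' @param graph An `interactome`.
#' @return An object of class `target_set`: list with `entity_id`, `level`,
#'   `proteins` (sorted character vector, non-empty) and `n_dropped`.
#' @export
target_set <- function(entity_id, level = c("ingredient", "herb", "disease"),
                       catalog, graph) {
  level <- match.arg(level)
  stopifnot(inherits(catalog, "entity_catalog"), inherits(graph, "interactome"))
  if (level == "herb") return(herb_target_union(entity_id, catalog, graph))
  tab <- switch(level,
    ingredient = catalog$ingredient_target,
    disease = catalog$disease_target
  )
  annotated <- sort(unique(tab[[2L]][tab[[1L]] == entity_id]))
  if (!length(annotated)) {
    stopf("entity '%s' not found at level '%s' (no annotated targets)", entity_id, level)
  }
  nodes <- igraph::V(graph$graph)$name
  proteins <- intersect(annotated, nodes)
  if (!length(proteins)) {
    stopf("entity '%s': no mappable targets (all %d annotated targets absent from the interactome)",
          entity_id, length(annotated))
  }
  new_target_set(entity_id, level, sort(proteins), length(annotated) - length(proteins))
}

new_target_set <- function(entity_id, level, proteins, n_dropped) {
  structure(
    list(entity_id = entity_id, level = level,
         proteins = proteins, n_dropped = as.integer(n_dropped)),
    class = "target_set"
  )
}

#' Herb target set as the union of its ingredients' targets
#'
#' A herb acts through its ingredients, so its target set is the union of the
#' mapped target sets of all its ingredients. Ingredients with no mappable
#' targets are skipped; a herb with none is an error.
#'
#' @inheritParams target_set
#' @param herb_id Herb identifier.
#' @return A `target_set` with `level = "herb"`. `n_dropped` sums the dropped
#'   target counts of the herb's usable ingredients.
#' @export
herb_target_union <- function(herb_id, catalog, graph) {
  stopifnot(inherits(catalog, "entity_catalog"), inherits(graph, "interactome"))
  ings <- ingredients_of_herb(catalog, herb_id)
  if (!length(ings)) stopf("herb '%s' has no ingredients in the catalog", herb_id)
  proteins <- character(0)
  n_dropped <- 0L
  usable <- 0L
  for (ing in ings) {
    ts <- tryCatch(target_set(ing, "ingredient", catalog, graph), error = function(e) NULL)
    if (is.null(ts)) next
    usable <- usable + 1L
    proteins <- union(proteins, ts$proteins)
    n_dropped <- n_dropped + ts$n_dropped
  }
  if (usable == 0L) {
    stopf("herb '%s': no ingredient with mappable targets", herb_id)
  }
  new_target_set(herb_id, "herb", sort(proteins), n_dropped)
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target set [%s] %s: %d protein(s), %d dropped\n",
              x$level, x$entity_id, length(x$proteins), x$n_dropped))
  invisible(x)
}

# Accept either a target_set or a bare character vector of node IDs.
as_protein_set <- function(x) {
  if (inherits(x, "target_set")) return(x$proteins)
  if (is.character(x) && length(x) > 0L) return(sort(unique(x)))
  stopf("expected a target_set or a non-empty character vector of node IDs")
}
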