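# Network proximity metrics.
#
# All distances are unweighted shortest-path hop counts on the interactome.
# Four metrics are provided:
#   closest  d^C(A,B) = [ sum_a min_b d(a,b) + sum_b min_a d(a,b) ] / (|A|+|B|)
#   shortest d^S(a,b) = mean over all cross pairs of d(a',b')   (product norm)
#   center   d^CC(HA,HB) = d^S between the two herbs' center ingredients
#   disease  d(X,Y)   = (1/|Y|) sum_{y in Y} min_{x in X} d(x,y)  (directed)
# Smaller values indicate stronger putative interaction.

# Shortest-path hop-count matrix between two node sets. Errors on unreachable
# pairs: the metrics are undefined at infinite distance, and LCC restriction
# at load time is the supported way to guarantee finiteness.
distance_matrix <- function(graph, from, to) {
  stopifnot(inherits(graph, "interactome"))
  D <- igraph::distances(graph$graph, v = from, to = to)
  if (any(is.infinite(D))) {
    stopf("unreachable node pair encountered; load the interactome with restrict_lcc = TRUE")
  }
  D
}

#' Closest network distance between two target sets
#'
#' Symmetric average, over the targets of both sets, of each target's minimum
#' shortest-path distance to the other set. This is the ingredient-ingredient
#' synergy score: two ingredients whose targets interleave on the interactome
#' score near zero.
#'
#' @param A,B Target sets ([target_set] objects or character vectors of
#'   interactome node IDs).
#' @param graph An `interactome`.
#' @return A single non-negative number (hops). Zero iff the sets coincide.
#' @examples
#' g <- load_interactome(data.frame(a = c("v1","v2","v3","v4"),
#'                                  b = c("v2","v3","v4","v5")))
#' closest_distance(c("v1","v2"), c("v4","v5"), g)  # 2.5
#' @export
closest_distance <- function(A, B, graph) {
  a <- as_protein_set(A)
  b <- as_protein_set(B)
  D <- distance_matrix(graph, a, b)
  (sum(apply(D, 1L, min)) + sum(apply(D, 2L, min))) / (length(a) + length(b))
}

#' Shortest (all-pairs average) network distance between two target sets
#'
#' Averages the shortest-path length over all cross pairs of targets. This is
#' the ingredient-level edge weight used when comparing herbs. The default
#' normalisation divides by the number of cross pairs `|a|*|b|` (so the value
#' is a true mean); `norm = "sum"` divides the same sum by `|a|+|b|` instead.
#'
#' @inheritParams closest_distance
#' @param a,b Target sets.
#' @param norm `"product"` (default, mean over all pairs) or `"sum"`.
#' @return A single non-negative number (hops).
#' @export
shortest_distance <- function(a, b, graph, norm = c("product", "sum")) {
  norm <- match.arg(norm)
  pa <- as_protein_set(a)
  pb <- as_protein_set(b)
  D <- distance_matrix(graph, pa, pb)
  denom <- if (norm == "product") length(pa) * length(pb) else length(pa) + length(pb)
  sum(D) / denom
}

#' Center ingredient of a herb
#'
#' The center ingredient minimises the summed pairwise distance to the herb's
#' other ingredients; it stands in for the herb in herb-herb scoring. The
#' pairwise distance defaults to the shortest (all-pairs average) distance
#' between the ingredients' mapped target sets. Ties are broken by the
#' lexicographically smallest ingredient ID; a single-ingredient herb returns
#' that ingredient (the empty sum is zero).
#'
#' @param herb_id Herb identifier.
#' @param catalog An `entity_catalog`.
#' @param graph An `interactome`.
#' @param pairwise_distance Optional `function(ingredient_a, ingredient_b)`
#'   returning a distance; defaults to [shortest_distance()] between mapped
#'   target sets.
#' @return The center ingredient's ID (character scalar).
#' @export
center_ingredient <- function(herb_id, catalog, graph, pairwise_distance = NULL) {
  ings <- usable_ingredients(herb_id, catalog, graph, allow_custom = !is.null(pairwise_distance))
  if (length(ings) == 1L) return(ings)
  if (is.null(pairwise_distance)) {
    sets <- lapply(ings, function(i) target_set(i, "ingredient", catalog, graph))
    names(sets) <- ings
    pairwise_distance <- function(x, y) shortest_distance(sets[[x]], sets[[y]], graph)
  }
  sums <- vapply(ings, function(u) {
    sum(vapply(setdiff(ings, u), function(v) pairwise_distance(u, v), numeric(1L)))
  }, numeric(1L))
  unname(ings[which(sums == min(sums))][1L])  # ings sorted, so first minimum is lexicographic
}

usable_ingredients <- function(herb_id, catalog, graph, allow_custom = FALSE) {
  ings <- ingredients_of_herb(catalog, herb_id)
  if (!length(ings)) stopf("herb '%s' has no ingredients in the catalog", herb_id)
  if (allow_custom) return(ings)
  ok <- vapply(ings, function(i) {
    !is.null(tryCatch(target_set(i, "ingredient", catalog, graph), error = function(e) NULL))
  }, logical(1L))
  if (!any(ok)) stopf("herb '%s': no ingredient with mappable targets", herb_id)
  unname(ings[ok])
}

#' Center distance between two herbs
#'
#' The herb-herb interaction score: the shortest (all-pairs average) distance
#' between the target sets of the two herbs' center ingredients, determined on
#' their ingredient-ingredient network.
#'
#' @inheritParams center_ingredient
#' @param herb_a,herb_b Herb identifiers.
#' @param norm Normalisation passed to [shortest_distance()].
#' @return A single non-negative number (hops).
#' @export
center_distance <- function(herb_a, herb_b, catalog, graph, norm = "product") {
  ca <- center_ingredient(herb_a, catalog, graph)
  cb <- center_ingredient(herb_b, catalog, graph)
  shortest_distance(
    target_set(ca, "ingredient", catalog, graph),
    target_set(cb, "ingredient", catalog, graph),
    graph, norm = norm
  )
}

#' Disease-directed network proximity
#'
#' Average, over the disease genes `Y`, of the minimum shortest-path distance
#' to the drug/herb/ingredient target set `X`. The average runs in one
#' direction only — from the disease to the drug — so the measure is not
#' symmetric: it is zero iff every disease gene is itself a drug target
#' (`Y` a subset of `X`).
#'
#' @param X Drug-side target set (ingredient or herb union).
#' @param Y Disease gene set.
#' @param graph An `interactome`.
#' @return A single non-negative number (hops).
#' @export
disease_proximity <- function(X, Y, graph) {
  x <- as_protein_set(X)
  y <- as_protein_set(Y)
  D <- distance_matrix(graph, y, x)  # rows: disease genes, cols: drug targets
  mean(apply(D, 1L, min))
}

#' Pairwise distance matrix over a list of target sets
#'
#' Computes the symmetric matrix of closest or shortest distances for a batch
#' of target sets. Shortest-path distances are computed once from the union of
#' all member nodes and reused across pairs, so each target set's single-source
#' searches are not repeated.
#'
#' @param sets Named list of target sets (or character vectors).
#' @param graph An `interactome`.
#' @param metric `"closest"` or `"shortest"`.
#' @param norm Normalisation for the shortest metric.
#' @return A symmetric numeric matrix with dimnames from `names(sets)`.
#' @export
all_pairs_distances <- function(sets, graph, metric = c("closest", "shortest"),
                                norm = "product") {
  metric <- match.arg(metric)
  stopifnot(length(sets) >= 1L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  prots <- lapply(sets, as_protein_set)
  cache <- distance_cache(graph, unique(unlist(prots)))
  n <- length(prots)
  M <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- cached_pair_distance(cache, prots[[i]], prots[[j]], metric, norm)
      M[i, j] <- d
      M[j, i] <- d
    }
  }
  M
}

# Precompute the hop-count matrix over a fixed node universe; pair metrics
# then reduce to submatrix row/column operations.
distance_cache <- function(graph, nodes) {
  nodes <- sort(nodes)
  D <- distance_matrix(graph, nodes, nodes)
  rownames(D) <- nodes
  colnames(D) <- nodes
  D
}

cached_pair_distance <- function(cache, a, b, metric, norm = "product") {
  D <- cache[a, b, drop = FALSE]
  switch(metric,
    closest = (sum(apply(D, 1L, min)) + sum(apply(D, 2L, min))) / (length(a) + length(b)),
    shortest = sum(D) / if (norm == "product") length(a) * length(b) else length(a) + length(b),
    disease = stop("use cached_disease_distance"),
    stopf("unknown metric '%s'", metric)
  )
}

# disease-directed: rows of the cache are disease genes (Y), cols drug targets.
cached_disease_distance <- function(cache, x, y) {
  D <- cache[y, x, drop = FALSE]
  mean(apply(D, 1L, min))
}

# Center ingredient for each of several herbs, sharing one hop-count cache
# across all within-herb pairwise shortest distances.
compute_centers <- function(herbs, catalog, graph, norm = "product") {
  ings_by_herb <- lapply(herbs, usable_ingredients, catalog = catalog, graph = graph)
  names(ings_by_herb) <- herbs
  all_ings <- unique(unlist(ings_by_herb))
  sets <- lapply(all_ings, target_set, level = "ingredient", catalog = catalog, graph = graph)
  names(sets) <- all_ings
  cache <- distance_cache(graph, unique(unlist(lapply(sets, `[[`, "proteins"))))
  vapply(herbs, function(h) {
    ings <- ings_by_herb[[h]]
    if (length(ings) == 1L) return(ings)
    sums <- vapply(ings, function(u) {
      sum(vapply(setdiff(ings, u), function(v) {
        cached_pair_distance(cache, sets[[u]]$proteins, sets[[v]]$proteins, "shortest", norm)
      }, numeric(1L)))
    }, numeric(1L))
    unname(ings[which(sums == min(sums))][1L])
  }, character(1L))
}
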