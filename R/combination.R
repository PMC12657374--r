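# Combination queries: within-formula synergy scans, the five recommendation
# patterns, landscape graphs, and Louvain disease-module extraction.

#' Scan a formula for significantly proximal ingredient pairs
#'
#' Evaluates the closest distance for every unordered pair of the formula's
#' usable ingredients (reached through its herbs), tests each against the
#' supplied null, and returns the significant pairs sorted by ascending
#' distance.
#'
#' @param formula_id Formula identifier.
#' @param catalog An `entity_catalog`.
#' @param graph An `interactome`.
#' @param null A `null_model` for ingredient-ingredient closest distances; if
#'   `NULL`, one is sampled from random catalog ingredient pairs
#'   (`n_null` pairs, using `seed`).
#' @param n_null,seed Null sampling controls when `null` is `NULL`.
#' @param alpha Significance level.
#' @return Data frame with columns `ingredient_a`, `ingredient_b`, `distance`,
#'   `z`, `p` — significant pairs only, ascending distance. The set of all
#'   evaluated pairs (`C(k,2)` for `k` usable ingredients) is in the
#'   `n_evaluated` attribute.
#' @export
formula_synergy_scan <- function(formula_id, catalog, graph, null = NULL,
                                 n_null = 1000L, seed = NULL, alpha = 0.05) {
  ings <- ingredients_of_formula(catalog, formula_id)
  if (!length(ings)) stopf("formula '%s' not found or has no ingredients", formula_id)
  sets <- list()
  for (i in ings) {
    ts <- tryCatch(target_set(i, "ingredient", catalog, graph), error = function(e) NULL)
    if (!is.null(ts)) sets[[i]] <- ts
  }
  if (length(sets) < 2L) {
    stopf("formula '%s': fewer than 2 ingredients with mappable targets", formula_id)
  }
  if (is.null(null)) null <- random_pair_null("ingredient", catalog, graph, n_null, seed)
  M <- all_pairs_distances(sets, graph, metric = "closest")
  pr <- t(combn(names(sets), 2L))
  d <- M[pr]
  zt <- z_test(d, null, alpha = alpha)
  out <- data.frame(ingredient_a = pr[, 1L], ingredient_b = pr[, 2L],
                    distance = d, z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  out <- out[zt$significant, , drop = FALSE]
  out <- out[order(out$distance, out$ingredient_a, out$ingredient_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- nrow(pr)
  attr(out, "null") <- null
  out
}

# null from uniformly random entity pairs at one level
random_pair_null <- function(level, catalog, graph, n_null, seed,
                             metric = if (level == "herb") "center" else "closest") {
  ids <- if (level == "herb") catalog$herb_ids else catalog$ingredient_ids
  if (level != "herb") {
    ok <- vapply(ids, function(e) {
      !is.null(tryCatch(target_set(e, "ingredient", catalog, graph), error = function(x) NULL))
    }, logical(1L))
    ids <- ids[ok]
  }
  if (length(ids) < 2L) stopf("not enough mappable entities at level '%s' for a null", level)
  universe <- expand.grid(a = ids, b = ids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  universe <- universe[universe$a < universe$b, , drop = FALSE]
  universe <- universe[order(universe$a, universe$b), , drop = FALSE]
  attr(universe, "level_a") <- level
  attr(universe, "level_b") <- level
  sample_null(universe, metric = metric, catalog = catalog, graph = graph,
              n = n_null, seed = seed, level = paste0(level, "_", level))
}

#' Run a combination-recommendation query
#'
#' Scores a user-chosen combination under one of the five query patterns and
#' assembles the scored, significance-flagged multi-entity network
#' (combination landscape):
#'
#' * `"herb+herb"` — one herb-herb edge (center distance).
#' * `"ingredient+ingredient"` — one ingredient-ingredient edge (closest
#'   distance).
#' * `"herb+herb+disease"` — the herb-herb edge plus disease-proximity edges
#'   for each input herb and for each constituent ingredient.
#' * `"ingredient+ingredient+disease"` — the ingredient-ingredient edge plus
#'   a disease edge per ingredient.
#' * `"prescription+prescription+disease"` — expands each prescription
#'   (formula) to its herbs and ingredients, scores all cross-prescription
#'   herb-herb and ingredient-ingredient pairs and every entity-disease edge.
#'   Within-prescription pairs are included with `include_within = TRUE`.
#'
#' Each relation is tested against its own null; nulls not supplied in
#' `nulls` are sampled per test from the catalog with `seed`.
#'
#' @param pattern One of the five pattern strings above.
#' @param a,b The two input entity IDs (herbs, ingredients or formulas,
#'   matching the pattern).
#' @param disease Disease ID, required for the three-way patterns.
#' @param catalog An `entity_catalog`.
#' @param graph An `interactome`.
#' @param nulls Optional named list of `null_model`s, keys among `"ing_ing"`,
#'   `"herb_herb"`, `"ing_disease"`, `"herb_disease"`.
#' @param n_null,seed Null sampling controls for missing nulls.
#' @param alpha Significance level.
#' @param include_within Also score within-prescription pairs (prescription
#'   pattern only).
#' @return A `combination_landscape`: list with `nodes` (id, level), `edges`
#'   (source, target, relation, distance, z, p, significant) and `query`.
#' @export
recommend <- function(pattern, a, b, disease = NULL, catalog, graph,
                      nulls = list(), n_null = 1000L, seed = NULL, alpha = 0.05,
                      include_within = FALSE) {
  patterns <- c("herb+herb", "ingredient+ingredient", "herb+herb+disease",
                "ingredient+ingredient+disease", "prescription+prescription+disease")
  if (!is_string(pattern) || !pattern %in% patterns) {
    stopf("unknown pattern '%s'; expected one of: %s", pattern,
          paste(patterns, collapse = ", "))
  }
  needs_disease <- grepl("disease", pattern, fixed = TRUE)
  if (needs_disease && is.null(disease)) stopf("pattern '%s' requires a disease", pattern)

  get_null <- function(key, level, metric) {
    if (!is.null(nulls[[key]])) return(nulls[[key]])
    if (metric == "disease") disease_null(level, catalog, graph, n_null, seed)
    else random_pair_null(level, catalog, graph, n_null, seed, metric = metric)
  }

  nodes <- data.frame(id = character(0), level = character(0), stringsAsFactors = FALSE)
  edges <- data.frame(source = character(0), target = character(0),
                      relation = character(0), distance = numeric(0), z = numeric(0),
                      p = numeric(0), significant = logical(0), stringsAsFactors = FALSE)
  add_node <- function(id, level) {
    if (!id %in% nodes$id) {
      nodes <<- rbind(nodes, data.frame(id = id, level = level, stringsAsFactors = FALSE))
    }
  }
  add_edges <- function(src, dst, relation, d, null) {
    zt <- z_test(d, null, alpha = alpha)
    edges <<- rbind(edges, data.frame(
      source = src, target = dst, relation = relation, distance = d,
      z = zt$z, p = zt$p, significant = zt$significant, stringsAsFactors = FALSE))
  }

  Y <- if (needs_disease) target_set(disease, "disease", catalog, graph) else NULL
  if (needs_disease) add_node(disease, "disease")

  if (pattern %in% c("ingredient+ingredient", "ingredient+ingredient+disease")) {
    add_node(a, "ingredient"); add_node(b, "ingredient")
    ta <- target_set(a, "ingredient", catalog, graph)
    tb <- target_set(b, "ingredient", catalog, graph)
    add_edges(a, b, "ing-ing", closest_distance(ta, tb, graph),
              get_null("ing_ing", "ingredient", "closest"))
    if (needs_disease) {
      nd <- get_null("ing_disease", "ingredient", "disease")
      add_edges(a, disease, "ing-disease", disease_proximity(ta, Y, graph), nd)
      add_edges(b, disease, "ing-disease", disease_proximity(tb, Y, graph), nd)
    }
  } else if (pattern %in% c("herb+herb", "herb+herb+disease")) {
    add_node(a, "herb"); add_node(b, "herb")
    add_edges(a, b, "herb-herb", center_distance(a, b, catalog, graph),
              get_null("herb_herb", "herb", "center"))
    if (needs_disease) {
      nh <- get_null("herb_disease", "herb", "disease")
      ni <- get_null("ing_disease", "ingredient", "disease")
      for (h in c(a, b)) {
        add_edges(h, disease, "herb-disease",
                  disease_proximity(target_set(h, "herb", catalog, graph), Y, graph), nh)
        for (ing in usable_ingredients(h, catalog, graph)) {
          add_node(ing, "ingredient")
          add_edges(ing, disease, "ing-disease",
                    disease_proximity(target_set(ing, "ingredient", catalog, graph), Y, graph),
                    ni)
        }
      }
    }
  } else {  # prescription+prescription+disease
    herbs_a <- herbs_of_formula(catalog, a)
    herbs_b <- herbs_of_formula(catalog, b)
    if (!length(herbs_a)) stopf("prescription '%s' not found or empty", a)
    if (!length(herbs_b)) stopf("prescription '%s' not found or empty", b)
    usable_herb <- function(h) {
      !is.null(tryCatch(herb_target_union(h, catalog, graph), error = function(e) NULL))
    }
    herbs_a <- herbs_a[vapply(herbs_a, usable_herb, logical(1L))]
    herbs_b <- herbs_b[vapply(herbs_b, usable_herb, logical(1L))]
    for (h in union(herbs_a, herbs_b)) add_node(h, "herb")
    ings_a <- unique(unlist(lapply(herbs_a, usable_ingredients, catalog = catalog, graph = graph)))
    ings_b <- unique(unlist(lapply(herbs_b, usable_ingredients, catalog = catalog, graph = graph)))
    for (i in union(ings_a, ings_b)) add_node(i, "ingredient")

    herb_pairs <- cross_pairs(herbs_a, herbs_b, include_within)
    if (nrow(herb_pairs)) {
      nh <- get_null("herb_herb", "herb", "center")
      centers <- compute_centers(union(herbs_a, herbs_b), catalog, graph)
      csets <- lapply(unique(unname(centers)), target_set, level = "ingredient",
                      catalog = catalog, graph = graph)
      names(csets) <- unique(unname(centers))
      ccache <- distance_cache(graph, unique(unlist(lapply(csets, `[[`, "proteins"))))
      d <- vapply(seq_len(nrow(herb_pairs)), function(k) {
        cached_pair_distance(ccache, csets[[centers[[herb_pairs$a[k]]]]]$proteins,
                             csets[[centers[[herb_pairs$b[k]]]]]$proteins, "shortest")
      }, numeric(1L))
      add_edges(herb_pairs$a, herb_pairs$b, "herb-herb", d, nh)
    }
    ing_pairs <- cross_pairs(ings_a, ings_b, include_within)
    if (nrow(ing_pairs)) {
      ni <- get_null("ing_ing", "ingredient", "closest")
      all_ings <- union(ings_a, ings_b)
      sets <- lapply(all_ings, target_set, level = "ingredient", catalog = catalog, graph = graph)
      names(sets) <- all_ings
      cache <- distance_cache(graph, unique(c(unlist(lapply(sets, `[[`, "proteins")),
                                              Y$proteins)))
      d <- vapply(seq_len(nrow(ing_pairs)), function(k) {
        cached_pair_distance(cache, sets[[ing_pairs$a[k]]]$proteins,
                             sets[[ing_pairs$b[k]]]$proteins, "closest")
      }, numeric(1L))
      add_edges(ing_pairs$a, ing_pairs$b, "ing-ing", d, ni)
      ndis <- get_null("ing_disease", "ingredient", "disease")
      d_dis <- vapply(all_ings, function(i) {
        cached_disease_distance(cache, sets[[i]]$proteins, Y$proteins)
      }, numeric(1L))
      add_edges(all_ings, disease, "ing-disease", d_dis, ndis)
    }
    nhd <- get_null("herb_disease", "herb", "disease")
    for (h in union(herbs_a, herbs_b)) {
      add_edges(h, disease, "herb-disease",
                disease_proximity(herb_target_union(h, catalog, graph), Y, graph), nhd)
    }
  }

  edges <- edges[order(edges$relation, edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$level, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes, edges = edges,
         query = list(pattern = pattern, a = a, b = b, disease = disease,
                      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                      alpha = alpha)),
    class = "combination_landscape"
  )
}

cross_pairs <- function(xs, ys, include_within = FALSE) {
  if (!length(xs) || !length(ys)) {
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  }
  pairs <- expand.grid(a = xs, b = ys, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (include_within) {
    within <- function(v) {
      if (length(v) < 2L) return(NULL)
      m <- t(combn(sort(v), 2L))
      data.frame(a = m[, 1L], b = m[, 2L], stringsAsFactors = FALSE)
    }
    pairs <- rbind(pairs, within(xs), within(ys))
  }
  lo <- pmin(pairs$a, pairs$b)
  hi <- pmax(pairs$a, pairs$b)
  keep <- lo != hi & !duplicated(paste(lo, hi, sep = "\r"))
  data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
}

#' @export
print.combination_landscape <- function(x, ...) {
  cat(sprintf("combination landscape [%s]: %d nodes, %d edges (%d significant)\n",
              x$query$pattern, nrow(x$nodes), nrow(x$edges), sum(x$edges$significant)))
  invisible(x)
}

#' Build a weighted graph from a combination landscape
#'
#' Converts landscape edges to an undirected weighted graph for community
#' detection. Edge weights are `exp(-distance)` by default — monotone
#' decreasing in distance and finite at distance zero (shared-target pairs are
#' common, so a `1/d` transform would blow up). By default only significant
#' edges (`p < 0.05`) are kept, matching the practice of building the
#' combination network from significantly associated pairs; nodes left
#' without edges stay in the graph as isolates.
#'
#' @param landscape A `combination_landscape`.
#' @param weight_transform Function mapping distance to edge weight.
#' @param significant_only Keep only significant edges.
#' @return An [igraph][igraph::igraph-package] graph with a `weight` edge
#'   attribute and a `level` vertex attribute.
#' @export
build_combination_graph <- function(landscape, weight_transform = function(d) exp(-d),
                                    significant_only = TRUE) {
  stopifnot(inherits(landscape, "combination_landscape"))
  e <- landscape$edges
  if (significant_only) e <- e[e$significant, , drop = FALSE]
  if (nrow(e) == 0L) stopf("no %sedges to build a graph from",
                           if (significant_only) "significant " else "")
  nodes <- landscape$nodes[order(landscape$nodes$id), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, level = nodes$level, stringsAsFactors = FALSE)
  )
  igraph::E(g)$weight <- weight_transform(e$distance)
  igraph::E(g)$distance <- e$distance
  g
}

#' Louvain community detection on a landscape graph
#'
#' Runs Louvain modularity maximisation on a weighted graph. The partition is
#' deterministic for a given seed (vertices are processed in sorted-ID order
#' and the RNG is fixed).
#'
#' @param graph A weighted [igraph][igraph::igraph-package] graph, e.g. from
#'   [build_combination_graph()].
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param seed Integer RNG seed.
#' @return Named integer vector: community label per node ID.
#' @export
detect_modules <- function(graph, resolution = 1.0, seed = NULL) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::vcount(graph) == 0L) stopf("empty graph")
  nm <- igraph::V(graph)$name
  g <- igraph::permute(graph, match(nm, sort(nm)))  # canonical vertex order
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  membership <- igraph::membership(cl)
  out <- as.integer(membership)
  names(out) <- igraph::V(g)$name
  out
}

#' Extract the disease module of a combination landscape
#'
#' The case-study workflow in one call: restrict the landscape to the
#' ingredient-disease network (relations `ing-ing` and `ing-disease` by
#' default), build the weighted graph over ALL its edges, run Louvain, and
#' return the entities sharing the disease node's community.
#'
#' Module detection deliberately uses the complete weighted network rather
#' than only the significant edges: modularity compares observed edge weight
#' against the weight expected from the full network, and pre-thresholding
#' collapses the landscape to a single dense component whose
#' modularity-optimal partition fragments it. With `exp(-distance)` weights
#' the non-significant edges form exactly the background against which a
#' disease-proximal module stands out.
#'
#' @param landscape A `combination_landscape`.
#' @param disease_node Disease node ID (defaults to the query's disease).
#' @param relations Edge relations to keep.
#' @param resolution,seed Passed to [detect_modules()].
#' @param weight_transform Passed to [build_combination_graph()].
#' @return Sorted character vector of module member IDs (the `labels`
#'   attribute carries the full community labeling).
#' @export
extract_disease_module <- function(landscape, disease_node = landscape$query$disease,
                                   relations = c("ing-ing", "ing-disease"),
                                   resolution = 1.0, seed = NULL,
                                   weight_transform = function(d) exp(-d)) {
  stopifnot(inherits(landscape, "combination_landscape"))
  if (is.null(disease_node)) stopf("no disease node given and none in the query")
  sub <- landscape
  sub$edges <- landscape$edges[landscape$edges$relation %in% relations, , drop = FALSE]
  keep <- unique(c(sub$edges$source, sub$edges$target))
  sub$nodes <- landscape$nodes[landscape$nodes$id %in% keep, , drop = FALSE]
  g <- build_combination_graph(sub, weight_transform = weight_transform,
                               significant_only = FALSE)
  labels <- detect_modules(g, resolution = resolution, seed = seed)
  structure(disease_module_members(labels, disease_node), labels = labels)
}

#' Members of the disease-containing community
#'
#' Returns the non-disease entities sharing the disease node's community
#' label: the ingredients (and herbs) most likely to act synergistically on
#' the disease under the landscape's proximity structure.
#'
#' @param labels Named community labels from [detect_modules()].
#' @param disease_node Disease node ID.
#' @return Sorted character vector of entity IDs (possibly empty).
#' @export
disease_module_members <- function(labels, disease_node) {
  if (!disease_node %in% names(labels)) {
    stopf("disease node '%s' absent from the community labeling", disease_node)
  }
  sort(setdiff(names(labels)[labels == labels[[disease_node]]], disease_node))
}

#' Write a combination landscape to node-link JSON and an edge-list CSV
#'
#' The JSON follows the node-link convention (`nodes`: id, level; `links`:
#' source, target, relation, distance, z, p, significant) and embeds the
#' query (pattern, inputs, seed). Optional community labels are appended as a
#' node attribute. The CSV is a flat edge list with the same columns,
#' distances with 6 decimals and p-values with 4 significant digits.
#'
#' @param landscape A `combination_landscape`.
#' @param json_path Output JSON path (NULL to skip).
#' @param csv_path Output CSV path (NULL to skip).
#' @param communities Optional named labels from [detect_modules()].
#' @return `json_path` (or `csv_path`), invisibly.
#' @export
write_landscape <- function(landscape, json_path = NULL, csv_path = NULL,
                            communities = NULL) {
  stopifnot(inherits(landscape, "combination_landscape"))
  if (!is.null(json_path)) {
    nodes <- landscape$nodes
    if (!is.null(communities)) {
      nodes$community <- unname(communities[nodes$id])
    }
    obj <- list(nodes = nodes,
                links = data.frame(source = landscape$edges$source,
                                   target = landscape$edges$target,
                                   relation = landscape$edges$relation,
                                   distance = landscape$edges$distance,
                                   z = landscape$edges$z,
                                   p = landscape$edges$p,
                                   significant = landscape$edges$significant,
                                   stringsAsFactors = FALSE),
                query = landscape$query)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", na = "null")
  }
  if (!is.null(csv_path)) {
    e <- landscape$edges
    e$distance <- fmt_distance(e$distance)
    e$z <- fmt_distance(e$z)
    e$p <- fmt_pvalue(e$p)
    e$significant <- tolower(as.character(e$significant))
    write.csv(e, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path %||% csv_path)
}

#' Read a combination landscape from node-link JSON
#' @param path Path written by [write_landscape()].
#' @return A `combination_landscape` (with a `community` node column if one
#'   was written).
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$links
  names(edges)[names(edges) == "source"] <- "source"
  structure(
    list(nodes = as.data.frame(obj$nodes, stringsAsFactors = FALSE),
         edges = data.frame(source = edges$source, target = edges$target,
                            relation = edges$relation, distance = edges$distance,
                            z = edges$z, p = edges$p, significant = edges$significant,
                            stringsAsFactors = FALSE),
         query = obj$query),
    class = "combination_landscape"
  )
}
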