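# Synthetic scenario generator.
#
# Emulates the shapes of the curated catalog — interactome, formula / herb /
# ingredient / disease association tables, ADMET table — with a planted
# disease module and planted disease-proximal ("synergistic") ingredients, so
# the whole inference pipeline is exercisable and benchmarkable without any
# external download. The planted/background truth labels make recovery
# measurable.

#' Generate a synthetic interactome
#'
#' Random-graph models: Barabási–Albert preferential attachment (scale-free,
#' the default — protein interactomes are approximately scale-free),
#' Watts–Strogatz small-world, and Erdős–Rényi. The graph is regenerated until
#' connected (up to 50 attempts; thereafter its largest component is taken),
#' and nodes are labeled `P0001`, `P0002`, ...
#'
#' @param model `"barabasi_albert"`, `"watts_strogatz"` or `"erdos_renyi"`.
#' @param n Number of proteins requested.
#' @param params Model parameters: `m` (edges per new node, BA, default 3),
#'   `nei`/`p` (Watts–Strogatz neighborhood and rewiring, defaults 4, 0.05),
#'   `p` (Erdős–Rényi edge probability, default `2*log(n)/n`).
#' @param seed Integer RNG seed.
#' @return An `interactome` (connected).
#' @export
generate_interactome <- function(model = c("barabasi_albert", "watts_strogatz", "erdos_renyi"),
                                 n = 1000L, params = list(), seed = NULL) {
  model <- match.arg(model)
  if (n < 2L) stopf("need at least 2 proteins")
  with_seed(seed, {
    g <- NULL
    for (attempt in 1:50) {
      cand <- switch(model,
        barabasi_albert = igraph::sample_pa(n, m = params$m %||% 3L, directed = FALSE),
        watts_strogatz = igraph::sample_smallworld(1L, n, nei = params$nei %||% 4L,
                                                   p = params$p %||% 0.05),
        erdos_renyi = igraph::sample_gnp(n, p = params$p %||% min(1, 2 * log(n) / n))
      )
      if (igraph::ecount(cand) == 0L) {
        stopf("model parameters yield a graph with no edges")
      }
      if (igraph::is_connected(cand)) { g <- cand; break }
    }
    if (is.null(g)) g <- cand  # fall back to the LCC of the last attempt
    width <- max(4L, nchar(as.character(n)))
    igraph::V(g)$name <- sprintf(paste0("P%0", width, "d"), seq_len(igraph::vcount(g)))
    e <- igraph::as_edgelist(g, names = TRUE)
    load_interactome(data.frame(protein_a = e[, 1L], protein_b = e[, 2L],
                                stringsAsFactors = FALSE),
                     restrict_lcc = TRUE)
  })
}

#' Generate a full synthetic scenario with planted signal
#'
#' Builds an interactome, picks a connected disease module (a breadth-first
#' ball around a random center node), and creates ingredients whose target
#' sets either carry planted proximity signal or are uniform background:
#'
#' * planted ingredients draw `round(proximity_bias * targets_per_entity)`
#'   targets from inside the disease module and the rest uniformly from the
#'   remaining nodes;
#' * background ingredients draw all targets uniformly.
#'
#' Ingredients are grouped into herbs and herbs into formulas, with at least
#' one formula guaranteed to contain two planted ingredients so that
#' within-formula synergy scans can find a planted pair. The single disease's
#' gene set is the module itself.
#'
#' Defaults (1000-node Barabási–Albert interactome with m = 3, module of 30,
#' 20 planted vs 80 background ingredients, 8 targets each, bias 0.8) define
#' the benchmark conditions used throughout the test suite.
#'
#' @param graph_model,n_proteins,graph_params Passed to
#'   [generate_interactome()].
#' @param disease_module_size Number of genes in the planted disease module.
#' @param n_planted,n_background Ingredient counts.
#' @param targets_per_entity Targets per ingredient.
#' @param proximity_bias Fraction of a planted ingredient's targets drawn
#'   from the disease module (effect size, in \[0, 1\]).
#' @param ingredients_per_herb,herbs_per_formula Grouping sizes.
#' @param seed Integer RNG seed.
#' @return A `synthetic_scenario`: list with `graph` (`interactome`),
#'   `catalog` (`entity_catalog`), `truth` (planted/background IDs, planted
#'   co-occurring pairs, module genes) and `config`.
#' @export
generate_scenario <- function(graph_model = "barabasi_albert", n_proteins = 1000L,
                              graph_params = list(m = 3L),
                              disease_module_size = 30L,
                              n_planted = 20L, n_background = 80L,
                              targets_per_entity = 8L, proximity_bias = 0.8,
                              ingredients_per_herb = 5L, herbs_per_formula = 10L,
                              seed = NULL) {
  if (proximity_bias < 0 || proximity_bias > 1) stopf("proximity_bias must be in [0, 1]")
  if (disease_module_size > n_proteins) stopf("disease module larger than the interactome")
  config <- list(graph_model = graph_model, n_proteins = n_proteins,
                 graph_params = graph_params, disease_module_size = disease_module_size,
                 n_planted = n_planted, n_background = n_background,
                 targets_per_entity = targets_per_entity, proximity_bias = proximity_bias,
                 ingredients_per_herb = ingredients_per_herb,
                 herbs_per_formula = herbs_per_formula,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  with_seed(seed, {
    graph <- generate_interactome(graph_model, n_proteins, graph_params, seed = NULL)
    nodes <- interactome_nodes(graph)
    module <- bfs_ball(graph, sample(nodes, 1L), disease_module_size)

    k <- n_planted + n_background
    ing_ids <- sprintf("ING%03d", seq_len(k))
    planted <- sort(sample(ing_ids, n_planted))
    background <- setdiff(ing_ids, planted)
    k_in <- round(proximity_bias * targets_per_entity)
    k_in <- min(k_in, length(module))
    targets <- lapply(ing_ids, function(id) {
      if (id %in% planted) {
        inside <- sample(module, k_in)
        outside <- sample(setdiff(nodes, inside), targets_per_entity - k_in)
        c(inside, outside)
      } else {
        sample(nodes, targets_per_entity)
      }
    })
    names(targets) <- ing_ids
    ingredient_target <- data.frame(
      ingredient_id = rep(ing_ids, lengths(targets)),
      protein_id = unlist(targets, use.names = FALSE),
      stringsAsFactors = FALSE
    )

    # group shuffled ingredients into herbs, herbs into formulas
    shuffled <- sample(ing_ids)
    n_herbs <- ceiling(k / ingredients_per_herb)
    herb_ids <- sprintf("HRB%03d", seq_len(n_herbs))
    herb_of <- rep(herb_ids, each = ingredients_per_herb, length.out = k)
    herb_ingredient <- data.frame(herb_id = herb_of, ingredient_id = shuffled,
                                  stringsAsFactors = FALSE)
    n_formulas <- ceiling(n_herbs / herbs_per_formula)
    formula_ids <- sprintf("FORM%02d", seq_len(n_formulas))
    formula_of <- rep(formula_ids, each = herbs_per_formula, length.out = n_herbs)
    formula_herb <- data.frame(formula_id = formula_of, herb_id = herb_ids,
                               stringsAsFactors = FALSE)

    disease_target <- data.frame(disease_id = "DIS1", protein_id = module,
                                 stringsAsFactors = FALSE)
    catalog <- load_catalog(formula_herb, herb_ingredient, ingredient_target,
                            disease_target)

    planted_pairs <- planted_cooccurring_pairs(catalog, planted)
    if (nrow(planted_pairs) == 0L && n_planted >= 2L && n_formulas >= 1L) {
      # guarantee at least one within-formula planted pair: put the herb of a
      # second planted ingredient into the formula of the first one's herb
      h1 <- herb_ingredient$herb_id[herb_ingredient$ingredient_id == planted[1L]]
      h2 <- herb_ingredient$herb_id[herb_ingredient$ingredient_id == planted[2L]]
      f1 <- formula_herb$formula_id[formula_herb$herb_id == h1][1L]
      formula_herb <- rbind(formula_herb,
                            data.frame(formula_id = f1, herb_id = h2,
                                       stringsAsFactors = FALSE))
      catalog <- load_catalog(formula_herb, herb_ingredient, ingredient_target,
                              disease_target)
      planted_pairs <- planted_cooccurring_pairs(catalog, planted)
    }

    structure(
      list(graph = graph, catalog = catalog,
           truth = list(planted = planted, background = background,
                        planted_pairs = planted_pairs, module = module,
                        disease_id = "DIS1"),
           config = config),
      class = "synthetic_scenario"
    )
  })
}

# first `size` nodes in breadth-first order (distance, then node ID) around a
# center: a connected ball, the simplest structure with well-defined
# proximity signal
bfs_ball <- function(graph, center, size) {
  d <- igraph::distances(graph$graph, v = center)[1L, ]
  ord <- order(d, names(d))
  sort(names(d)[ord][seq_len(size)])
}

planted_cooccurring_pairs <- function(catalog, planted) {
  pairs <- tryCatch(cooccurring_pairs(catalog, "ingredient_ingredient"),
                    error = function(e) NULL)
  if (is.null(pairs)) {
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  }
  pairs[pairs$a %in% planted & pairs$b %in% planted, , drop = FALSE]
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic scenario: %d-node %s interactome, module %d, %d planted + %d background",
    " ingredients, bias %.2f, seed %s\n"),
    x$config$n_proteins, x$config$graph_model, x$config$disease_module_size,
    x$config$n_planted, x$config$n_background, x$config$proximity_bias,
    if (is.na(x$config$seed)) "n/a" else x$config$seed))
  invisible(x)
}

#' Generate a toy ADMET property table
#'
#' Emits per-ingredient HIA (+/-), OB (oral bioavailability, 0-100), BBB
#' (+/-) and hepatotoxicity (+/-), with marginal rates chosen to mirror the
#' reported landscape of herbal ingredients: most absorb well in the
#' intestine (~86% HIA+), about two thirds cross the blood-brain barrier,
#' roughly a third are hepatotoxicity alerts, and bioavailability is skewed
#' low so that only a minority clears the 30% bar.
#'
#' @param ingredient_ids Character vector of ingredient IDs.
#' @param seed Integer RNG seed.
#' @return An `admet_table` with one row per input ID.
#' @export
generate_admet_table <- function(ingredient_ids, seed = NULL) {
  stopifnot(length(ingredient_ids) > 0L)
  ids <- as.character(ingredient_ids)
  with_seed(seed, {
    df <- data.frame(
      ingredient_id = ids,
      HIA = ifelse(stats::runif(length(ids)) < 0.86, "+", "-"),
      OB = round(100 * stats::rbeta(length(ids), 1.5, 5), 2),
      BBB = ifelse(stats::runif(length(ids)) < 0.67, "+", "-"),
      hepatotoxicity = ifelse(stats::runif(length(ids)) < 0.37, "+", "-"),
      stringsAsFactors = FALSE
    )
    read_admet_table(df)
  })
}

#' Write a synthetic scenario to a directory
#'
#' Emits exactly the files the loaders read back: `interactome.csv`, the four
#' catalog CSVs, `truth.json`, and `scenario.json` (the resolved
#' configuration, seed included).
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactome(scenario$graph, file.path(dir, "interactome.csv"))
  write_catalog(scenario$catalog, dir)
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  jsonlite::write_json(scenario$config, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a scenario directory written by [write_scenario()]
#' @param dir Directory path.
#' @return A `synthetic_scenario` (graph, catalog, truth, config).
#' @export
read_scenario <- function(dir) {
  graph <- load_interactome(file.path(dir, "interactome.csv"))
  catalog <- read_catalog_dir(dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  if (is.list(truth$planted_pairs) && !is.data.frame(truth$planted_pairs)) {
    truth$planted_pairs <- as.data.frame(truth$planted_pairs, stringsAsFactors = FALSE)
  }
  config <- jsonlite::read_json(file.path(dir, "scenario.json"), simplifyVector = TRUE)
  structure(list(graph = graph, catalog = catalog, truth = truth, config = config),
            class = "synthetic_scenario")
}
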