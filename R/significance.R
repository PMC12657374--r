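# Significance regimes.
#
# Three regimes back the proximity scores:
#   1. random-pair null (n = 1000 by default) + one-tailed Fisher Z-test for
#      within-formula ingredient pairs and herb pairs;
#   2. per-test nulls from 1000 random entity-disease pairs for repositioning;
#   3. an exhaustive formula co-occurrence pool with an empirical 5%-tail
#      threshold for browse-scale screening, where per-pair Z-tests would be
#      computationally prohibitive.
# In every regime small distances are the interesting tail: the Z-test p-value
# is the LEFT tail of the standard normal at Z = (x - mu_null) / sigma_null.

new_null_model <- function(values, strategy, seed, level, metric) {
  values <- as.numeric(values)
  if (length(values) < 2L) stopf("null model needs at least 2 values")
  sigma <- sd(values)  # sample sd, denominator n-1
  if (!is.finite(sigma) || sigma <= 0) stopf("degenerate null: sigma is zero")
  structure(
    list(values = values, mu = mean(values), sigma = sigma,
         strategy = strategy, n = length(values),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         level = level, metric = metric),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null model [%s, %s, %s]: n=%d, mu=%.4f, sigma=%.4f, seed=%s\n",
              x$strategy, x$level %||% "?", x$metric, x$n, x$mu, x$sigma,
              if (is.na(x$seed)) "n/a" else x$seed))
  invisible(x)
}

# Compute metric distances for a 2-column pair table. Unique pairs are
# evaluated once; distances come from a shared hop-count cache.
pair_metric_values <- function(pairs, metric, catalog, graph, norm = "product") {
  key <- paste(pairs[[1L]], pairs[[2L]], sep = "\r")
  uniq <- !duplicated(key)
  ua <- pairs[[1L]][uniq]
  ub <- pairs[[2L]][uniq]
  vals <- if (metric == "center") {
    centers <- compute_centers(unique(c(ua, ub)), catalog, graph)
    csets <- lapply(unique(unname(centers)), target_set, level = "ingredient",
                    catalog = catalog, graph = graph)
    names(csets) <- unique(unname(centers))
    cache <- distance_cache(graph, unique(unlist(lapply(csets, `[[`, "proteins"))))
    vapply(seq_along(ua), function(k) {
      cached_pair_distance(cache, csets[[centers[[ua[k]]]]]$proteins,
                           csets[[centers[[ub[k]]]]]$proteins, "shortest", norm)
    }, numeric(1L))
  } else {
    level_a <- attr(pairs, "level_a") %||% "ingredient"
    level_b <- attr(pairs, "level_b") %||% if (metric == "disease") "disease" else "ingredient"
    sets_a <- lapply(unique(ua), target_set, level = level_a, catalog = catalog, graph = graph)
    names(sets_a) <- unique(ua)
    sets_b <- lapply(unique(ub), target_set, level = level_b, catalog = catalog, graph = graph)
    names(sets_b) <- unique(ub)
    all_nodes <- unique(c(unlist(lapply(sets_a, `[[`, "proteins")),
                          unlist(lapply(sets_b, `[[`, "proteins"))))
    cache <- distance_cache(graph, all_nodes)
    vapply(seq_along(ua), function(k) {
      pa <- sets_a[[ua[k]]]$proteins
      pb <- sets_b[[ub[k]]]$proteins
      if (metric == "disease") cached_disease_distance(cache, pa, pb)
      else cached_pair_distance(cache, pa, pb, metric, norm)
    }, numeric(1L))
  }
  names(vals) <- key[uniq]
  unname(vals[key])
}

#' Sample a random-pair null distance distribution
#'
#' Draws `n` pairs uniformly with replacement from a pair universe, computes
#' the metric distance for each, and records the null mean and standard
#' deviation used by [z_test()]. Fully reproducible given the universe order
#' and the seed. The default `n = 1000` is the regime used throughout for
#' random ingredient pairs and random drug-disease pairs.
#'
#' @param pair_universe Data frame with two ID columns (entity pairs). For
#'   `metric = "disease"` the second column holds disease IDs. Attributes
#'   `level_a`/`level_b` may name the entity levels (default `"ingredient"`,
#'   and `"disease"` for the second column of the disease metric).
#' @param metric One of `"closest"`, `"shortest"`, `"center"`, `"disease"`.
#' @param catalog An `entity_catalog`.
#' @param graph An `interactome`.
#' @param n Number of pairs to draw (default 1000).
#' @param seed Integer RNG seed.
#' @param level Label recording what the null describes (e.g. `"herb_herb"`,
#'   `"ingredient_disease"`); informational.
#' @param norm Normalisation for the shortest metric.
#' @return A `null_model` with `strategy = "random_pairs"`.
#' @export
sample_null <- function(pair_universe, metric = c("closest", "shortest", "center", "disease"),
                        catalog, graph, n = 1000L, seed = NULL, level = NULL,
                        norm = "product") {
  metric <- match.arg(metric)
  if (!is.data.frame(pair_universe) || ncol(pair_universe) < 2L || nrow(pair_universe) == 0L) {
    stopf("pair_universe must be a non-empty two-column data frame")
  }
  if (n < 2L) stopf("null sample size must be at least 2")
  idx <- with_seed(seed, sample.int(nrow(pair_universe), n, replace = TRUE))
  drawn <- pair_universe[idx, , drop = FALSE]
  attr(drawn, "level_a") <- attr(pair_universe, "level_a")
  attr(drawn, "level_b") <- attr(pair_universe, "level_b")
  values <- pair_metric_values(drawn, metric, catalog, graph, norm = norm)
  new_null_model(values, "random_pairs", seed, level, metric)
}

#' Enumerate entity pairs co-occurring in at least one formula
#'
#' For `level = "herb_herb"`, all unordered herb pairs sharing a formula; for
#' `"ingredient_ingredient"`, all unordered pairs of ingredients reached
#' through a formula's herbs. Pairs present in several formulas are counted
#' once.
#'
#' @param catalog An `entity_catalog`.
#' @param level `"herb_herb"` or `"ingredient_ingredient"`.
#' @return Data frame with columns `a`, `b` (`a < b` lexicographically).
#' @export
cooccurring_pairs <- function(catalog, level = c("herb_herb", "ingredient_ingredient")) {
  level <- match.arg(level)
  stopifnot(inherits(catalog, "entity_catalog"))
  members <- lapply(catalog$formula_ids, function(f) {
    if (level == "herb_herb") herbs_of_formula(catalog, f)
    else ingredients_of_formula(catalog, f)
  })
  pair_list <- lapply(members, function(m) {
    if (length(m) < 2L) return(NULL)
    t(combn(sort(m), 2L))
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stopf("no co-occurring %s pair in any formula", level)
  }
  df <- data.frame(a = pairs[, 1L], b = pairs[, 2L], stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$a, df$b, sep = "\r")), , drop = FALSE]
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Exhaustive co-occurrence null pool
#'
#' Builds the browse-regime null distribution from every entity pair that
#' co-occurs in at least one formula — no sampling, no seed. Herb pairs are
#' scored by the center distance, ingredient pairs by the closest distance.
#' Pairs involving an entity with no mappable targets are skipped with a
#' message.
#'
#' @inheritParams sample_null
#' @param level `"herb_herb"` or `"ingredient_ingredient"`.
#' @return A `null_model` with `strategy = "cooccurrence_pool"`.
#' @export
cooccurrence_pool <- function(catalog, graph,
                              level = c("herb_herb", "ingredient_ingredient"),
                              norm = "product") {
  level <- match.arg(level)
  pairs <- cooccurring_pairs(catalog, level)
  ent_level <- if (level == "herb_herb") "herb" else "ingredient"
  mappable <- vapply(sort(unique(c(pairs$a, pairs$b))), function(e) {
    !is.null(tryCatch(target_set(e, ent_level, catalog, graph), error = function(x) NULL))
  }, logical(1L))
  ok_ids <- names(mappable)[mappable]
  keep <- pairs$a %in% ok_ids & pairs$b %in% ok_ids
  if (sum(!keep) > 0L) {
    message(sprintf("cooccurrence_pool: skipped %d pair(s) with unmappable entities", sum(!keep)))
  }
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) stopf("no co-occurring pair with mappable targets")
  metric <- if (level == "herb_herb") "center" else "closest"
  attr(pairs, "level_a") <- ent_level
  attr(pairs, "level_b") <- ent_level
  values <- pair_metric_values(pairs, metric, catalog, graph, norm = norm)
  nm <- new_null_model(values, "cooccurrence_pool", NULL, level, metric)
  nm$pairs <- pairs
  nm
}

#' One-tailed Fisher Z-test of an observed proximity against a null
#'
#' Standardises the observed distance against the null distribution,
#' `Z = (x - mu_null) / sigma_null`, and reports the left-tail standard-normal
#' p-value: small distances (strong interactions) give negative Z and small p.
#' A pair is significant at `p < alpha`.
#'
#' @param observed Numeric vector of observed distances.
#' @param null A `null_model`.
#' @param alpha Significance level (default 0.05).
#' @return A data frame (class `significance_result`) with columns `observed`,
#'   `z`, `p`, `significant`.
#' @examples
#' nm <- structure(list(values = c(1, 2, 3), mu = 2, sigma = 1, n = 3,
#'                      strategy = "random_pairs", seed = NA_integer_,
#'                      level = NULL, metric = "closest"),
#'                 class = "null_model")
#' z_test(0, nm)  # z = -2, p ~ 0.0228
#' @export
z_test <- function(observed, null, alpha = 0.05) {
  stopifnot(inherits(null, "null_model"))
  z <- (observed - null$mu) / null$sigma
  p <- pnorm(z)
  structure(
    data.frame(observed = observed, z = z, p = p, significant = p < alpha),
    class = c("significance_result", "data.frame")
  )
}

#' Empirical lower-tail distance threshold
#'
#' The browse-regime cutoff: the `q`-quantile of the null pool by the
#' nearest-rank rule (rank `ceil(q*n)`, 1-based on the ascending sort). A pair
#' is flagged when its distance is at or below the threshold, i.e. it sits in
#' the extreme lower tail of the co-occurrence distance distribution.
#'
#' @param null A `null_model`.
#' @param q Tail fraction in (0, 1); default 0.05.
#' @return The threshold distance (numeric scalar).
#' @export
empirical_threshold <- function(null, q = 0.05) {
  stopifnot(inherits(null, "null_model"), q > 0, q < 1)
  sorted <- sort(null$values)
  sorted[nearest_rank(q, length(sorted))]
}

#' Serialize a null model to JSON
#' @param null A `null_model`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_null_model <- function(null, path) {
  stopifnot(inherits(null, "null_model"))
  obj <- list(strategy = null$strategy, level = null$level, metric = null$metric,
              n = null$n, seed = null$seed, mu = null$mu, sigma = null$sigma,
              values = null$values)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a null model from JSON
#' @param path Path written by [write_null_model()].
#' @return A `null_model`.
#' @export
read_null_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_null_model(obj$values, obj$strategy,
                 if (is.null(obj$seed) || is.na(obj$seed)) NULL else obj$seed,
                 obj$level, obj$metric)
}
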