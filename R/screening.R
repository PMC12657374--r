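# Repositioning screens: batch entity-disease proximity with per-test nulls.

#' Screen all herbs or ingredients against one disease
#'
#' Computes the disease-directed proximity of every catalog entity at `level`
#' to the disease's gene set, tests each against a per-screen null of random
#' entity-disease pairs, and returns ranked, significance-flagged rows.
#' Entities with no mappable targets are skipped and reported (not silently
#' dropped) in the `skipped` attribute.
#'
#' One null (default 1000 random entity-disease pairs) is sampled per screen
#' and shared across the entities of that screen; its seed and size are kept
#' in the result's `null` attribute.
#'
#' @param disease_id Disease identifier.
#' @param level `"ingredient"` or `"herb"` (herbs score through their target
#'   union).
#' @param catalog An `entity_catalog`.
#' @param graph An `interactome`.
#' @param n_null Null sample size (default 1000).
#' @param seed Integer RNG seed for the null.
#' @param alpha Significance level (default 0.05).
#' @return A `screen_result`: data frame with columns `entity_id`,
#'   `disease_id`, `metric`, `distance`, `z`, `p`, `significant`, `rank`
#'   (1-based, ascending distance, ties broken by entity ID), with attributes
#'   `null` (the `null_model`) and `skipped`.
#' @export
reposition_for_disease <- function(disease_id, level = c("ingredient", "herb"),
                                   catalog, graph, n_null = 1000L, seed = NULL,
                                   alpha = 0.05) {
  level <- match.arg(level)
  Y <- target_set(disease_id, "disease", catalog, graph)
  entities <- if (level == "ingredient") catalog$ingredient_ids else catalog$herb_ids
  if (!length(entities)) stopf("catalog has no entities at level '%s'", level)
  scr <- screen_distances(entities, level, list(Y), catalog, graph)
  if (nrow(scr$rows) == 0L) stopf("no entity at level '%s' has mappable targets", level)
  null <- disease_null(level, catalog, graph, n_null, seed)
  finish_screen(scr, null, alpha, query = list(kind = "disease", id = disease_id, level = level))
}

#' Screen one herb or ingredient against all diseases
#'
#' Mirror of [reposition_for_disease()]: ranks every catalog disease by its
#' directed proximity to the entity's target set, so the top-scoring diseases
#' are candidate novel indications.
#'
#' @inheritParams reposition_for_disease
#' @param entity_id Herb or ingredient identifier.
#' @return A `screen_result` (one row per disease).
#' @export
reposition_for_entity <- function(entity_id, level = c("ingredient", "herb"),
                                  catalog, graph, n_null = 1000L, seed = NULL,
                                  alpha = 0.05) {
  level <- match.arg(level)
  if (!length(catalog$disease_ids)) stopf("catalog has no diseases")
  X <- target_set(entity_id, level, catalog, graph)
  sets <- list()
  skipped <- data.frame(entity_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (d in catalog$disease_ids) {
    Y <- tryCatch(target_set(d, "disease", catalog, graph), error = function(e) e)
    if (inherits(Y, "error")) {
      skipped <- rbind(skipped, data.frame(entity_id = d, reason = conditionMessage(Y),
                                           stringsAsFactors = FALSE))
    } else sets[[d]] <- Y
  }
  if (!length(sets)) stopf("no disease has mappable genes")
  cache <- distance_cache(graph, unique(c(X$proteins, unlist(lapply(sets, `[[`, "proteins")))))
  rows <- data.frame(
    entity_id = entity_id,
    disease_id = names(sets),
    metric = "disease",
    distance = vapply(sets, function(Y) cached_disease_distance(cache, X$proteins, Y$proteins),
                      numeric(1L)),
    stringsAsFactors = FALSE
  )
  null <- disease_null(level, catalog, graph, n_null, seed)
  finish_screen(list(rows = rows, skipped = skipped, rank_by = "disease_id"),
                null, alpha, query = list(kind = "entity", id = entity_id, level = level))
}

# distance rows for a set of entities against one or more disease gene sets
screen_distances <- function(entities, level, disease_sets, catalog, graph) {
  skipped <- data.frame(entity_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  sets <- list()
  for (e in entities) {
    ts <- tryCatch(target_set(e, level, catalog, graph), error = function(err) err)
    if (inherits(ts, "error")) {
      skipped <- rbind(skipped, data.frame(entity_id = e, reason = conditionMessage(ts),
                                           stringsAsFactors = FALSE))
    } else sets[[e]] <- ts
  }
  rows_list <- list()
  if (length(sets)) {
    all_nodes <- unique(c(unlist(lapply(sets, `[[`, "proteins")),
                          unlist(lapply(disease_sets, `[[`, "proteins"))))
    cache <- distance_cache(graph, all_nodes)
    for (Y in disease_sets) {
      rows_list[[Y$entity_id]] <- data.frame(
        entity_id = names(sets),
        disease_id = Y$entity_id,
        metric = "disease",
        distance = vapply(sets, function(ts) {
          cached_disease_distance(cache, ts$proteins, Y$proteins)
        }, numeric(1L)),
        stringsAsFactors = FALSE
      )
    }
  }
  rows <- if (length(rows_list)) do.call(rbind, rows_list) else
    data.frame(entity_id = character(0), disease_id = character(0),
               metric = character(0), distance = numeric(0), stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  list(rows = rows, skipped = skipped, rank_by = "entity_id")
}

# per-test null over random (entity, disease) pairs
disease_null <- function(level, catalog, graph, n_null, seed) {
  entities <- if (level == "ingredient") catalog$ingredient_ids else catalog$herb_ids
  universe <- expand.grid(a = entities, b = catalog$disease_ids,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  universe <- universe[order(universe$a, universe$b), , drop = FALSE]
  # restrict the universe to mappable entities so null distances are defined
  ok <- vapply(unique(universe$a), function(e) {
    !is.null(tryCatch(target_set(e, level, catalog, graph), error = function(x) NULL))
  }, logical(1L))
  universe <- universe[universe$a %in% names(ok)[ok], , drop = FALSE]
  if (nrow(universe) == 0L) stopf("no (entity, disease) pair with mappable targets")
  attr(universe, "level_a") <- level
  attr(universe, "level_b") <- "disease"
  sample_null(universe, metric = "disease", catalog = catalog, graph = graph,
              n = n_null, seed = seed, level = paste0(level, "_disease"))
}

finish_screen <- function(scr, null, alpha, query) {
  rows <- scr$rows
  zt <- z_test(rows$distance, null, alpha = alpha)
  rows$z <- zt$z
  rows$p <- zt$p
  rows$significant <- zt$significant
  ord <- order(rows$distance, rows[[scr$rank_by]])
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  structure(rows,
            class = c("screen_result", "data.frame"),
            null = null, skipped = scr$skipped, query = query)
}

#' @export
print.screen_result <- function(x, n = 10L, ...) {
  q <- attr(x, "query")
  cat(sprintf("repositioning screen (%s %s, level %s): %d rows, %d significant, %d skipped\n",
              q$kind, q$id, q$level, nrow(x), sum(x$significant),
              nrow(attr(x, "skipped"))))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' Write a screen result to CSV with a null-provenance sidecar
#'
#' Distances and Z-scores are serialized with 6 decimal places, p-values in
#' scientific notation with 4 significant digits. The sidecar
#' `<path>.provenance.json` records the null strategy, size and seed.
#'
#' @param x A `screen_result`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_screen_result <- function(x, path) {
  stopifnot(inherits(x, "screen_result"))
  out <- as.data.frame(x)
  out$distance <- fmt_distance(out$distance)
  out$z <- fmt_distance(out$z)
  out$p <- fmt_pvalue(out$p)
  out$significant <- tolower(as.character(out$significant))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  null <- attr(x, "null")
  prov <- list(strategy = null$strategy, level = null$level, metric = null$metric,
               n = null$n, seed = null$seed, mu = null$mu, sigma = null$sigma,
               query = attr(x, "query"),
               skipped = attr(x, "skipped"))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a screen result CSV written by [write_screen_result()]
#' @param path CSV path.
#' @return A data frame with the screen columns (provenance, if present, in
#'   the `provenance` attribute).
#' @export
read_screen_result <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$significant <- df$significant == "true"
  side <- paste0(path, ".provenance.json")
  if (file.exists(side)) {
    attr(df, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  df
}

#' Stratified distance report
#'
#' Splits screen rows into two strata and compares their distance
#' distributions with a two-sample Wilcoxon rank-sum test.
#'
#' * `herb_frequency_median_split`: each herb's formula occurrence count is
#'   taken from the catalog; herbs at or above the median count (over the
#'   herbs present in `results`) form the HIGH stratum — ties go HIGH.
#'   `results` must carry the herb ID in a `herb_id` or `entity_id` column.
#' * `formula_complexity`: formulas with fewer than 6 herbs are "simple",
#'   those with 6 or more "complex". `results` must carry a `formula_id`
#'   column.
#'
#' @param results Data frame with a numeric `distance` column plus the
#'   stratifier column described above.
#' @param catalog An `entity_catalog`.
#' @param strata_spec `"herb_frequency_median_split"` or
#'   `"formula_complexity"`.
#' @return A `strata_report`: list with `spec`, `summary` (per-stratum `n`,
#'   `median`, `q25`, `q75`) and `p_value` (NA when a stratum is empty).
#' @export
stratified_distance_report <- function(results, catalog,
                                       strata_spec = c("herb_frequency_median_split",
                                                       "formula_complexity")) {
  strata_spec <- match.arg(strata_spec)
  stopifnot(is.data.frame(results), "distance" %in% names(results), nrow(results) > 0L)
  if (strata_spec == "herb_frequency_median_split") {
    key <- if ("herb_id" %in% names(results)) "herb_id" else "entity_id"
    if (!key %in% names(results)) stopf("results need a herb_id or entity_id column")
    counts <- table(catalog$formula_herb$herb_id)
    herbs <- unique(results[[key]])
    freq <- as.numeric(counts[herbs])
    freq[is.na(freq)] <- 0
    med <- median(freq)
    high_herbs <- herbs[freq >= med]  # ties at the median go HIGH
    stratum <- ifelse(results[[key]] %in% high_herbs, "high_frequency", "low_frequency")
    levels_ <- c("low_frequency", "high_frequency")
  } else {
    if (!"formula_id" %in% names(results)) stopf("results need a formula_id column")
    n_herbs <- table(unique(catalog$formula_herb)$formula_id)
    complex_ids <- names(n_herbs)[as.numeric(n_herbs) >= 6]
    stratum <- ifelse(results$formula_id %in% complex_ids, "complex", "simple")
    levels_ <- c("simple", "complex")
  }
  summ <- do.call(rbind, lapply(levels_, function(s) {
    d <- results$distance[stratum == s]
    data.frame(stratum = s, n = length(d),
               median = if (length(d)) median(d) else NA_real_,
               q25 = if (length(d)) unname(quantile(d, 0.25)) else NA_real_,
               q75 = if (length(d)) unname(quantile(d, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  p <- NA_real_
  if (all(summ$n > 0L)) {
    p <- suppressWarnings(
      wilcox.test(results$distance[stratum == levels_[1L]],
                  results$distance[stratum == levels_[2L]])$p.value
    )
  }
  structure(list(spec = strata_spec, summary = summ, p_value = p,
                 test = "two-sample Wilcoxon rank-sum"),
            class = "strata_report")
}

#' @export
print.strata_report <- function(x, ...) {
  cat(sprintf("stratified distance report (%s)\n", x$spec))
  print(x$summary, row.names = FALSE)
  cat(sprintf("rank-sum p = %s\n", if (is.na(x$p_value)) "n/a (empty stratum)"
              else fmt_pvalue(x$p_value)))
  invisible(x)
}

#' Write a strata report to CSV
#' @param x A `strata_report`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_strata_report <- function(x, path) {
  stopifnot(inherits(x, "strata_report"))
  out <- x$summary
  out$p_value <- fmt_pvalue(x$p_value)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
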