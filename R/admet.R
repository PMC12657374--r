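# ADMET filtering: consume a per-ingredient property table and apply
# conjunctive filters to candidate lists. Property values are never predicted
# here — the table is an input.

#' Read an ADMET property table
#'
#' CSV layout: first column `ingredient_id`, remaining columns property names.
#' Categorical values are `"+"`/`"-"`, numeric values plain decimals.
#'
#' @param x CSV path or data frame.
#' @return An `admet_table`: data frame keyed by `ingredient_id`, with a
#'   `properties` attribute naming the registered properties.
#' @export
read_admet_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
  }
  stopifnot(is.data.frame(x))
  if (!"ingredient_id" %in% names(x)) {
    names(x)[1L] <- "ingredient_id"
  }
  x$ingredient_id <- as.character(x$ingredient_id)
  if (anyDuplicated(x$ingredient_id)) stopf("ADMET table: duplicated ingredient_id")
  structure(x, class = c("admet_table", "data.frame"),
            properties = setdiff(names(x), "ingredient_id"))
}

#' Write an ADMET table to CSV
#' @param table An `admet_table`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_admet_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse an ADMET filter specification
#'
#' One conjunct per line, `<property> <comparator> <value>`, with comparators
#' `eq`, `ge`, `le`; e.g. `HIA eq +` or `OB ge 30`. All conjuncts must hold
#' for an ingredient to survive [admet_filter()].
#'
#' @param lines Character vector of conjunct lines, or the path to a file of
#'   them. Blank lines and `#` comments are ignored.
#' @param table Optional `admet_table`; if given, properties are validated
#'   against its registry at parse time.
#' @return A `filter_spec`: data frame with columns `property`, `comparator`,
#'   `value`.
#' @export
parse_filter_spec <- function(lines, table = NULL) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stopf("malformed filter conjunct: '%s'", lines[bad[1L]])
  spec <- data.frame(property = vapply(parts, `[[`, "", 1L),
                     comparator = vapply(parts, `[[`, "", 2L),
                     value = vapply(parts, `[[`, "", 3L),
                     stringsAsFactors = FALSE)
  ok <- spec$comparator %in% c("eq", "ge", "le")
  if (!all(ok)) stopf("unknown comparator '%s' (expected eq, ge, le)",
                      spec$comparator[!ok][1L])
  if (!is.null(table)) {
    unknown <- setdiff(spec$property, attr(table, "properties"))
    if (length(unknown)) stopf("unknown ADMET property: %s", unknown[1L])
  }
  structure(spec, class = c("filter_spec", "data.frame"))
}

#' Filter candidate ingredients by ADMET properties
#'
#' Keeps the candidates satisfying every conjunct of the filter spec, e.g.
#' good intestinal absorption and oral bioavailability above 30% with
#' blood-brain-barrier penetration. Candidates missing a referenced property
#' value (absent row or NA) are excluded and reported in the `excluded`
#' attribute. An empty spec is a vacuous conjunction: all candidates survive.
#'
#' @param table An `admet_table`.
#' @param spec A `filter_spec` (or character lines accepted by
#'   [parse_filter_spec()]).
#' @param candidate_ids Character vector of ingredient IDs to filter.
#' @return Sorted character vector of surviving IDs; the `excluded` attribute
#'   lists dropped IDs with reasons.
#' @export
admet_filter <- function(table, spec, candidate_ids) {
  stopifnot(inherits(table, "admet_table"))
  if (!inherits(spec, "filter_spec")) spec <- parse_filter_spec(spec, table)
  unknown <- setdiff(spec$property, attr(table, "properties"))
  if (length(unknown)) stopf("unknown ADMET property: %s", unknown[1L])
  candidate_ids <- sort(unique(as.character(candidate_ids)))
  if (nrow(spec) == 0L) return(candidate_ids)
  excluded <- data.frame(ingredient_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- logical(length(candidate_ids))
  for (k in seq_along(candidate_ids)) {
    id <- candidate_ids[k]
    row <- which(table$ingredient_id == id)
    if (!length(row)) {
      excluded <- rbind(excluded, data.frame(ingredient_id = id,
                                             reason = "not in ADMET table",
                                             stringsAsFactors = FALSE))
      next
    }
    ok <- TRUE
    for (j in seq_len(nrow(spec))) {
      v <- table[[spec$property[j]]][row]
      if (is.na(v) || (is.character(v) && !nzchar(v))) {
        excluded <- rbind(excluded, data.frame(
          ingredient_id = id,
          reason = sprintf("missing property '%s'", spec$property[j]),
          stringsAsFactors = FALSE))
        ok <- FALSE
        break
      }
      pass <- switch(spec$comparator[j],
        eq = as.character(v) == spec$value[j],
        ge = suppressWarnings(as.numeric(v) >= as.numeric(spec$value[j])),
        le = suppressWarnings(as.numeric(v) <= as.numeric(spec$value[j]))
      )
      if (is.na(pass)) {
        excluded <- rbind(excluded, data.frame(
          ingredient_id = id,
          reason = sprintf("non-numeric value for '%s'", spec$property[j]),
          stringsAsFactors = FALSE))
        ok <- FALSE
        break
      }
      if (!pass) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  if (nrow(excluded)) {
    message(sprintf("admet_filter: %d candidate(s) excluded for missing data", nrow(excluded)))
  }
  structure(candidate_ids[keep], excluded = excluded)
}
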