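#' Load the formula/herb/ingredient/disease association catalog
#'
#' Assembles the four association tables into a deduplicated entity catalog.
#' Identifier sets (formulas, herbs, ingredients, diseases) are derived as the
#' union of IDs seen across the tables. Duplicated association rows are
#' removed.
#'
#' @param formula_herb Data frame (or CSV path) with columns
#'   `formula_id,herb_id`.
#' @param herb_ingredient Data frame (or CSV path) with columns
#'   `herb_id,ingredient_id`.
#' @param ingredient_target Data frame (or CSV path) with columns
#'   `ingredient_id,protein_id`. Must be non-empty: without ingredient targets
#'   no proximity is computable.
#' @param disease_target Data frame (or CSV path) with columns
#'   `disease_id,protein_id`.
#' @return An object of class `entity_catalog`: the four deduplicated tables
#'   plus `formula_ids`, `herb_ids`, `ingredient_ids`, `disease_ids`.
#' @seealso [read_catalog_dir()] to load all four tables from a directory.
#' @export
load_catalog <- function(formula_herb, herb_ingredient, ingredient_target,
                         disease_target) {
  fh <- read_assoc(formula_herb, c("formula_id", "herb_id"), "formula_herb")
  hi <- read_assoc(herb_ingredient, c("herb_id", "ingredient_id"), "herb_ingredient")
  it <- read_assoc(ingredient_target, c("ingredient_id", "protein_id"), "ingredient_target")
  dt <- read_assoc(disease_target, c("disease_id", "protein_id"), "disease_target")
  if (nrow(it) == 0L) stopf("ingredient_target table is empty: no proximity computable")
  structure(
    list(
      formula_herb = fh, herb_ingredient = hi,
      ingredient_target = it, disease_target = dt,
      formula_ids = sort(unique(fh$formula_id)),
      herb_ids = sort(unique(c(fh$herb_id, hi$herb_id))),
      ingredient_ids = sort(unique(c(hi$ingredient_id, it$ingredient_id))),
      disease_ids = sort(unique(dt$disease_id))
    ),
    class = "entity_catalog"
  )
}

read_assoc <- function(x, cols, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("%s table not found: %s", what, x)
    x <- read.csv(x, stringsAsFactors = FALSE, colClasses = "character")
  }
  if (!is.data.frame(x)) stopf("%s must be a data frame or a CSV path", what)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    stopf("%s table is missing column(s): %s", what,
          paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(lapply(x[cols], function(v) trimws(as.character(v))),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  out <- out[!duplicated(out), , drop = FALSE]
  out <- out[order(out[[1L]], out[[2L]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a catalog from a directory of CSV files
#'
#' Expects `formula_herb.csv`, `herb_ingredient.csv`, `ingredient_target.csv`
#' and `disease_target.csv` in `dir`, the layout written by [write_catalog()]
#' and [write_scenario()].
#'
#' @param dir Directory path.
#' @return An `entity_catalog`.
#' @export
read_catalog_dir <- function(dir) {
  load_catalog(
    file.path(dir, "formula_herb.csv"),
    file.path(dir, "herb_ingredient.csv"),
    file.path(dir, "ingredient_target.csv"),
    file.path(dir, "disease_target.csv")
  )
}

#' Write a catalog's four association tables
#'
#' @param catalog An `entity_catalog`.
#' @param dir Output directory (created if absent).
#' @param format `"csv"` writes four CSV files; `"json"` writes a single
#'   `catalog.json` with one list of 2-element records per table.
#' @return The directory, invisibly.
#' @export
write_catalog <- function(catalog, dir, format = c("csv", "json")) {
  stopifnot(inherits(catalog, "entity_catalog"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("formula_herb", "herb_ingredient", "ingredient_target", "disease_target")
  if (format == "csv") {
    for (tb in tabs) {
      write.csv(catalog[[tb]], file.path(dir, paste0(tb, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
  } else {
    obj <- lapply(catalog[tabs], function(df) unname(as.list(as.data.frame(t(df)))))
    names(obj) <- tabs
    jsonlite::write_json(obj, file.path(dir, "catalog.json"), auto_unbox = FALSE)
  }
  invisible(dir)
}

#' Read a catalog from its JSON mirror
#' @param path Path to a `catalog.json` written by [write_catalog()].
#' @return An `entity_catalog`.
#' @export
read_catalog_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(m, cols) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 2L, byrow = TRUE)
    df <- data.frame(m[, 1L], m[, 2L], stringsAsFactors = FALSE)
    names(df) <- cols
    df
  }
  load_catalog(
    mk(obj$formula_herb, c("formula_id", "herb_id")),
    mk(obj$herb_ingredient, c("herb_id", "ingredient_id")),
    mk(obj$ingredient_target, c("ingredient_id", "protein_id")),
    mk(obj$disease_target, c("disease_id", "protein_id"))
  )
}

#' @export
print.entity_catalog <- function(x, ...) {
  cat(sprintf(paste0(
    "entity catalog: %d formulas, %d herbs, %d ingredients, %d diseases\n",
    "  associations: %d formula-herb, %d herb-ingredient, %d ingredient-target, %d disease-target\n"),
    length(x$formula_ids), length(x$herb_ids), length(x$ingredient_ids),
    length(x$disease_ids), nrow(x$formula_herb), nrow(x$herb_ingredient),
    nrow(x$ingredient_target), nrow(x$disease_target)))
  invisible(x)
}

herbs_of_formula <- function(catalog, formula_id) {
  sort(unique(catalog$formula_herb$herb_id[catalog$formula_herb$formula_id == formula_id]))
}

ingredients_of_herb <- function(catalog, herb_id) {
  sort(unique(catalog$herb_ingredient$ingredient_id[catalog$herb_ingredient$herb_id == herb_id]))
}

ingredients_of_formula <- function(catalog, formula_id) {
  herbs <- herbs_of_formula(catalog, formula_id)
  sort(unique(unlist(lapply(herbs, ingredients_of_herb, catalog = catalog))))
}
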