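test_that("disease repositioning ranks entities by directed proximity", {
  g <- path_graph()
  cat_ <- path_catalog()  # I1={v4,v5}, I2={v3}, I3={v1}; D1={v4,v5}
  res <- reposition_for_disease("D1", "ingredient", cat_, g, n_null = 50, seed = 21)
  expect_s3_class(res, "screen_result")
  expect_equal(res$entity_id, c("I1", "I2", "I3"))
  expect_equal(res$distance, c(0, 1.5, 3.5))
  expect_equal(res$rank, 1:3)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$significant, res$p < 0.05)
  # an entity whose targets equal the disease genes sits at rank 1, distance 0
  expect_equal(res$distance[res$rank == 1L], 0)

  res2 <- reposition_for_disease("D1", "ingredient", cat_, g, n_null = 50, seed = 21)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("entity repositioning mirrors the screen over diseases", {
  g <- path_graph()
  cat_ <- load_catalog(
    data.frame(formula_id = "F1", herb_id = "H1"),
    data.frame(herb_id = "H1", ingredient_id = "I1"),
    data.frame(ingredient_id = c("I1", "I1"), protein_id = c("v4", "v5")),
    data.frame(disease_id = c("DA", "DA", "DB", "DC"),
               protein_id = c("v4", "v5", "v3", "v1"))
  )
  res <- reposition_for_entity("I1", "ingredient", cat_, g, n_null = 50, seed = 3)
  expect_equal(res$disease_id[res$rank == 1L], "DA")
  expect_equal(res$distance[res$rank == 1L], 0)
  # DB genes sit 1 hop from I1's targets, DC genes 3 hops
  expect_equal(res$distance[res$disease_id == "DB"], 1)
  expect_equal(res$distance[res$disease_id == "DC"], 3)
  expect_equal(res$disease_id, c("DA", "DB", "DC"))

  no_disease <- load_catalog(
    data.frame(formula_id = "F1", herb_id = "H1"),
    data.frame(herb_id = "H1", ingredient_id = "I1"),
    data.frame(ingredient_id = "I1", protein_id = "v1"),
    data.frame(disease_id = character(0), protein_id = character(0))
  )
  expect_error(reposition_for_entity("I1", "ingredient", no_disease, g, seed = 1),
               "no diseases")
})

test_that("catalog row order never changes ranks", {
  g <- path_graph()
  base <- list(
    data.frame(formula_id = c("F1", "F1"), herb_id = c("H1", "H2")),
    data.frame(herb_id = c("H1", "H1", "H2"), ingredient_id = c("I1", "I2", "I3")),
    data.frame(ingredient_id = c("I1", "I1", "I2", "I3"),
               protein_id = c("v4", "v5", "v3", "v1")),
    data.frame(disease_id = c("D1", "D1"), protein_id = c("v4", "v5"))
  )
  set.seed(77)
  shuffled <- lapply(base, function(df) df[sample.int(nrow(df)), , drop = FALSE])
  r1 <- reposition_for_disease("D1", "ingredient", do.call(load_catalog, base),
                               g, n_null = 40, seed = 5)
  r2 <- reposition_for_disease("D1", "ingredient", do.call(load_catalog, shuffled),
                               g, n_null = 40, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("entities without mappable targets are skipped and reported", {
  g <- path_graph()
  cat_ <- load_catalog(
    data.frame(formula_id = "F1", herb_id = "H1"),
    data.frame(herb_id = "H1", ingredient_id = c("I1", "I2", "I3")),
    data.frame(ingredient_id = c("I1", "I2", "I3"), protein_id = c("v1", "QQ", "v4")),
    data.frame(disease_id = "D1", protein_id = "v5")
  )
  res <- reposition_for_disease("D1", "ingredient", cat_, g, n_null = 30, seed = 2)
  expect_equal(res$entity_id, c("I3", "I1"))
  skipped <- attr(res, "skipped")
  expect_equal(skipped$entity_id, "I2")
  expect_match(skipped$reason, "no mappable targets")
})

test_that("the significance decision is monotone in distance for a fixed null", {
  scen <- generate_scenario(n_proteins = 300L, disease_module_size = 15L,
                            n_planted = 8L, n_background = 22L, seed = 61L)
  res <- reposition_for_disease("DIS1", "ingredient", scen$catalog, scen$graph,
                                n_null = 200, seed = 62)
  if (any(res$significant) && any(!res$significant)) {
    expect_lt(max(res$distance[res$significant]),
              min(res$distance[!res$significant]) + 1e-12)
  }
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("herb-frequency strata split at the median with ties going high", {
  # herbs H1..H4 occur in 1,1,2,5 formulas; median 1.5, HIGH = count >= 2
  fh <- data.frame(
    formula_id = c("FA", "FB", "FC", "FD", "FE", "FA", "FB", "FC", "FD"),
    herb_id = c("H4", "H4", "H4", "H4", "H4", "H1", "H2", "H3", "H3")
  )
  cat_ <- load_catalog(
    fh,
    data.frame(herb_id = c("H1", "H2", "H3", "H4"),
               ingredient_id = c("I1", "I2", "I3", "I4")),
    data.frame(ingredient_id = "I1", protein_id = "P1"),
    data.frame(disease_id = "D1", protein_id = "P1")
  )
  results <- data.frame(herb_id = c("H1", "H2", "H3", "H4"),
                        distance = c(2, 2, 1, 1))
  rep_ <- stratified_distance_report(results, cat_, "herb_frequency_median_split")
  s <- rep_$summary
  expect_equal(s$n[s$stratum == "high_frequency"], 2L)  # H3, H4
  expect_equal(s$n[s$stratum == "low_frequency"], 2L)
  expect_equal(s$median[s$stratum == "high_frequency"], 1)
})

test_that("formula-complexity strata and rank-sum behave on shifted data", {
  fh <- rbind(
    data.frame(formula_id = "Fsimple", herb_id = paste0("S", 1:3)),
    data.frame(formula_id = "Fcomplex", herb_id = paste0("C", 1:7))
  )
  cat_ <- load_catalog(
    fh,
    data.frame(herb_id = c(paste0("S", 1:3), paste0("C", 1:7)),
               ingredient_id = paste0("I", 1:10)),
    data.frame(ingredient_id = "I1", protein_id = "P1"),
    data.frame(disease_id = "D1", protein_id = "P1")
  )
  base <- c(1.1, 1.4, 1.9, 2.2, 2.8)
  results <- data.frame(
    formula_id = rep(c("Fsimple", "Fcomplex"), each = 5),
    distance = c(base, base + 1)
  )
  rep_ <- stratified_distance_report(results, cat_, "formula_complexity")
  s <- rep_$summary
  expect_equal(s$median[s$stratum == "complex"],
               s$median[s$stratum == "simple"] + 1)

  # identical distributions: the rank-sum test sees no difference
  same <- data.frame(formula_id = rep(c("Fsimple", "Fcomplex"), each = 5),
                     distance = c(base, base))
  rep2 <- stratified_distance_report(same, cat_, "formula_complexity")
  expect_gte(rep2$p_value, 0.9)

  # an empty stratum is reported with n = 0 and no test
  only <- data.frame(formula_id = rep("Fsimple", 5), distance = base)
  rep3 <- stratified_distance_report(only, cat_, "formula_complexity")
  expect_equal(rep3$summary$n[rep3$summary$stratum == "complex"], 0L)
  expect_true(is.na(rep3$p_value))
})

test_that("screen results round-trip through CSV plus provenance sidecar", {
  g <- path_graph()
  cat_ <- path_catalog()
  res <- reposition_for_disease("D1", "ingredient", cat_, g, n_null = 40, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_screen_result(res, path)
  back <- read_screen_result(path)
  expect_equal(back$entity_id, res$entity_id)
  expect_equal(back$distance, as.numeric(fmt <- sprintf("%.6f", res$distance)))
  expect_equal(back$significant, res$significant)
  prov <- attr(back, "provenance")
  expect_equal(prov$seed, 8L)
  expect_equal(prov$n, 40L)
  # writer is stable: writing what we read reproduces identical bytes
  first <- readLines(path)
  write_screen_result(res, path)
  expect_identical(readLines(path), first)
})
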