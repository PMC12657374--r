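test_that("formula scans evaluate every unordered in-formula pair", {
  g <- path_graph()
  # 3 usable ingredients -> C(3,2) = 3 candidate pairs
  cat_ <- path_catalog()
  hits <- formula_synergy_scan("F1", cat_, g, n_null = 60, seed = 14)
  expect_equal(attr(hits, "n_evaluated"), 3L)
  expect_true(all(diff(hits$distance) >= 0))
  expect_true(all(hits$p < 0.05))

  # two ingredients sharing all targets: distance 0, minimal possible
  cat0 <- load_catalog(
    data.frame(formula_id = "F1", herb_id = "H1"),
    data.frame(herb_id = "H1", ingredient_id = c("Ix", "Iy", "Iz")),
    data.frame(ingredient_id = c("Ix", "Ix", "Iy", "Iy", "Iz"),
               protein_id = c("v1", "v2", "v1", "v2", "v5")),
    data.frame(disease_id = "D1", protein_id = "v1")
  )
  null0 <- make_ref_null(c(1.5, 2.0, 2.5))  # mu 2, sigma 0.5
  hits0 <- formula_synergy_scan("F1", cat0, g, null = null0)
  expect_equal(hits0$distance[hits0$ingredient_a == "Ix" & hits0$ingredient_b == "Iy"], 0)

  one <- load_catalog(
    data.frame(formula_id = "F1", herb_id = "H1"),
    data.frame(herb_id = "H1", ingredient_id = "I1"),
    data.frame(ingredient_id = "I1", protein_id = "v1"),
    data.frame(disease_id = "D1", protein_id = "v1")
  )
  expect_error(formula_synergy_scan("F1", one, g, seed = 1), "fewer than 2")
})

test_that("a planted proximal pair is flagged while background pairs are not", {
  scen <- generate_scenario(seed = 42L)
  pp <- scen$truth$planted_pairs
  expect_gt(nrow(pp), 0L)
  f_of_pair <- NULL
  for (f in scen$catalog$formula_ids) {
    ings <- herbnet:::ingredients_of_formula(scen$catalog, f)
    if (pp$a[1L] %in% ings && pp$b[1L] %in% ings) { f_of_pair <- f; break }
  }
  hits <- formula_synergy_scan(f_of_pair, scen$catalog, scen$graph,
                               n_null = 300, seed = 7)
  key <- paste(hits$ingredient_a, hits$ingredient_b)
  in_formula <- pp[vapply(seq_len(nrow(pp)), function(k) {
    ings <- herbnet:::ingredients_of_formula(scen$catalog, f_of_pair)
    pp$a[k] %in% ings && pp$b[k] %in% ings
  }, logical(1L)), ]
  expect_gt(sum(paste(in_formula$a, in_formula$b) %in% key), 0L)
  # background-background pairs are mostly absent from the significant list
  bg <- scen$truth$background
  n_bg_hits <- sum(hits$ingredient_a %in% bg & hits$ingredient_b %in% bg)
  expect_lt(n_bg_hits / attr(hits, "n_evaluated"), 0.05)
})

test_that("two-way recommendation patterns produce a single scored edge", {
  g <- path_graph()
  cat_ <- path_catalog()
  ref <- list(ing_ing = make_ref_null(c(1.5, 2.0, 2.5)),
              herb_herb = make_ref_null(c(1.5, 2.0, 2.5), metric = "center"))
  land <- recommend("ingredient+ingredient", "I1", "I3", catalog = cat_,
                    graph = g, nulls = ref, seed = 5)
  expect_equal(nrow(land$nodes), 2L)
  expect_equal(nrow(land$edges), 1L)
  expect_equal(land$edges$relation, "ing-ing")
  expect_equal(land$edges$distance, closest_distance(c("v4", "v5"), "v1", g))

  # two herbs that are identical singletons: center distance 0
  cat2 <- load_catalog(
    data.frame(formula_id = "F1", herb_id = c("HA", "HB")),
    data.frame(herb_id = c("HA", "HB"), ingredient_id = c("IA", "IB")),
    data.frame(ingredient_id = c("IA", "IB"), protein_id = c("v2", "v2")),
    data.frame(disease_id = "D1", protein_id = "v1")
  )
  land2 <- recommend("herb+herb", "HA", "HB", catalog = cat2, graph = g,
                     nulls = ref, seed = 6)
  expect_equal(land2$edges$distance, 0)
  expect_equal(land2$edges$relation, "herb-herb")
})

test_that("three-way patterns attach disease edges for entities and ingredients", {
  g <- path_graph()
  cat_ <- load_catalog(
    data.frame(formula_id = "F1", herb_id = c("HA", "HB")),
    data.frame(herb_id = c("HA", "HB"), ingredient_id = c("IA", "IB")),
    data.frame(ingredient_id = c("IA", "IA", "IB", "IB"),
               protein_id = c("v4", "v5", "v3", "v4")),
    data.frame(disease_id = c("D1", "D1"), protein_id = c("v4", "v5"))
  )
  ref <- list(ing_ing = make_ref_null(c(1.5, 2.0, 2.5)),
              herb_herb = make_ref_null(c(1.5, 2.0, 2.5), metric = "center"),
              ing_disease = make_ref_null(c(1.5, 2.0, 2.5), metric = "disease"),
              herb_disease = make_ref_null(c(1.5, 2.0, 2.5), metric = "disease"))
  # disease genes a subset of IA's targets -> its disease edge is 0
  land <- recommend("ingredient+ingredient+disease", "IA", "IB", disease = "D1",
                    catalog = cat_, graph = g, nulls = ref, seed = 9)
  e <- land$edges
  expect_setequal(e$relation, c("ing-ing", "ing-disease"))
  expect_equal(e$distance[e$source == "IA" & e$relation == "ing-disease"], 0)
  expect_equal(sum(e$relation == "ing-disease"), 2L)

  land_h <- recommend("herb+herb+disease", "HA", "HB", disease = "D1",
                      catalog = cat_, graph = g, nulls = ref, seed = 9)
  expect_setequal(unique(land_h$edges$relation),
                  c("herb-herb", "herb-disease", "ing-disease"))
  expect_true(all(c("HA", "HB", "IA", "IB", "D1") %in% land_h$nodes$id))

  expect_error(recommend("herb+herb+disease", "HA", "HB", catalog = cat_, graph = g),
               "requires a disease")
  expect_error(recommend("nonsense", "a", "b", catalog = cat_, graph = g),
               "unknown pattern")
})

test_that("prescription patterns score cross-prescription pairs", {
  scen <- generate_scenario(n_proteins = 300L, disease_module_size = 15L,
                            n_planted = 6L, n_background = 14L,
                            ingredients_per_herb = 5L, herbs_per_formula = 2L,
                            seed = 33L)
  fids <- scen$catalog$formula_ids[1:2]
  land <- recommend("prescription+prescription+disease", fids[1L], fids[2L],
                    disease = "DIS1", catalog = scen$catalog, graph = scen$graph,
                    n_null = 100, seed = 44)
  expect_setequal(unique(land$edges$relation),
                  c("herb-herb", "ing-ing", "ing-disease", "herb-disease"))
  ia <- herbnet:::ingredients_of_formula(scen$catalog, fids[1L])
  ib <- herbnet:::ingredients_of_formula(scen$catalog, fids[2L])
  ii <- land$edges[land$edges$relation == "ing-ing", ]
  cross <- (ii$source %in% ia & ii$target %in% ib) |
           (ii$source %in% ib & ii$target %in% ia)
  expect_true(all(cross[!(ii$source %in% intersect(ia, ib) | ii$target %in% intersect(ia, ib))]))
  expect_true(all(land$edges$p >= 0 & land$edges$p <= 1))
  expect_true(all(is.finite(land$edges$distance)))
  expect_true(all(c(land$edges$source, land$edges$target) %in% land$nodes$id))
})

test_that("landscape graphs use the exponential weight transform", {
  g <- path_graph()
  cat_ <- path_catalog()
  land <- recommend("ingredient+ingredient", "I1", "I2", catalog = cat_,
                    graph = g, n_null = 40, seed = 5)
  gr <- build_combination_graph(land, significant_only = FALSE)
  d <- land$edges$distance
  expect_equal(igraph::E(gr)$weight, exp(-d))
  expect_equal(exp(-0), 1.0)
  expect_equal(exp(-1), 0.3678794, tolerance = 1e-6)
  # monotone: larger distance, smaller weight
  expect_true(all(diff(exp(-sort(c(0, d, d + 1)))) <= 0))
  expect_error(build_combination_graph(
    structure(list(nodes = land$nodes,
                   edges = land$edges[0, ], query = land$query),
              class = "combination_landscape")), "no ")
})

test_that("Louvain splits two bridged cliques exactly and deterministically", {
  g <- two_clique_graph()
  labels <- detect_modules(g, seed = 17)
  expect_equal(length(unique(labels)), 2L)
  expect_equal(length(unique(labels[paste0("a", 1:4)])), 1L)
  expect_equal(length(unique(labels[paste0("b", 1:4)])), 1L)
  expect_false(labels[["a1"]] == labels[["b1"]])
  expect_identical(labels, detect_modules(g, seed = 17))

  # exhaustive oracle: the clique split maximises modularity over all
  # partitions of the 8 nodes
  nodes <- igraph::V(g)$name
  best_q <- -Inf
  best_part <- NULL
  for (p in set_partitions(nodes)) {
    mem <- integer(length(nodes))
    names(mem) <- nodes
    for (j in seq_along(p)) mem[p[[j]]] <- j
    q <- igraph::modularity(g, mem[igraph::V(g)$name])
    if (q > best_q + 1e-12) { best_q <- q; best_part <- mem }
  }
  expect_equal(sort(unname(tapply(names(best_part), best_part, paste, collapse = ","))),
               c("a1,a2,a3,a4", "b1,b2,b3,b4"))
  expect_equal(igraph::modularity(g, labels[igraph::V(g)$name]), best_q)

  single <- igraph::graph_from_edgelist(t(combn(paste0("c", 1:4), 2)), directed = FALSE)
  igraph::E(single)$weight <- 1
  expect_equal(length(unique(detect_modules(single, seed = 1))), 1L)
})

test_that("disease module members share the disease node's community", {
  labels <- c(DIS = 1L, i1 = 1L, i2 = 1L, i3 = 2L, i4 = 2L)
  expect_equal(disease_module_members(labels, "DIS"), c("i1", "i2"))
  expect_equal(disease_module_members(c(DIS = 3L, i1 = 1L), "DIS"), character(0))
  expect_error(disease_module_members(labels, "missing"), "absent")

  # disease attached inside clique A of the two-clique fixture
  g <- two_clique_graph()
  g <- igraph::add_vertices(g, 1L, name = "DIS")
  g <- igraph::add_edges(g, c("DIS", "a1", "DIS", "a2", "DIS", "a3"))
  igraph::E(g)$weight <- 1
  lab <- detect_modules(g, seed = 3)
  expect_setequal(disease_module_members(lab, "DIS"), paste0("a", 1:4))
})

test_that("ADMET filtering applies conjuncts and reports exclusions", {
  tab <- read_admet_table(data.frame(
    ingredient_id = c("I1", "I2", "I3", "I4"),
    HIA = c("+", "+", "-", "+"),
    OB = c(40, 20, 50, 35),
    BBB = c("+", "+", "+", "-")
  ))
  spec <- parse_filter_spec(c("HIA eq +", "OB ge 30", "BBB eq +"), tab)
  expect_equal(c(admet_filter(tab, spec, c("I1", "I2", "I3", "I4"))), "I1")
  expect_equal(c(admet_filter(tab, parse_filter_spec(character(0))
                              , c("I1", "I2"))), c("I1", "I2"))

  # missing property value: excluded with a reason
  tab2 <- read_admet_table(data.frame(ingredient_id = c("I1", "I2"),
                                      HIA = c("+", NA)))
  surv <- quiet(admet_filter(tab2, parse_filter_spec("HIA eq +", tab2), c("I1", "I2")))
  expect_equal(c(surv), "I1")
  expect_match(attr(surv, "excluded")$reason, "missing property")

  expect_error(parse_filter_spec("NOPE eq +", tab), "unknown ADMET property")
  expect_error(parse_filter_spec("HIA gt +"), "unknown comparator")

  # antitone: adding a conjunct never grows the surviving set
  set.seed(90)
  big <- generate_admet_table(sprintf("X%02d", 1:40), seed = 12)
  s1 <- c(admet_filter(big, parse_filter_spec("HIA eq +"), big$ingredient_id))
  s2 <- c(admet_filter(big, parse_filter_spec(c("HIA eq +", "OB ge 30")), big$ingredient_id))
  s3 <- c(admet_filter(big, parse_filter_spec(c("HIA eq +", "OB ge 30", "BBB eq +")),
                       big$ingredient_id))
  expect_true(all(s2 %in% s1))
  expect_true(all(s3 %in% s2))
})

test_that("landscapes serialize to node-link JSON and edge CSV reproducibly", {
  g <- path_graph()
  cat_ <- path_catalog()
  land <- recommend("ingredient+ingredient+disease", "I1", "I2", disease = "D1",
                    catalog = cat_, graph = g, n_null = 40, seed = 5)
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "land.json")
  cp <- file.path(dir, "land.csv")
  write_landscape(land, jp, cp)
  back <- read_landscape(jp)
  expect_equal(back$edges$distance, land$edges$distance)
  expect_equal(back$edges$significant, land$edges$significant)
  expect_equal(back$nodes$id, land$nodes$id)
  expect_equal(back$query$pattern, land$query$pattern)

  # byte-identical when rebuilt with the same seed
  land2 <- recommend("ingredient+ingredient+disease", "I1", "I2", disease = "D1",
                     catalog = cat_, graph = g, n_null = 40, seed = 5)
  jp2 <- file.path(dir, "land2.json")
  write_landscape(land2, jp2, NULL)
  expect_identical(readLines(jp2), readLines(jp))
})

test_that("the disease module of a planted landscape contains the planted block", {
  scen <- generate_scenario(seed = 42L)
  land <- recommend("prescription+prescription+disease", "FORM01", "FORM02",
                    disease = "DIS1", catalog = scen$catalog, graph = scen$graph,
                    seed = 11, n_null = 500, include_within = TRUE)
  mem <- extract_disease_module(land, seed = 5)
  recovered <- mean(scen$truth$planted %in% mem)
  expect_gte(recovered, 0.8)
  expect_identical(c(mem), c(extract_disease_module(land, seed = 5)))
})
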