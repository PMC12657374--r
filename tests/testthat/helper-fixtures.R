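# Shared fixtures and independent oracles. The oracle shortest-path engine is
# a hand-written breadth-first search over an adjacency list, deliberately not
# igraph, so metric tests compare two independent routes.

path_graph <- function() {
  suppressMessages(load_interactome(data.frame(
    protein_a = c("v1", "v2", "v3", "v4"),
    protein_b = c("v2", "v3", "v4", "v5"),
    stringsAsFactors = FALSE
  )))
}

# catalog on the path graph: ingredients I1={v4,v5}, I2={v3}, I3={v1},
# herbs H1={I1,I2}, H2={I3}, formula F1={H1,H2}, disease D1={v4,v5}
path_catalog <- function() {
  load_catalog(
    data.frame(formula_id = c("F1", "F1"), herb_id = c("H1", "H2")),
    data.frame(herb_id = c("H1", "H1", "H2"), ingredient_id = c("I1", "I2", "I3")),
    data.frame(ingredient_id = c("I1", "I1", "I2", "I3"),
               protein_id = c("v4", "v5", "v3", "v1")),
    data.frame(disease_id = c("D1", "D1"), protein_id = c("v4", "v5"))
  )
}

# ---- independent oracle: hand-written BFS all-pairs hop counts ----

oracle_all_pairs <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(dist[[v]])) {
            dist[[v]] <- dist[[u]] + 1
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_closest <- function(D, A, B) {
  S <- D[A, B, drop = FALSE]
  (sum(apply(S, 1L, min)) + sum(apply(S, 2L, min))) / (length(A) + length(B))
}

oracle_shortest <- function(D, A, B) mean(D[A, B, drop = FALSE])

oracle_disease <- function(D, X, Y) mean(apply(D[Y, X, drop = FALSE], 1L, min))

# random connected graph built without igraph: a random tree plus extra edges
random_connected_edges <- function(n, extra = n) {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- to <- character(0)
  for (i in 2:n) {
    from <- c(from, nodes[sample.int(i - 1L, 1L)])
    to <- c(to, nodes[i])
  }
  for (k in seq_len(extra)) {
    p <- sample(nodes, 2L)
    if (p[1L] != p[2L]) {
      from <- c(from, p[1L])
      to <- c(to, p[2L])
    }
  }
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  keep <- !duplicated(paste(lo, hi))
  list(edges = cbind(lo[keep], hi[keep]), nodes = nodes)
}

two_clique_graph <- function() {
  cl <- function(v) t(combn(v, 2L))
  el <- rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)), c("a1", "b1"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- 1
  g
}

# all set partitions of a vector (Bell-number enumeration, fine for n <= 8)
set_partitions <- function(items) {
  if (length(items) == 1L) return(list(list(items)))
  rest <- set_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (j in seq_along(p)) {
      q <- p
      q[[j]] <- c(items[1L], q[[j]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1L]), p)
  }
  out
}

# rank-based AUC: probability a planted entity scores closer than a background
auc_planted <- function(distance, is_planted) {
  r <- rank(distance)
  n1 <- sum(is_planted)
  n0 <- sum(!is_planted)
  (sum(r[!is_planted]) - n0 * (n0 + 1) / 2) / (n1 * n0)
}

quiet <- function(expr) suppressMessages(expr)

# reference null model built directly from a value list (bypasses sampling)
make_ref_null <- function(values, metric = "closest") {
  structure(list(values = values, mu = mean(values), sigma = sd(values),
                 n = length(values), strategy = "random_pairs",
                 seed = NA_integer_, level = NULL, metric = metric),
            class = "null_model")
}
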