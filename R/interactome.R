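#' Load a protein-protein interactome from an edge table
#'
#' Reads a two-column edge table (`protein_a`, `protein_b`) into an undirected,
#' deduplicated interactome on which all shortest-path distances are computed.
#' Self-loops in the input are tolerated and dropped with a message; duplicate
#' edges (including reversed duplicates) are stored once.
#'
#' All downstream proximity metrics assume finite shortest paths, so by default
#' the graph is restricted to its largest connected component. With
#' `restrict_lcc = FALSE` a disconnected graph is kept as-is and any distance
#' query that hits an unreachable pair raises an error rather than silently
#' returning infinity.
#'
#' @param edges A data frame with two character columns, or the path to a
#'   CSV/TSV file with a mandatory header row.
#' @param restrict_lcc Keep only the largest connected component (ties broken
#'   by the component containing the lexicographically smallest node).
#' @return An object of class `interactome`: a list with elements `graph`
#'   (an [igraph][igraph::igraph-package] graph), `lcc_flag`, `n_dropped_nodes`
#'   and `n_self_loops`.
#' @examples
#' edges <- data.frame(protein_a = c("P1", "P2"), protein_b = c("P2", "P3"))
#' g <- load_interactome(edges)
#' interactome_nodes(g)
#' @export
load_interactome <- function(edges, restrict_lcc = TRUE) {
  if (is.character(edges)) edges <- read_edge_file(edges)
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stopf("interactome edge table must have two columns")
  }
  if (nrow(edges) == 0L) stopf("interactome edge table is empty")
  a <- trimws(as.character(edges[[1L]]))
  b <- trimws(as.character(edges[[2L]]))
  bad <- which(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b))
  if (length(bad)) {
    stopf("malformed interactome record at line %d: empty protein ID", bad[1L])
  }
  loops <- a == b
  n_loops <- sum(loops)
  a <- a[!loops]
  b <- b[!loops]
  if (!length(a)) stopf("interactome has no edges after dropping self-loops")
  # canonical unordered orientation, then dedup
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[keep]
  hi <- hi[keep]
  nodes <- sort(unique(c(lo, hi)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  n_dropped <- 0L
  if (restrict_lcc) {
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      sizes <- comp$csize
      best <- which(sizes == max(sizes))
      if (length(best) > 1L) {
        # tie-break: component containing the lexicographically smallest node
        firsts <- vapply(best, function(k) {
          min(nodes[comp$membership == k])
        }, character(1L))
        best <- best[order(firsts)][1L]
      }
      keep_nodes <- nodes[comp$membership == best]
      n_dropped <- length(nodes) - length(keep_nodes)
      g <- igraph::induced_subgraph(g, keep_nodes)
      message(sprintf("restricted to largest connected component: %d node(s) dropped",
                      n_dropped))
    }
  }
  if (n_loops > 0L) message(sprintf("dropped %d self-loop(s)", n_loops))
  structure(
    list(graph = g, lcc_flag = restrict_lcc, n_dropped_nodes = n_dropped,
         n_self_loops = n_loops),
    class = "interactome"
  )
}

read_edge_file <- function(path) {
  if (!file.exists(path)) stopf("interactome file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, colClasses = "character")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (x$lcc_flag) " (restricted to LCC)" else ""))
  invisible(x)
}

#' Node identifiers of an interactome
#' @param x An `interactome` object.
#' @return Character vector of protein node IDs, sorted.
#' @export
interactome_nodes <- function(x) {
  stopifnot(inherits(x, "interactome"))
  sort(igraph::V(x$graph)$name)
}

#' Edge table of an interactome
#'
#' Returns the canonical two-column edge table (`protein_a`, `protein_b`,
#' each edge once with `protein_a < protein_b`, rows sorted). Loading this
#' table back with [load_interactome()] reproduces an identical graph.
#'
#' @param x An `interactome` object.
#' @return A data frame with columns `protein_a`, `protein_b`.
#' @export
interactome_edges <- function(x) {
  stopifnot(inherits(x, "interactome"))
  e <- igraph::as_edgelist(x$graph, names = TRUE)
  out <- data.frame(protein_a = pmin(e[, 1L], e[, 2L]),
                    protein_b = pmax(e[, 1L], e[, 2L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interactome edge table to CSV
#' @param x An `interactome` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_interactome <- function(x, path) {
  write.csv(interactome_edges(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
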