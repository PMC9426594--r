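#' Build the genetic-interaction network
#'
#' Nodes are the screened genes (isolated nodes retained); each edge is a
#' significant interaction of one gene pair under one growth condition
#' that deviates from the multiplicative expectation by at least
#' `min_deviation`. The same pair can contribute several edges, one per
#' condition (a multigraph).
#'
#' @param interactions An `sga_interactions` object or its records tibble.
#' @param genes Node set; default all genes appearing in the records.
#' @param min_deviation Minimum `|observed/expected - 1|` for an edge.
#'   Default 0.15.
#' @param alpha Significance threshold (`q <= alpha`). Default 0.05.
#' @return An object of class `sga_network`: list with `nodes` (tibble
#'   `gene`, later `community`, `x`, `y`), `edges` (tibble `gene_a`,
#'   `gene_b`, `condition`, `class`, `deviation_ratio`, `q_value`), and
#'   `graph` (the igraph multigraph).
#' @export
build_network <- function(interactions, genes = NULL, min_deviation = 0.15,
                          alpha = 0.05) {
  rec <- if (inherits(interactions, "sga_interactions")) {
    tidy(interactions)
  } else {
    as_tibble(interactions)
  }
  if (is.null(genes)) genes <- sort(unique(c(rec$gene_a, rec$gene_b)))
  edges <- rec |>
    dplyr::filter(.data$testable, !is.na(.data$q_value),
                  .data$q_value <= alpha,
                  abs(.data$deviation_ratio - 1) >= min_deviation) |>
    dplyr::select("gene_a", "gene_b", "condition", "class",
                  "deviation_ratio", "q_value")
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  structure(
    list(nodes = tibble(gene = genes), edges = as_tibble(edges), graph = g,
         min_deviation = min_deviation, alpha = alpha),
    class = "sga_network"
  )
}

#' @export
print.sga_network <- function(x, ...) {
  cat(sprintf("<sga_network> %d genes, %d condition-level edges",
              nrow(x$nodes), nrow(x$edges)))
  if (!is.null(x$nodes$community)) {
    cat(sprintf(", %d communities", length(unique(x$nodes$community))))
  }
  cat("\n")
  invisible(x)
}

# Collapse per-condition multi-edges to a weighted simple graph
# (weight = number of conditions in which the pair interacts).
collapse_multiedges <- function(graph) {
  igraph::E(graph)$weight <- 1
  igraph::simplify(graph, edge.attr.comb = list(weight = "sum", "ignore"))
}

#' Detect gene communities by Louvain modularity maximization
#'
#' Multi-edges are first collapsed to weighted simple edges (weight =
#' number of shared interaction conditions), then the Louvain method
#' partitions the genes. Community ids are contiguous integers from 0.
#' Deterministic for a given seed.
#'
#' @param network An [build_network()] result.
#' @param seed Integer seed. Default 1.
#' @param resolution Louvain resolution parameter. Default 1.
#' @param isolated How to group edge-less genes: `"singleton"` (default,
#'   one community each, as Louvain leaves them) or `"lump"` (one shared
#'   catch-all community).
#' @return The network with `nodes$community` filled in and a
#'   `communities` named vector attached.
#' @export
detect_communities <- function(network, seed = 1, resolution = 1,
                               isolated = c("singleton", "lump")) {
  stopifnot(inherits(network, "sga_network"))
  isolated <- match.arg(isolated)
  g <- collapse_multiedges(network$graph)
  comm <- with_seed_if(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  member <- igraph::membership(comm)
  if (isolated == "lump") {
    deg <- igraph::degree(g)
    if (any(deg == 0)) member[deg == 0] <- max(member) + 1
  }
  # renumber contiguously from 0, stable in node order
  member <- as.integer(factor(member, levels = unique(member))) - 1L
  names(member) <- igraph::V(g)$name
  network$nodes$community <- unname(member[network$nodes$gene])
  network$communities <- member
  network
}

#' Force-directed network layout (Fruchterman-Reingold)
#'
#' Computes deterministic (seeded) Fruchterman-Reingold coordinates on the
#' collapsed weighted graph and centers them on the origin, so a single
#' node lands at (0, 0).
#'
#' @param network An [build_network()] result.
#' @param seed Integer seed. Default 1.
#' @param iterations Iterations of the spring simulation. Default 500.
#' @return The network with `nodes$x` and `nodes$y` filled in.
#' @export
layout_network <- function(network, seed = 1, iterations = 500) {
  stopifnot(inherits(network, "sga_network"))
  g <- collapse_multiedges(network$graph)
  xy <- with_seed_if(seed,
    igraph::layout_with_fr(g, niter = iterations))
  xy <- sweep(xy, 2, colMeans(xy))
  network$nodes$x <- xy[, 1]
  network$nodes$y <- xy[, 2]
  network
}

#' Export / import an interaction network
#'
#' GraphML keeps the full multigraph with edge attributes (`condition`,
#' `class`, `deviation_ratio`, `q_value`) and node attributes
#' (`community`, `x`, `y`) and round-trips through
#' [import_network()]. The TSV format writes the edge list (one row per
#' condition-level edge) plus a companion `<path>.nodes.tsv` with the
#' node table.
#'
#' @param network An `sga_network` (communities/layout optional).
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `export_network()` returns `path` invisibly;
#'   `import_network()` returns an `sga_network`.
#' @export
export_network <- function(network, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(network, "sga_network"))
  format <- match.arg(format)
  g <- network$graph
  for (attr in c("community", "x", "y")) {
    if (!is.null(network$nodes[[attr]])) {
      g <- igraph::set_vertex_attr(g, attr, value = network$nodes[[attr]])
    }
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(network$edges, path, na = "NA")
    readr::write_tsv(network$nodes, paste0(path, ".nodes.tsv"), na = "NA")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    edges <- as_tibble(igraph::as_data_frame(g, what = "edges")) |>
      dplyr::rename(gene_a = "from", gene_b = "to")
    nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices")) |>
      dplyr::rename(gene = "name")
  } else {
    edges <- readr::read_tsv(path, na = "NA", show_col_types = FALSE)
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"), na = "NA",
                             show_col_types = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
  }
  keep <- intersect(c("gene_a", "gene_b", "condition", "class",
                      "deviation_ratio", "q_value"), names(edges))
  structure(
    list(nodes = nodes, edges = edges[keep], graph = g,
         min_deviation = NA_real_, alpha = NA_real_),
    class = "sga_network"
  )
}
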