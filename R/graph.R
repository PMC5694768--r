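# Internal graph plumbing: edge tibbles <-> igraph, validation, local statistics.
#
# Convention: an edge table is a data frame with integer columns `from`, `to`
# (1-based node ids) and optionally `weight` (> 0, distance-like). Nodes are
# 1..n with n = max id unless `n` is given explicitly.

as_edge_tbl <- function(edges, require_weight = FALSE) {
  if (!is.data.frame(edges)) {
    abort("`edges` must be a data frame with columns `from` and `to`.")
  }
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  out <- tibble::as_tibble(edges)
  if (nrow(out) > 0 &&
      (any(out$from != as.integer(out$from)) || any(out$to != as.integer(out$to)))) {
    abort("Node ids in `from`/`to` must be integers.")
  }
  out$from <- as.integer(out$from)
  out$to <- as.integer(out$to)
  if (nrow(out) > 0 && (min(out$from, out$to) < 1L)) {
    abort("Node ids must be positive (1-based).")
  }
  if (require_weight && !"weight" %in% names(out)) {
    abort("`edges` must carry a `weight` column.")
  }
  if ("weight" %in% names(out) && any(!is.finite(out$weight) | out$weight <= 0)) {
    abort("Edge weights must be finite and positive.")
  }
  out
}

n_nodes <- function(edges, n = NULL) {
  if (!is.null(n)) return(as.integer(n))
  if (nrow(edges) == 0) abort("Cannot infer node count from an empty edge table.")
  max(edges$from, edges$to)
}

edges_to_igraph <- function(edges, n = NULL, weighted = FALSE) {
  edges <- as_edge_tbl(edges, require_weight = weighted)
  n <- n_nodes(edges, n)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  if (weighted) igraph::E(g)$weight <- edges$weight
  g
}

check_simple_connected <- function(g) {
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    abort("Graph must be simple: no self-loops or duplicate edges.")
  }
  if (igraph::vcount(g) > 1 && !igraph::is_connected(g)) {
    abort("Graph must be connected (a single component).")
  }
  invisible(g)
}

# Common-neighbour count for each edge of a simple graph.
edge_common_neighbours <- function(g, edges) {
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, as.integer)
  vapply(seq_len(nrow(edges)), function(k) {
    length(intersect(adj[[edges$from[k]]], adj[[edges$to[k]]]))
  }, integer(1))
}
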