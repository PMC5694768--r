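#' Distance kernels for dimension reduction
#'
#' Both kernels turn a weighted connected graph into a symmetric, zero-
#' diagonal all-pairs node distance matrix.
#'
#' * `shortest_path_kernel()` stores the weighted shortest-path (geodesic)
#'   distance between every node pair, the Isomap kernel.
#' * `mc_kernel()` is the minimum-curvilinear kernel: distances are summed
#'   along the unique path in the minimum spanning tree of the weighted
#'   graph, so every pairwise distance travels the MST "highway". Entries are
#'   never smaller than the corresponding shortest-path distances.
#'
#' @param edges Edge table (`from`, `to`, `weight`); use [preweight_edges()]
#'   to produce weights from an unweighted network (`rule = "NONE"` gives the
#'   hop-count kernels).
#' @return A dense symmetric `n x n` matrix with attribute
#'   `kernel` = `"shortest_path"` or `"minimum_curvilinear"`.
#' @export
#' @examples
#' el <- preweight_edges(toy_fixtures("path:3"), "NONE")
#' shortest_path_kernel(el)   # D[1,3] == 2
shortest_path_kernel <- function(edges) {
  edges <- as_edge_tbl(edges, require_weight = TRUE)
  g <- edges_to_igraph(edges, weighted = TRUE)
  check_simple_connected(g)
  D <- igraph::distances(g, weights = igraph::E(g)$weight, algorithm = "dijkstra")
  dimnames(D) <- NULL
  structure(D, kernel = "shortest_path")
}

#' @rdname shortest_path_kernel
#' @export
mc_kernel <- function(edges) {
  edges <- as_edge_tbl(edges, require_weight = TRUE)
  g <- edges_to_igraph(edges, weighted = TRUE)
  check_simple_connected(g)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  D <- igraph::distances(tree, weights = igraph::E(tree)$weight,
                         algorithm = "dijkstra")
  dimnames(D) <- NULL
  structure(D, kernel = "minimum_curvilinear")
}
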