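#' Pre-weight the edges of an unweighted network
#'
#' Converts an unweighted adjacency into positive, distance-suggesting edge
#' weights, the first step of coalescent embedding. Larger weight means
#' "geometrically farther".
#'
#' Rules (with \eqn{d_i} the degree of node *i*, \eqn{CN_{ij}} the number of
#' common neighbours of the edge's endpoints, and
#' \eqn{e_i = d_i - CN_{ij} - 1} the per-edge external degree, i.e. the
#' neighbours of *i* that are neither *j* nor shared with *j*):
#'
#' * `"RA1"` (repulsion–attraction, local):
#'   \eqn{w_{ij} = (d_i + d_j + d_i d_j) / (1 + CN_{ij})}
#' * `"RA2"`: \eqn{w_{ij} = (1 + e_i + e_j + e_i e_j) / (1 + CN_{ij})}
#' * `"EBC"` (global): edge betweenness centrality, the sum over unordered
#'   node pairs of the fraction of shortest paths traversing the edge
#'   (Brandes' algorithm).
#' * `"NONE"`: all weights 1.
#'
#' Hubs that share no neighbours repel (large weight, far apart); many common
#' neighbours attract (small weight, close).
#'
#' @param edges Edge table (`from`, `to`) of a simple connected graph.
#' @param rule One of `"RA1"`, `"RA2"`, `"EBC"`, `"NONE"` (case-insensitive).
#' @return The edge tibble with a `weight` column appended.
#' @export
#' @examples
#' preweight_edges(toy_fixtures("complete:3"), "RA1")  # every edge 4
preweight_edges <- function(edges, rule = c("RA1", "RA2", "EBC", "NONE")) {
  rule <- toupper(rule[1])
  rule <- match.arg(rule, c("RA1", "RA2", "EBC", "NONE"))
  edges <- as_edge_tbl(edges)
  g <- edges_to_igraph(edges)
  check_simple_connected(g)
  w <- switch(rule,
    NONE = rep(1, nrow(edges)),
    EBC = igraph::edge_betweenness(g, directed = FALSE),
    RA1 = ,
    RA2 = {
      d <- igraph::degree(g)
      cn <- edge_common_neighbours(g, edges)
      di <- d[edges$from]
      dj <- d[edges$to]
      if (rule == "RA1") {
        (di + dj + di * dj) / (1 + cn)
      } else {
        ei <- di - cn - 1
        ej <- dj - cn - 1
        (1 + ei + ej + ei * ej) / (1 + cn)
      }
    }
  )
  out <- edges
  out$weight <- as.numeric(w)
  out
}
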