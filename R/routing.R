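#' Greedy routing over an embedded network
#'
#' Simulates hyperbolic greedy routing for every ordered node pair: a packet
#' at the current node is forwarded to the neighbor at the lowest hyperbolic
#' distance from the destination (ties broken by lowest node id) and is
#' dropped when it would revisit a node — the greedy next hop depends only
#' on the current node, so a revisit (in particular, bouncing straight back)
#' means an endless loop.
#'
#' The GR-score averages \eqn{sp_{ij}/p_{ij}} over all ordered pairs, where
#' \eqn{sp_{ij}} is the shortest hop count and \eqn{p_{ij}} the greedy hop
#' count, with 0 for dropped packets: 1 means every packet is delivered
#' along a shortest path, 0 that nothing arrives.
#'
#' @param edges Edge table of a simple connected graph.
#' @param coords Coordinate table (`node`, `r`, `theta`, optional `phi`)
#'   covering every node.
#' @param zeta Curvature parameter.
#' @return A `greedy_routing_report`: list with `pairs` (tibble `source`,
#'   `target`, `delivered`, `hops`, `sp`), `success_rate`,
#'   `mean_hops_successful` and `gr_score`. `tidy()` returns the per-pair
#'   tibble, `glance()` the aggregates.
#' @export
#' @examples
#' net <- generate_pso(40, m = 2, temp = 0, seed = 5)
#' glance(greedy_routing(net$edges, net$coords))
greedy_routing <- function(edges, coords, zeta = 1) {
  edges <- as_edge_tbl(edges)
  n <- n_nodes(edges)
  if (!all(seq_len(n) %in% coords$node) || nrow(coords) < n) {
    abort("`coords` must provide coordinates for every node.")
  }
  coords <- coords[match(seq_len(n), coords$node), ]
  g <- edges_to_igraph(edges, n = n)
  check_simple_connected(g)
  H <- pairwise_hyperbolic_distances(coords, zeta = zeta)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                function(v) sort(as.integer(v)))
  P <- greedy_route_all(adj, H)
  SP <- igraph::distances(g, algorithm = "unweighted")

  off <- row(P) != col(P)
  src <- row(P)[off]; tgt <- col(P)[off]
  hops <- P[off]; sp <- SP[off]
  delivered <- hops > 0
  pairs <- tibble::tibble(
    source = src, target = tgt, delivered = delivered,
    hops = ifelse(delivered, hops, NA_integer_), sp = as.integer(sp))
  structure(list(
    pairs = pairs,
    success_rate = mean(delivered),
    mean_hops_successful = if (any(delivered)) mean(hops[delivered]) else NA_real_,
    gr_score = mean(ifelse(delivered, sp / hops, 0))),
    class = "greedy_routing_report")
}

# Greedy routing over all ordered pairs. `adj` holds ascending 1-based
# neighbor lists; `H` the pairwise hyperbolic distances. Returns hop counts,
# -1 for drops, 0 on the diagonal. The greedy next hop depends only on
# (current node, destination), so it is precomputed per destination and any
# revisit along a trajectory implies an endless loop (the immediate-return
# two-cycle of the classic drop rule being the usual case).
greedy_route_all <- function(adj, H) {
  n <- nrow(H)
  P <- matrix(0L, n, n)
  stamp <- integer(n)
  pair_id <- 0L
  for (t in seq_len(n)) {
    Ht <- H[, t]
    nxt <- vapply(adj, function(nb) nb[which.min(Ht[nb])], integer(1))
    for (s in seq_len(n)) {
      if (s == t) next
      pair_id <- pair_id + 1L
      cur <- s
      hops <- 0L
      res <- -1L
      stamp[s] <- pair_id
      repeat {
        nx <- nxt[cur]
        hops <- hops + 1L
        if (nx == t) {
          res <- hops
          break
        }
        if (stamp[nx] == pair_id) break
        stamp[nx] <- pair_id
        cur <- nx
      }
      P[s, t] <- res
    }
  }
  P
}

#' @export
print.greedy_routing_report <- function(x, ...) {
  cat(sprintf(
    "Greedy routing: %.1f%% delivered, mean successful hops %.2f, GR-score %.4f\n",
    100 * x$success_rate, x$mean_hops_successful, x$gr_score))
  invisible(x)
}

#' @export
tidy.greedy_routing_report <- function(x, ...) x$pairs

#' @export
glance.greedy_routing_report <- function(x, ...) {
  tibble::tibble(success_rate = x$success_rate,
                 mean_hops_successful = x$mean_hops_successful,
                 gr_score = x$gr_score)
}
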