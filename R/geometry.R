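#' Hyperbolic distance between points of the native disk/ball
#'
#' Distance in the native representation of the hyperbolic space of
#' curvature \eqn{K = -\zeta^2}, by the hyperbolic law of cosines
#' \deqn{\cosh(\zeta h) = \cosh(\zeta r_a)\cosh(\zeta r_b) -
#'       \sinh(\zeta r_a)\sinh(\zeta r_b)\cos\Delta\theta}
#' where \eqn{\Delta\theta} is the central angle between the two points: the
#' angular separation in 2D, the great-circle angle of the (polar, azimuth)
#' directions in 3D (spherical law of cosines). Vectorized over points.
#'
#' @param r1,r2 Radial coordinates (>= 0).
#' @param theta1,theta2 Angular coordinates (2D) or azimuths (3D).
#' @param phi1,phi2 Optional polar angles in `[0, pi]` for 3D points.
#' @param zeta Curvature parameter \eqn{\zeta = \sqrt{-K} > 0}.
#' @return Nonnegative distance(s); 0 iff the coordinates coincide;
#'   `|r1 - r2|` when the central angle is 0.
#' @export
#' @examples
#' hyperbolic_distance(1, 0, 1, pi)  # ~2.0000
hyperbolic_distance <- function(r1, theta1, r2, theta2,
                                phi1 = NULL, phi2 = NULL, zeta = 1) {
  if (zeta <= 0) abort("`zeta` must be positive.")
  if (is.null(phi1) != is.null(phi2)) {
    abort("Provide polar angles for both points or neither.")
  }
  if (is.null(phi1)) {
    dtheta <- abs(theta1 - theta2) %% (2 * pi)
    cosang <- cos(pmin(dtheta, 2 * pi - dtheta))
  } else {
    cosang <- cos(phi1) * cos(phi2) + sin(phi1) * sin(phi2) * cos(theta1 - theta2)
    cosang <- pmin(1, pmax(-1, cosang))
  }
  a <- zeta * r1
  b <- zeta * r2
  arg <- cosh(a) * cosh(b) - sinh(a) * sinh(b) * cosang
  h <- acosh(pmax(1, arg)) / zeta
  # collinear geodesics analytically, avoiding acosh cancellation near 1
  exact <- cosang >= 1 - 1e-15
  if (any(exact)) {
    h[exact] <- (abs(r1 - r2) + 0 * h)[exact]
  }
  h
}

#' All-pairs hyperbolic distance matrix
#'
#' @param coords Coordinate table with columns `r`, `theta` and optionally
#'   `phi` (3D), one row per node (e.g. [tidy()] of an embedding).
#' @param zeta Curvature parameter.
#' @return Symmetric zero-diagonal `n x n` matrix.
#' @export
pairwise_hyperbolic_distances <- function(coords, zeta = 1) {
  stopifnot(all(c("r", "theta") %in% names(coords)))
  n <- nrow(coords)
  r <- coords$r
  theta <- coords$theta
  if ("phi" %in% names(coords)) {
    phi <- coords$phi
    cosang <- outer(cos(phi), cos(phi)) +
      outer(sin(phi), sin(phi)) * cos(outer(theta, theta, "-"))
    cosang <- pmin(1, pmax(-1, cosang))
  } else {
    dt <- abs(outer(theta, theta, "-")) %% (2 * pi)
    cosang <- cos(pmin(dt, 2 * pi - dt))
  }
  ch <- cosh(zeta * r)
  sh <- sinh(zeta * r)
  arg <- outer(ch, ch) - outer(sh, sh) * cosang
  arg[arg < 1] <- 1
  H <- acosh(arg) / zeta
  exact <- cosang >= 1 - 1e-15
  if (any(exact)) {
    Drad <- abs(outer(r, r, "-"))
    H[exact] <- Drad[exact]
  }
  diag(H) <- 0
  H
}

#' Geometric edge weights for community detection
#'
#' Weights the adjacency of an embedded network by hyperbolic proximity, the
#' pre-processing that boosts off-the-shelf community detection. Observed
#' edges get \eqn{x^{HD}_{ij} = 1/(1 + HD_{ij})} with \eqn{HD_{ij}} the
#' hyperbolic distance between the endpoints. In `mode = "observed_plus_hsp"`
#' non-adjacent pairs additionally get \eqn{x^{HSP}_{ij} = 1/(1 + HSP_{ij})},
#' where \eqn{HSP_{ij}} is the sum of hyperbolic distances along the
#' shortest path over observed edges — by default the path minimizing total
#' hyperbolic length (`hsp_basis = "weighted"`); `hsp_basis = "hops"` sums
#' the distances along a minimum-hop path instead.
#'
#' @param edges Edge table of the (connected, simple) network.
#' @param coords Coordinate table (`node`, `r`, `theta`, optional `phi`)
#'   covering every node.
#' @param mode `"observed_only"` or `"observed_plus_hsp"`.
#' @param hsp_basis Shortest-path basis for the non-observed pairs, see above.
#' @param zeta Curvature parameter.
#' @return Symmetric `n x n` matrix with entries in `(0, 1]` on weighted
#'   pairs, 1 on the diagonal (distance 0, by convention) and 0 on pairs left
#'   unweighted in `"observed_only"` mode.
#' @export
geometric_weights <- function(edges, coords,
                              mode = c("observed_only", "observed_plus_hsp"),
                              hsp_basis = c("weighted", "hops"), zeta = 1) {
  mode <- match.arg(mode)
  hsp_basis <- match.arg(hsp_basis)
  edges <- as_edge_tbl(edges)
  n <- n_nodes(edges)
  if (!all(seq_len(n) %in% coords$node) || nrow(coords) < n) {
    abort("`coords` must provide coordinates for every node.")
  }
  coords <- coords[match(seq_len(n), coords$node), ]
  g <- edges_to_igraph(edges, n = n)
  check_simple_connected(g)
  H <- pairwise_hyperbolic_distances(coords, zeta = zeta)
  hd <- H[cbind(edges$from, edges$to)]
  W <- matrix(0, n, n)
  idx <- cbind(edges$from, edges$to)
  W[idx] <- 1 / (1 + hd)
  W[idx[, 2:1, drop = FALSE]] <- 1 / (1 + hd)
  if (mode == "observed_plus_hsp") {
    if (hsp_basis == "weighted") {
      HSP <- igraph::distances(g, weights = hd, algorithm = "dijkstra")
    } else {
      HSP <- hop_path_hd_sums(g, H)
    }
    unobserved <- W == 0
    W[unobserved] <- 1 / (1 + HSP[unobserved])
  }
  diag(W) <- 1
  dimnames(W) <- NULL
  structure(W, mode = mode)
}

# Sum of hyperbolic distances along one BFS-shortest (minimum hop) path per
# pair; igraph's deterministic path choice fixes ties.
hop_path_hd_sums <- function(g, H) {
  n <- igraph::vcount(g)
  out <- matrix(0, n, n)
  for (s in seq_len(n - 1)) {
    paths <- igraph::shortest_paths(g, from = s, to = (s + 1):n,
                                    output = "vpath")$vpath
    for (k in seq_along(paths)) {
      vp <- as.integer(paths[[k]])
      tot <- sum(H[cbind(vp[-length(vp)], vp[-1])])
      t <- s + k
      out[s, t] <- tot
      out[t, s] <- tot
    }
  }
  out
}
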