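#' Degree-based radial coordinates
#'
#' Assigns each node the radius it would have in a popularity-fading growth
#' process: nodes are sorted by descending degree (ties by ascending node
#' id) and the node of rank *i* gets
#' \deqn{r_i = \frac{2}{\zeta}\left[\beta \ln i + (1-\beta)\ln n\right]}
#' with \eqn{\beta = 1/(\gamma - 1)} the popularity-fading parameter derived
#' from the degree-distribution exponent \eqn{\gamma}. High-degree (old,
#' popular) nodes sit near the disk center.
#'
#' @param edges Edge table of the network.
#' @param gamma Power-law degree exponent (> 1); fit it with
#'   [fit_degree_exponent()] when unknown.
#' @param zeta Curvature parameter (> 0).
#' @return Numeric vector of radii indexed by node id.
#' @export
#' @examples
#' radial_coordinates(toy_fixtures("star:4"), gamma = 2.5)
radial_coordinates <- function(edges, gamma, zeta = 1) {
  if (gamma <= 1) abort("`gamma` must exceed 1.")
  if (zeta <= 0) abort("`zeta` must be positive.")
  edges <- as_edge_tbl(edges)
  g <- edges_to_igraph(edges)
  d <- igraph::degree(g)
  n <- length(d)
  beta <- 1 / (gamma - 1)
  ord <- order(-d, seq_len(n))
  r <- numeric(n)
  r[ord] <- (2 / zeta) * (beta * log(seq_len(n)) + (1 - beta) * log(n))
  r
}
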