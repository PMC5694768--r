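#' HyperMap maximum-likelihood embedding (baseline)
#'
#' Embeds a network in the 2D hyperbolic disk by replaying its growth under
#' the popularity-similarity model and placing each node at the angle that
#' maximizes the likelihood of its observed connections. Nodes are sorted by
#' descending degree (ties by ascending id) and labeled `i = 1..n`; node 1
#' is born at radius zero with a random angle; each later node gets
#' \eqn{r_i = (2/\zeta)\ln i}, earlier radii fade as
#' \eqn{r_j(i) = \beta r_j + (1-\beta) r_i}, and the angle is chosen on a
#' grid of `n` candidates spaced \eqn{2\pi/n} to maximize the Bernoulli
#' likelihood \eqn{L_i = \prod_{j<i} p(h_{ij})^{x_{ij}}
#' (1-p(h_{ij}))^{1-x_{ij}}} with [connection_probability()] and the PSO
#' disk radius \eqn{R_i}. The log-likelihood is accumulated with
#' probabilities clamped to `[1e-12, 1 - 1e-12]`. The only randomness is the
#' first node's angle (and none of the grid search), so results are
#' reproducible given `seed`.
#'
#' @param edges Edge table of a simple connected graph.
#' @param m Half average degree assumed by the model.
#' @param temp Temperature (> 0; the likelihood model is undefined at 0).
#' @param gamma Degree-distribution exponent (> 1).
#' @param zeta Curvature parameter.
#' @param seed Optional integer seed.
#' @return A `hyper_embedding` object (see [embed_network()]) with
#'   `config$method = "hypermap"`.
#' @export
#' @examples
#' net <- generate_pso(60, m = 2, temp = 0.3, seed = 3)
#' hm <- hypermap_embed(net$edges, m = 2, temp = 0.3, gamma = 2.5, seed = 3)
hypermap_embed <- function(edges, m, temp, gamma, zeta = 1, seed = NULL) {
  if (temp <= 0) abort("HyperMap requires `temp` > 0.")
  if (temp >= 1) abort("The disk-radius normalization requires `temp` < 1.")
  if (gamma <= 1) abort("`gamma` must exceed 1.")
  edges <- as_edge_tbl(edges)
  g <- edges_to_igraph(edges)
  check_simple_connected(g)
  if (!is.null(seed)) set.seed(seed)

  n <- igraph::vcount(g)
  beta <- 1 / (gamma - 1)
  deg <- igraph::degree(g)
  ord <- order(-deg, seq_len(n))        # original id of rank i
  A <- matrix(FALSE, n, n)
  A[cbind(edges$from, edges$to)] <- TRUE
  A[cbind(edges$to, edges$from)] <- TRUE
  A <- A[ord, ord, drop = FALSE]        # adjacency in rank order

  grid <- 2 * pi * (seq_len(n) - 1) / n
  theta <- numeric(n)
  theta[1] <- runif(1, 0, 2 * pi)
  for (i in seq_len(n)[-1]) {
    r_i <- (2 / zeta) * log(i)
    j <- seq_len(i - 1)
    r_j <- (2 / zeta) * (beta * log(j) + (1 - beta) * log(i))
    R_i <- pso_disk_radius(i, m, temp, beta, zeta)
    cosang <- cos(outer(grid, theta[j], "-"))
    arg <- cosh(zeta * r_i) * cosh(zeta * r_j)[col(cosang)] -
      sinh(zeta * r_i) * sinh(zeta * r_j)[col(cosang)] * cosang
    arg[arg < 1] <- 1
    h <- acosh(arg) / zeta
    p <- 1 / (1 + exp((h - R_i) / (2 * temp)))
    p[p < 1e-12] <- 1e-12
    p[p > 1 - 1e-12] <- 1 - 1e-12
    x <- A[i, j]
    ll <- log(p) %*% x + log1p(-p) %*% (1 - x)
    theta[i] <- grid[which.max(ll)]
  }

  i <- seq_len(n)
  r_final <- (2 / zeta) * (beta * log(i) + (1 - beta) * log(n))
  coords <- tibble::tibble(node = ord, r = r_final, theta = theta)
  coords <- coords[order(coords$node), ]
  new_hyper_embedding(coords,
    config = list(method = "hypermap", preweight = NA_character_,
                  reducer = NA_character_, adjust = NA_character_,
                  dims = 2, gamma = gamma, zeta = zeta, m = m, temp = temp))
}
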