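#' Generate a popularity-similarity-optimization (PSO) network
#'
#' Grows a random geometric graph on the native hyperbolic disk. At time
#' `i = 1..n` a new node appears at radius \eqn{r_i = (2/\zeta)\ln i} with an
#' angle drawn uniformly on `[0, 2*pi)`; every earlier node `j` fades in
#' popularity, drifting outward to \eqn{r_j(i) = \beta r_j + (1-\beta) r_i}.
#' At temperature `temp = 0` the newcomer links to the `min(i-1, m)`
#' hyperbolically closest nodes (ties broken by earliest birth); at
#' `temp > 0` it repeatedly samples a not-yet-linked existing node uniformly
#' and accepts it with probability [connection_probability()] until
#' `min(i-1, m)` links are made. The resulting degree distribution follows a
#' power law with exponent \eqn{\gamma = 1 + 1/\beta}; clustering is maximal
#' at `temp = 0` and decreases with temperature.
#'
#' The current disk radius entering the connection probability is
#' \deqn{R_i = r_i - \frac{2}{\zeta}\ln\!\left[\frac{2T\,(1 - i^{-(1-\beta)})}
#'       {\sin(T\pi)\, m\, (1-\beta)}\right]}
#' (with its closed-form \eqn{\beta \to 1} limit), the standard PSO
#' normalization that yields average degree close to `2m`. It requires
#' `temp < 1`, the regime of all experiments shipped with the package.
#'
#' @param n Number of nodes (>= 1).
#' @param m Half the target average degree (positive integer).
#' @param temp Temperature, in `[0, 1)`.
#' @param gamma Target power-law exponent (> 1); mutually consistent with
#'   `beta` via `gamma = 1 + 1/beta`. Supply one of the two.
#' @param beta Popularity-fading parameter in `(0, 1]`; overrides `gamma`
#'   when given.
#' @param zeta Curvature parameter \eqn{\sqrt{-K}} (> 0).
#' @param seed Optional integer seed; equal seeds reproduce the network and
#'   coordinates exactly.
#' @return A `pso_network` object: list with `edges` (tibble `from`, `to`),
#'   `coords` (tibble `node`, `r`, `theta`, the ground-truth coordinates at
#'   final time) and `params`.
#' @export
#' @examples
#' net <- generate_pso(100, m = 2, temp = 0, seed = 1)
#' nrow(net$edges)  # 2*100 - 3 = 197
generate_pso <- function(n, m = 2, temp = 0, gamma = 2.5, beta = NULL,
                         zeta = 1, seed = NULL) {
  if (is.null(beta)) {
    if (gamma <= 1) abort("`gamma` must exceed 1.")
    beta <- 1 / (gamma - 1)
  }
  gamma <- 1 + 1 / beta
  if (length(n) != 1 || n < 1 || n != as.integer(n)) {
    abort("`n` must be a positive integer.")
  }
  if (length(m) != 1 || m < 1 || m != as.integer(m)) {
    abort("`m` must be a positive integer.")
  }
  if (beta <= 0 || beta > 1) abort("`beta` must lie in (0, 1].")
  if (temp < 0) abort("`temp` must be nonnegative.")
  if (temp > 0 && temp >= 1) {
    abort("The connection-probability normalization requires `temp` < 1.")
  }
  if (zeta <= 0) abort("`zeta` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  theta <- runif(n, 0, 2 * pi)
  el <- pso_grow(n, as.integer(m), temp, beta, zeta, theta)
  i <- seq_len(n)
  coords <- tibble::tibble(
    node = i,
    r = beta * (2 / zeta) * log(i) + (1 - beta) * (2 / zeta) * log(n),
    theta = theta)
  structure(list(
    edges = tibble::tibble(from = el[, 1], to = el[, 2]),
    coords = coords,
    params = list(n = n, m = as.integer(m), temp = temp, beta = beta,
                  gamma = gamma, zeta = zeta, seed = seed)),
    class = "pso_network")
}

#' PSO / HyperMap connection probability
#'
#' Probability that a newborn node links to an existing node at hyperbolic
#' distance `h` when the current disk radius is `disk_radius`:
#' \deqn{p(h) = \frac{1}{1 + \exp\left(\frac{h - R_i}{2T}\right)}}
#' Monotonically decreasing in `h`, equal to 1/2 at `h = disk_radius`.
#' Only defined for `temp > 0`; at zero temperature linking is the
#' deterministic closest-node rule and callers must not use this function.
#'
#' @param h Hyperbolic distance(s).
#' @param disk_radius Current radius \eqn{R_i} of the growing disk.
#' @param temp Temperature (> 0).
#' @return Probabilities in `(0, 1)`.
#' @export
#' @examples
#' connection_probability(3, disk_radius = 3, temp = 0.5)  # 0.5
connection_probability <- function(h, disk_radius, temp) {
  if (temp <= 0) {
    abort("`temp` must be > 0; at temp = 0 use the deterministic closest-node rule.")
  }
  1 / (1 + exp((h - disk_radius) / (2 * temp)))
}

#' Current disk radius of the growing PSO disk
#'
#' The normalization \eqn{R_i} entering [connection_probability()] at growth
#' step `i` (see [generate_pso()] for the formula and its `beta = 1` limit).
#'
#' @param i Growth step (node birth index, >= 2).
#' @param m Half average degree.
#' @param temp Temperature in `(0, 1)`.
#' @param beta Popularity-fading parameter in `(0, 1]`.
#' @param zeta Curvature parameter.
#' @return The disk radius \eqn{R_i}.
#' @export
pso_disk_radius <- function(i, m, temp, beta, zeta = 1) {
  if (temp <= 0 || temp >= 1) abort("`temp` must lie in (0, 1).")
  r_i <- (2 / zeta) * log(i)
  fade <- if (beta == 1) log(i) else (1 - i^(-(1 - beta))) / (1 - beta)
  r_i - (2 / zeta) * log(2 * temp * fade / (sin(temp * pi) * m))
}

# Growth loop of the PSO model. Node i arrives at radius (2/zeta)*log(i);
# earlier radii fade; links are the m closest nodes (T = 0) or drawn by
# uniform candidate sampling with acceptance probability p(h) (T > 0).
pso_grow <- function(n, m, temp, beta, zeta, theta) {
  total <- sum(pmin(seq_len(n) - 1L, m))
  ef <- integer(total)
  et <- integer(total)
  ptr <- 0L
  if (n < 2) return(cbind(from = integer(0), to = integer(0)))
  for (i in 2:n) {
    links <- min(i - 1L, m)
    if (i - 1L <= m) {
      sel <- seq_len(i - 1L)
    } else {
      r_new <- (2 / zeta) * log(i)
      j <- seq_len(i - 1L)
      r_j <- (2 / zeta) * (beta * log(j) + (1 - beta) * log(i))
      h <- hyperbolic_distance(r_new, theta[i], r_j, theta[j], zeta = zeta)
      if (temp == 0) {
        sel <- j[order(h, j)[seq_len(links)]]
      } else {
        R_i <- pso_disk_radius(i, m, temp, beta, zeta)
        p <- 1 / (1 + exp((h - R_i) / (2 * temp)))
        sel <- sample_accepted(p, links, h)
      }
    }
    idx <- ptr + seq_along(sel)
    ef[idx] <- sel
    et[idx] <- i
    ptr <- ptr + length(sel)
  }
  cbind(from = ef, to = et)
}

# Draws the T > 0 link set: the model repeatedly samples a candidate
# uniformly among the not-yet-linked nodes and accepts it with probability
# p. The first acceptance lands on node j with probability p_j / sum(p), and
# the argument repeats on the shrunken pool, so the accepted set is exactly a
# successive weighted sample without replacement with weights p — drawn here
# in closed form. Distances `h` break the degenerate case where fewer than m
# weights survive in floating point (p underflows for far nodes at low T):
# the vanishing-weight candidates are then ranked by distance, the limit
# behavior of the acceptance process.
sample_accepted <- function(p, m, h) {
  pos <- which(p > 0)
  if (length(pos) >= m) {
    return(sort(sample.int(length(p), m, replace = FALSE, prob = p)))
  }
  rest <- order(p, -h, decreasing = TRUE)
  rest <- setdiff(rest, pos)
  sort(c(pos, rest[seq_len(m - length(pos))]))
}

#' @export
print.pso_network <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "PSO network: %d nodes, %d edges (m = %d, T = %g, gamma = %g, zeta = %g)\n",
    p$n, nrow(x$edges), p$m, p$temp, p$gamma, p$zeta))
  invisible(x)
}

#' @export
tidy.pso_network <- function(x, ...) x$coords

#' @export
glance.pso_network <- function(x, ...) {
  g <- edges_to_igraph(x$edges, n = x$params$n)
  tibble::tibble(
    n = x$params$n, m = x$params$m, temp = x$params$temp,
    gamma = x$params$gamma, zeta = x$params$zeta,
    n_edges = nrow(x$edges),
    mean_degree = mean(igraph::degree(g)),
    mean_clustering = igraph::transitivity(g, type = "localaverage",
                                           isolates = "zero"))
}
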