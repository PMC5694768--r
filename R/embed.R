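#' Coalescent embedding of a network into hyperbolic space
#'
#' The full pipeline: pre-weight the edges ([preweight_edges()]), build the
#' distance kernel or heat-weighted Laplacian, reduce dimension
#' ([reduce_embedding()]), assign angular coordinates
#' ([circular_adjustment()], optionally [equidistant_adjustment()]) and
#' radial coordinates ([radial_coordinates()]). The pipeline contains no
#' random stage: repeated runs on the same input are identical.
#'
#' If `edges` carries a `weight` column the user weights are adopted
#' directly and `preweight` is ignored (they are assumed distance-like:
#' larger = farther).
#'
#' @param edges Edge table (`from`, `to`, optional `weight`) of a simple
#'   connected graph.
#' @param preweight Pre-weighting rule, see [preweight_edges()].
#' @param reducer Dimension-reduction engine, see [reduce_embedding()].
#' @param adjust `"CA"` (circular) or `"EA"` (equidistant) angular
#'   adjustment; `"EA"` is 2D-only.
#' @param dims Ambient dimension, 2 or 3 (3 only for ISO/ncISO/LE; the 3D
#'   angles are the spherical polar/azimuth angles of the reduced points).
#' @param gamma Degree-distribution exponent used for the radii; when `NULL`
#'   it is fitted from the degree sequence with [fit_degree_exponent()].
#' @param zeta Curvature parameter.
#' @return A `hyper_embedding` object: list with `coords` (tibble `node`,
#'   `r`, `theta`, plus `phi` for 3D) and `config` (all settings, for
#'   provenance). `tidy()` returns the coordinate tibble, `glance()` a
#'   one-row summary, `autoplot()` a polar scatter of the disk.
#' @export
#' @examples
#' net <- generate_pso(60, m = 2, temp = 0, seed = 7)
#' emb <- embed_network(net$edges, preweight = "RA1", reducer = "ncMCE",
#'                      adjust = "EA", gamma = 2.5)
#' head(tidy(emb))
embed_network <- function(edges, preweight = c("RA1", "RA2", "EBC", "NONE"),
                          reducer = c("ncMCE", "MCE", "ISO", "ncISO", "LE"),
                          adjust = c("EA", "CA"), dims = 2,
                          gamma = NULL, zeta = 1) {
  reducer <- match.arg(toupper(reducer[1]), c("NCMCE", "MCE", "ISO", "NCISO", "LE"))
  reducer <- c(NCMCE = "ncMCE", MCE = "MCE", ISO = "ISO",
               NCISO = "ncISO", LE = "LE")[[reducer]]
  adjust <- match.arg(toupper(adjust[1]), c("EA", "CA"))
  if (!dims %in% c(2, 3)) abort("`dims` must be 2 or 3.")
  if (dims == 3 && adjust == "EA") {
    abort("Equidistant adjustment is defined for 2D embeddings only.")
  }
  edges <- as_edge_tbl(edges)
  g <- edges_to_igraph(edges)
  check_simple_connected(g)

  user_weighted <- "weight" %in% names(edges)
  if (user_weighted) {
    preweight <- "user"
    wedges <- edges
  } else {
    preweight <- match.arg(toupper(preweight[1]), c("RA1", "RA2", "EBC", "NONE"))
    wedges <- preweight_edges(edges, preweight)
  }

  reduced <- switch(reducer,
    LE = reduce_embedding(wedges, "LE", dims),
    ISO = ,
    ncISO = reduce_embedding(shortest_path_kernel(wedges), reducer, dims),
    MCE = ,
    ncMCE = reduce_embedding(mc_kernel(wedges), reducer, dims))

  n <- n_nodes(edges)
  if (dims == 2) {
    theta <- circular_adjustment(reduced)
    if (adjust == "EA") theta <- equidistant_adjustment(theta)
    phi <- NULL
  } else {
    theta <- atan2(reduced[, 2], reduced[, 1]) %% (2 * pi)
    rho <- sqrt(rowSums(reduced^2))
    z <- ifelse(rho > 0, reduced[, 3] / rho, 1)
    phi <- acos(pmin(1, pmax(-1, z)))
  }
  if (is.null(gamma)) gamma <- fit_degree_exponent(igraph::degree(g))$gamma
  r <- radial_coordinates(edges, gamma = gamma, zeta = zeta)

  coords <- tibble::tibble(node = seq_len(n), r = r, theta = theta)
  if (!is.null(phi)) coords$phi <- phi
  new_hyper_embedding(coords,
    config = list(method = "coalescent", preweight = preweight,
                  reducer = reducer, adjust = if (dims == 2) adjust else "none",
                  dims = dims, gamma = gamma, zeta = zeta))
}

new_hyper_embedding <- function(coords, config) {
  structure(list(coords = coords, config = config), class = "hyper_embedding")
}

#' @export
print.hyper_embedding <- function(x, ...) {
  cfg <- x$config
  desc <- if (cfg$method == "coalescent") {
    sprintf("%s-%s-%s", cfg$preweight, cfg$reducer, cfg$adjust)
  } else {
    cfg$method
  }
  cat(sprintf("Hyperbolic embedding (%s, %dD): %d nodes, gamma = %.3f\n",
              desc, cfg$dims, nrow(x$coords), cfg$gamma))
  invisible(x)
}

#' @export
tidy.hyper_embedding <- function(x, ...) x$coords

#' @export
glance.hyper_embedding <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    method = cfg$method,
    preweight = cfg$preweight %||% NA_character_,
    reducer = cfg$reducer %||% NA_character_,
    adjust = cfg$adjust %||% NA_character_,
    dims = cfg$dims, gamma = cfg$gamma, zeta = cfg$zeta,
    n = nrow(x$coords))
}
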