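#' Angular adjustment of reduced coordinates
#'
#' `circular_adjustment()` turns the retained reduced coordinates into angles
#' on `[0, 2*pi)`:
#' * 2-column (manifold) coordinates: the polar angle of each node's point
#'   around the origin;
#' * 1-column (MCE/ncMCE) coordinates: a linear rescaling of the scores onto
#'   `[0, 2*pi*(n-1)/n]`, so the minimum score maps to 0 and the two extremes
#'   do not collide on the circle.
#'
#' `equidistant_adjustment()` discards the angular spacing and reassigns
#' `theta = 2*pi*k/n`, `k = 0..n-1`, in the circular order of the input
#' angles: the node with the smallest input angle gets `k = 0`. Ties are
#' broken by ascending node id. This trades short-range angular noise for an
#' even spread.
#'
#' @param coords An `n x 1` or `n x 2` matrix from [reduce_embedding()]
#'   (2D pipelines).
#' @return A numeric vector of angles in `[0, 2*pi)`.
#' @export
#' @examples
#' circular_adjustment(cbind(c(1, 0), c(0, -1)))  # 0 and 3*pi/2
#' equidistant_adjustment(c(0.1, 0.2, 3.0, 6.0))  # 0, pi/2, pi, 3*pi/2
circular_adjustment <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) == 2) {
    theta <- atan2(coords[, 2], coords[, 1]) %% (2 * pi)
  } else if (ncol(coords) == 1) {
    v <- coords[, 1]
    rng <- max(v) - min(v)
    if (rng == 0) abort("All 1D coordinates identical; cannot spread on the circle.")
    theta <- (v - min(v)) / rng * 2 * pi * (length(v) - 1) / length(v)
  } else {
    abort("Circular adjustment expects 1 or 2 retained dimensions.")
  }
  theta
}

#' @rdname circular_adjustment
#' @param theta Angles in `[0, 2*pi)` (e.g. from `circular_adjustment()`).
#' @export
equidistant_adjustment <- function(theta) {
  n <- length(theta)
  ord <- order(theta, seq_len(n))
  out <- numeric(n)
  out[ord] <- 2 * pi * (seq_len(n) - 1) / n
  out
}
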